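# Readers/writers for the on-disk formats the pipeline touches:
# MatrixMarket coordinate matrices with TSV sidecars (10x-style triplets),
# BED3/BED4 peaks, TSV gene annotations and cell tables, edge-list TSV and
# GraphML for the final network.

peak_id <- function(chrom, start, end) sprintf("%s:%d-%d", chrom, start, end)

#' Read a sparse count matrix (MatrixMarket + TSV sidecars)
#'
#' Rows are features in file order, columns are barcodes in file order.
#' Entries must be non-negative integers.
#'
#' @param mtx_path MatrixMarket coordinate file.
#' @param features_path,barcodes_path One-column (first column used) TSV files
#'   naming the rows and columns.
#' @return A `dgCMatrix` with feature/barcode dimnames.
#' @export
read_count_matrix <- function(mtx_path, features_path, barcodes_path) {
  for (p in c(mtx_path, features_path, barcodes_path)) {
    if (!file.exists(p)) stop_format("file not found: %s", p)
  }
  m <- Matrix::readMM(mtx_path)
  feats <- readr::read_tsv(features_path, col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)[[1]]
  cells <- readr::read_tsv(barcodes_path, col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)[[1]]
  if (nrow(m) != length(feats)) {
    stop_format("%s declares %d rows but %s lists %d features",
                mtx_path, nrow(m), features_path, length(feats))
  }
  if (ncol(m) != length(cells)) {
    stop_format("%s declares %d columns but %s lists %d barcodes",
                mtx_path, ncol(m), barcodes_path, length(cells))
  }
  m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
  dimnames(m) <- list(feats, cells)
  validate_count_matrix(m, name = mtx_path)
  m
}

#' Write a sparse count matrix (MatrixMarket + TSV sidecars)
#'
#' Inverse of [read_count_matrix()]; round-trips all nonzeros exactly.
#'
#' @param counts Features x cells matrix with dimnames.
#' @param mtx_path,features_path,barcodes_path Output paths.
#' @export
write_count_matrix <- function(counts, mtx_path, features_path, barcodes_path) {
  validate_count_matrix(counts)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"), mtx_path)
  readr::write_tsv(tibble::tibble(x = rownames(counts)), features_path,
                   col_names = FALSE)
  readr::write_tsv(tibble::tibble(x = colnames(counts)), barcodes_path,
                   col_names = FALSE)
  invisible(NULL)
}

#' Validate a count matrix
#'
#' Checks the CountMatrix contract: non-negative integer entries, unique
#' feature and cell identifiers.
#'
#' @param counts Matrix to check.
#' @param name Label used in error messages.
#' @return The matrix, invisibly.
#' @export
validate_count_matrix <- function(counts, name = "count matrix") {
  x <- if (methods::is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (length(x) && any(x < 0)) stop_valid("%s contains negative entries", name)
  if (length(x) && any(x != round(x))) {
    stop_valid("%s contains non-integer entries", name)
  }
  if (anyDuplicated(rownames(counts))) stop_valid("%s has duplicated feature ids", name)
  if (anyDuplicated(colnames(counts))) stop_valid("%s has duplicated cell ids", name)
  invisible(counts)
}

#' Read peaks from a BED file
#'
#' BED3 or BED4; coordinates are 0-based half-open and preserved exactly, in
#' input order. An optional numeric 4th column is taken as the per-peak GC
#' fraction (used for background matching); otherwise `gc` is NA and can be
#' supplied later.
#'
#' @param path BED file.
#' @return Tibble with columns `peak_id` (`chrom:start-end`), `chrom`,
#'   `start`, `end`, `gc`.
#' @export
read_peaks_bed <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  # base read.table with fill: BED3 and BED4 lines may be mixed
  bed <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(bed) < 3) stop_format("%s: BED needs at least 3 columns", path)
  pk <- tibble::tibble(
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]),
    end = as.integer(bed[[3]]),
    gc = if (ncol(bed) >= 4) {
      suppressWarnings(as.numeric(ifelse(bed[[4]] == "", NA, bed[[4]])))
    } else NA_real_
  )
  bad <- which(pk$start >= pk$end)
  if (length(bad)) {
    stop_valid("%s line %d: start (%d) must be < end (%d)",
               path, bad[1], pk$start[bad[1]], pk$end[bad[1]])
  }
  if (any(!is.na(pk$gc) & (pk$gc < 0 | pk$gc > 1))) {
    stop_valid("%s: gc fraction outside [0,1]", path)
  }
  pk <- dplyr::mutate(pk, peak_id = peak_id(.data$chrom, .data$start, .data$end),
                      .before = 1)
  if (anyDuplicated(pk$peak_id)) {
    stop_valid("%s: duplicated peak (chrom,start,end)", path)
  }
  pk
}

#' Write peaks to a BED file
#'
#' BED4 when `gc` is present (4th column = gc fraction), else BED3.
#'
#' @param peaks Tibble as returned by [read_peaks_bed()].
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  cols <- peaks[, c("chrom", "start", "end")]
  if (all(!is.na(peaks$gc))) cols$gc <- peaks$gc
  readr::write_tsv(cols, path, col_names = FALSE)
  invisible(NULL)
}

#' Read gene annotations (TSV)
#'
#' Requires columns `gene_id`, `chrom`, `strand` and either a resolved `tss`
#' column or `start`/`end` gene-body coordinates from which the TSS is
#' resolved strand-aware: TSS = start for `+` genes, TSS = end - 1 for `-`
#' genes (0-based half-open, so end - 1 is the last covered base).
#'
#' @param path TSV file with a header.
#' @return Tibble with `gene_id`, `chrom`, `strand`, `tss` and, when the
#'   input carried them, `start`/`end`.
#' @export
read_gene_annotations <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  g <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "chrom", "strand")
  if (!all(need %in% names(g))) {
    stop_format("%s: missing column(s) %s", path,
                paste(setdiff(need, names(g)), collapse = ", "))
  }
  g$strand <- as.character(g$strand)
  bad <- which(!g$strand %in% c("+", "-"))
  if (length(bad)) {
    stop_valid("%s line %d: unknown strand symbol '%s'",
               path, bad[1] + 1L, g$strand[bad[1]])
  }
  if (!"tss" %in% names(g)) {
    if (!all(c("start", "end") %in% names(g))) {
      stop_format("%s: need either a tss column or start/end columns", path)
    }
    g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  }
  g$tss <- as.integer(g$tss)
  if (any(g$tss < 0)) stop_valid("%s: negative tss", path)
  if (anyDuplicated(g$gene_id)) {
    stop_valid("%s: duplicated gene_id '%s'", path,
               g$gene_id[duplicated(g$gene_id)][1])
  }
  keep <- intersect(c("gene_id", "chrom", "strand", "tss", "start", "end"),
                    names(g))
  tibble::as_tibble(g[, keep])
}

#' Read a binary peak x TF motif-match matrix
#'
#' @param mtx_path MatrixMarket file, peaks x TFs, entries in \{0,1\}.
#' @param tfs_path TSV with header columns `tf_id` and `gene_id` mapping each
#'   TF to its coding gene (gene_id may be NA for TFs absent from the
#'   expression space; these are flagged and skipped downstream).
#' @param peak_ids Character vector naming the rows (peak ids in matrix row
#'   order).
#' @return A `motif_matches` object: list with `matches` (binary dgCMatrix,
#'   peaks x TFs) and `tf_genes` (named character, TF id -> gene id).
#' @export
read_motif_matches <- function(mtx_path, tfs_path, peak_ids) {
  m <- Matrix::readMM(mtx_path)
  tf <- readr::read_tsv(tfs_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("tf_id", "gene_id") %in% names(tf))) {
    stop_format("%s: needs tf_id and gene_id columns", tfs_path)
  }
  if (ncol(m) != nrow(tf)) {
    stop_format("%s declares %d TFs but %s lists %d", mtx_path, ncol(m),
                tfs_path, nrow(tf))
  }
  if (nrow(m) != length(peak_ids)) {
    stop_format("%s declares %d peaks but %d peak ids supplied",
                mtx_path, nrow(m), length(peak_ids))
  }
  m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
  if (length(m@x) && !all(m@x %in% c(0, 1))) {
    stop_valid("%s: motif matrix entries must be 0/1", mtx_path)
  }
  dimnames(m) <- list(peak_ids, tf$tf_id)
  motif_matches(m, stats::setNames(as.character(tf$gene_id), tf$tf_id))
}

#' Construct a motif_matches object
#'
#' @param matches Binary peaks x TFs sparse matrix with dimnames.
#' @param tf_genes Named character vector, TF id -> coding gene id.
#' @return A `motif_matches` list.
#' @export
motif_matches <- function(matches, tf_genes) {
  stopifnot(!is.null(colnames(matches)), !is.null(rownames(matches)))
  if (!all(colnames(matches) %in% names(tf_genes))) {
    stop_valid("every tf_id needs a tf_genes entry")
  }
  structure(list(matches = matches,
                 tf_genes = tf_genes[colnames(matches)]),
            class = "motif_matches")
}

#' Read a cell metadata table
#'
#' @param path TSV with header columns `cell_id`, `modality`
#'   (RNA/ATAC/PAIRED), `cluster`, optional `batch`.
#' @return Tibble.
#' @export
read_cell_table <- function(path) {
  ct <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cell_id", "modality", "cluster")
  if (!all(need %in% names(ct))) {
    stop_format("%s: missing column(s) %s", path,
                paste(setdiff(need, names(ct)), collapse = ", "))
  }
  if (!all(ct$modality %in% c("RNA", "ATAC", "PAIRED"))) {
    stop_valid("%s: modality must be RNA, ATAC or PAIRED", path)
  }
  dup <- ct |> dplyr::count(.data$modality, .data$cell_id) |> dplyr::filter(n > 1)
  if (nrow(dup)) {
    stop_valid("%s: duplicated cell_id '%s' within modality %s",
               path, dup$cell_id[1], dup$modality[1])
  }
  if (!"batch" %in% names(ct)) ct$batch <- NA_character_
  tibble::as_tibble(ct[, c("cell_id", "modality", "cluster", "batch")])
}

#' Export an eGRN as edge-list TSV and GraphML
#'
#' The edge list carries tf, gene, weight; when node statistics are attached
#' (see [annotate_egrn()]) they are written as GraphML node attributes
#' `pagerank`, `betweenness`, `peak_time`.
#'
#' @param egrn An `egrn` object.
#' @param edgelist_path,graphml_path Output paths (either may be NULL to
#'   skip).
#' @export
write_grn <- function(egrn, edgelist_path = NULL, graphml_path = NULL) {
  stopifnot(inherits(egrn, "egrn"))
  edges <- egrn$edges
  if (nrow(edges) == 0) {
    rlang::warn("eGRN is empty; writing headers only")
  }
  if (!is.null(edgelist_path)) {
    readr::write_tsv(edges[, c("tf", "gene", "weight")], edgelist_path)
  }
  if (!is.null(graphml_path)) {
    g <- egrn_igraph(egrn)
    ns <- egrn$nodes
    if (!is.null(ns)) {
      idx <- match(igraph::V(g)$name, ns$node)
      igraph::V(g)$pagerank <- ns$pagerank[idx]
      igraph::V(g)$betweenness <- ns$betweenness[idx]
      igraph::V(g)$peak_time <- ns$peak_time[idx]
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(NULL)
}

# igraph view of an egrn (directed TF -> gene, weight attribute).
egrn_igraph <- function(egrn) {
  nodes <- unique(c(egrn$edges$tf, egrn$edges$gene,
                    if (!is.null(egrn$nodes)) egrn$nodes$node))
  igraph::graph_from_data_frame(
    egrn$edges[, c("tf", "gene", "weight")],
    directed = TRUE,
    vertices = data.frame(name = nodes %||% character())
  )
}
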