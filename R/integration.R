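# Cross-modality integration: gene activity scores from ATAC, CCA
# co-embedding of RNA and ATAC cells, and exact minimum-cost one-to-one cell
# pairing restricted to k-nearest cross-modality candidates.

#' Gene activity scores from ATAC counts
#'
#' Sums, per cell, the counts of all peaks overlapping each gene's window
#' (gene body plus `upstream_bp` bp upstream of the TSS, strand-aware). Peaks
#' overlapping several windows count fully for each gene. Genes without any
#' overlapping peak keep an all-zero row.
#'
#' @param atac Peaks x cells count matrix; rownames are peak ids matching
#'   `peaks$peak_id`.
#' @param peaks Peak tibble ([read_peaks_bed()]).
#' @param genes Gene annotation tibble ([read_gene_annotations()]); uses
#'   `start`/`end` gene bodies when present, else the TSS alone.
#' @param upstream_bp Upstream extension in bp (default 1e5, so distal
#'   regulatory peaks contribute to the score).
#' @return Genes x cells sparse matrix.
#' @export
gene_activity_scores <- function(atac, peaks, genes, upstream_bp = 1e5) {
  stopifnot(nrow(atac) == nrow(peaks))
  if (!is.null(rownames(atac)) && !identical(rownames(atac), peaks$peak_id)) {
    stop_valid("atac rownames do not match peaks$peak_id")
  }
  body_start <- if ("start" %in% names(genes)) genes$start else genes$tss
  body_end <- if ("end" %in% names(genes)) genes$end else genes$tss + 1L
  win_start <- ifelse(genes$strand == "+", body_start - upstream_bp, body_start)
  win_end <- ifelse(genes$strand == "+", body_end, body_end + upstream_bp)
  win_start <- pmax(win_start, 0)

  missing_chr <- setdiff(unique(genes$chrom), unique(peaks$chrom))
  if (length(missing_chr)) {
    rlang::warn(sprintf("no peaks on chromosome(s) %s; affected genes get zero activity",
                        paste(missing_chr, collapse = ", ")))
  }
  # GRanges are 1-based closed; shift from 0-based half-open.
  gr_peaks <- GenomicRanges::GRanges(peaks$chrom,
                                     IRanges::IRanges(peaks$start + 1L, peaks$end))
  gr_win <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(win_start + 1L, win_end))
  hits <- GenomicRanges::findOverlaps(gr_peaks, gr_win)
  ind <- Matrix::sparseMatrix(
    i = S4Vectors::subjectHits(hits),
    j = S4Vectors::queryHits(hits),
    x = 1,
    dims = c(nrow(genes), nrow(peaks))
  )
  act <- ind %*% atac
  dimnames(act) <- list(genes$gene_id, colnames(atac))
  methods::as(act, "CsparseMatrix")
}

#' CCA co-embedding of RNA and ATAC cells
#'
#' Both matrices are library-size normalized (counts per 10k, log1p) and
#' restricted to the `n_features` most variable shared genes (variance ranked
#' on the normalized RNA matrix). Features are standardized within each
#' modality, and the classical diagonal-free CCA is computed as the SVD of the
#' cells x cells cross-product through features, `K = t(X_rna) %*% X_atac`.
#' Cell coordinates are the singular vectors scaled by the singular values and
#' L2-normalized per cell. Signs are fixed deterministically: within each
#' component the largest-magnitude entry of the stacked (RNA, ATAC) vector is
#' made positive, so the embedding is invariant to cell ordering.
#'
#' @param rna Genes x cells RNA count matrix.
#' @param activity Genes x cells activity (or RNA-like) matrix for the ATAC
#'   cells, e.g. from [gene_activity_scores()].
#' @param n_dims Number of canonical components (default 20).
#' @param n_features Number of shared variable genes (default 2000, capped at
#'   the number available).
#' @return A `co_embedding` list with matrices `rna` and `atac`
#'   (cells x n_dims, rownames = cell ids).
#' @export
joint_embedding <- function(rna, activity, n_dims = 20, n_features = 2000) {
  shared <- intersect(rownames(rna), rownames(activity))
  if (length(shared) < n_dims) {
    stop_valid("only %d shared features for %d dimensions",
               length(shared), n_dims)
  }
  ln_rna <- log_normalize(rna[shared, , drop = FALSE])
  ln_atac <- log_normalize(activity[shared, , drop = FALSE])
  v <- row_var_sparse(ln_rna)
  n_features <- min(n_features, length(shared))
  hvg <- order(-v, shared)[seq_len(n_features)]
  X_r <- standardize_rows(ln_rna[hvg, , drop = FALSE])
  X_a <- standardize_rows(ln_atac[hvg, , drop = FALSE])
  K <- crossprod(X_r, X_a)
  s <- svd(K, nu = n_dims, nv = n_dims)
  u <- s$u
  w <- s$v
  for (j in seq_len(n_dims)) {
    stacked <- c(u[, j], w[, j])
    if (stacked[which.max(abs(stacked))] < 0) {
      u[, j] <- -u[, j]
      w[, j] <- -w[, j]
    }
  }
  coords_r <- u %*% diag(s$d[seq_len(n_dims)], n_dims)
  coords_a <- w %*% diag(s$d[seq_len(n_dims)], n_dims)
  rownames(coords_r) <- colnames(rna)
  rownames(coords_a) <- colnames(activity)
  structure(list(rna = l2_normalize_rows(coords_r),
                 atac = l2_normalize_rows(coords_a)),
            class = "co_embedding")
}

row_var_sparse <- function(x) {
  n <- ncol(x)
  mu <- Matrix::rowMeans(x)
  (Matrix::rowSums(x^2) - n * mu^2) / (n - 1)
}

l2_normalize_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  x / nrm
}

#' Principal-component embedding of an expression matrix
#'
#' Log-normalizes, selects the most variable genes, standardizes them and
#' takes the top singular vectors — the standard low-dimensional
#' representation used for trajectory inference on paired data.
#'
#' @param counts Genes x cells count matrix.
#' @param n_dims,n_features As in [joint_embedding()].
#' @return Cells x n_dims matrix with cell-id rownames.
#' @export
pca_embedding <- function(counts, n_dims = 20, n_features = 2000) {
  ln <- log_normalize(counts)
  v <- row_var_sparse(ln)
  keep <- order(-v, rownames(counts))[seq_len(min(n_features, nrow(counts)))]
  X <- standardize_rows(ln[keep, , drop = FALSE])
  n_dims <- min(n_dims, nrow(X) - 1, ncol(X) - 1)
  s <- svd(X, nu = n_dims, nv = n_dims)
  for (j in seq_len(n_dims)) {
    if (s$v[which.max(abs(s$v[, j])), j] < 0) s$v[, j] <- -s$v[, j]
  }
  coords <- s$v %*% diag(s$d[seq_len(n_dims)], n_dims)
  rownames(coords) <- colnames(counts)
  coords
}

#' Exact minimum-cost one-to-one assignment
#'
#' Solves the (possibly rectangular) assignment problem by Jonker-Volgenant
#' shortest augmenting paths (compiled, exact, deterministic). `Inf` entries
#' forbid a pair; if the optimum is forced through a forbidden pair the
#' result is flagged infeasible so callers can relax the restriction. Used by
#' [pair_cells()]; exported because it is also the right tool for any small
#' matching subproblem.
#'
#' @param cost Numeric matrix, rows x columns; `Inf` forbids a pair.
#' @return List with `pairs` (two-column integer matrix, row index / col
#'   index; `min(dim(cost))` rows), `total_cost`, and `feasible` (FALSE when a
#'   forbidden pair was unavoidable).
#' @export
min_cost_matching <- function(cost) {
  finite <- is.finite(cost)
  if (!any(finite)) stop_valid("no feasible pairs in cost matrix")
  flip <- nrow(cost) > ncol(cost)
  C <- if (flip) t(cost) else cost
  forb <- !is.finite(C)
  # any all-finite assignment costs less than one forbidden edge
  big <- (max(C[!forb]) - min(0, min(C[!forb]))) * min(dim(C)) + 1
  C[forb] <- big
  sol <- .lap_solve(C)
  pairs <- cbind(row = seq_len(nrow(C)), col = sol$col)
  feasible <- !any(forb[pairs])
  if (flip) pairs <- cbind(row = pairs[, 2], col = pairs[, 1])
  list(pairs = pairs, total_cost = sum(cost[pairs]), feasible = feasible)
}

#' One-to-one cell pairing across modalities
#'
#' Pairs RNA cells to ATAC cells by exact minimum-total-cost matching on
#' Euclidean distances in the shared co-embedding, restricted to each cell's
#' `k_candidates` nearest cross-modality neighbors (the union of both
#' directions; non-candidates are forbidden). If the restricted problem cannot
#' match min(n_RNA, n_ATAC) cells, it falls back to the unrestricted exact
#' matching with a warning.
#'
#' @param emb_rna,emb_atac Cells x dims coordinate matrices in the same space
#'   (e.g. from [joint_embedding()]), rownames = cell ids.
#' @param k_candidates Candidate-neighborhood size (default 10); `Inf` for the
#'   unrestricted dense problem.
#' @return Tibble (`rna_cell`, `atac_cell`, `cost`) of class `cell_pairing`
#'   with attribute `total_cost`.
#' @export
pair_cells <- function(emb_rna, emb_atac, k_candidates = 10) {
  stopifnot(ncol(emb_rna) == ncol(emb_atac), k_candidates >= 1)
  d2 <- pmax(outer(rowSums(emb_rna^2), rowSums(emb_atac^2), "+") -
               2 * tcrossprod(emb_rna, emb_atac), 0)
  cost <- sqrt(d2)
  n_r <- nrow(cost)
  n_a <- ncol(cost)
  k <- min(k_candidates, n_r, n_a)
  restricted <- cost
  if (is.finite(k_candidates) && k < max(n_r, n_a)) {
    keep <- matrix(FALSE, n_r, n_a)
    for (i in seq_len(n_r)) keep[i, order(cost[i, ])[seq_len(k)]] <- TRUE
    for (j in seq_len(n_a)) keep[order(cost[, j])[seq_len(k)], j] <- TRUE
    restricted[!keep] <- Inf
  }
  m <- min_cost_matching(restricted)
  if (!m$feasible) {
    rlang::warn("candidate restriction infeasible; falling back to unrestricted matching")
    m <- min_cost_matching(cost)
  }
  out <- tibble::tibble(
    rna_cell = rownames(emb_rna)[m$pairs[, 1]],
    atac_cell = rownames(emb_atac)[m$pairs[, 2]],
    cost = cost[m$pairs]
  )
  structure(out, total_cost = m$total_cost,
            class = c("cell_pairing", class(out)))
}

#' Evaluate a pairing against ground truth
#'
#' @param pairing Tibble from [pair_cells()].
#' @param truth_pairs Tibble with `rna_cell`, `atac_cell` true pairs.
#' @param cluster_labels Named character vector, cell id -> cluster label
#'   (covering cells of both modalities).
#' @return Tibble with `exact_pair_recovery` (count of exactly recovered
#'   pairs) and `celltype_accuracy` (fraction of pairs whose cells share a
#'   cluster label).
#' @export
evaluate_pairing <- function(pairing, truth_pairs, cluster_labels) {
  key <- paste(pairing$rna_cell, pairing$atac_cell)
  tkey <- paste(truth_pairs$rna_cell, truth_pairs$atac_cell)
  same <- cluster_labels[pairing$rna_cell] == cluster_labels[pairing$atac_cell]
  tibble::tibble(
    exact_pair_recovery = sum(key %in% tkey),
    celltype_accuracy = mean(same)
  )
}
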