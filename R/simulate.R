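# Synthetic multiome simulator with a planted enhancer-based regulatory
# network. One linear synthetic chromosome, deterministic gene layout,
# pseudotime-driven TF activity profiles, target genes driven by planted
# TF->gene weights, enhancer peaks whose accessibility tracks their gene, and
# pseudotime-independent promoters and decoys. Everything derives from one
# seed, so outputs are bit-identical across runs.

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: 2000 cells on a
#' uniform \[0, 100\] pseudotime split into 4 ordered clusters, 10 TFs, equal
#' numbers of trajectory-driven target genes and pseudotime-independent
#' decoys, 2 distal enhancers plus 1 promoter peak per gene on a 250 kb gene
#' grid, enhancer distances uniform on \[2, 100\] kb (so every planted enhancer
#' survives the 2 kb rule and every promoter fails it), moderate sequencing
#' depths and Poisson counts.
#'
#' @param n_cells Number of cells (default 2000).
#' @param n_tfs Number of TFs (default 10).
#' @param n_target_genes Trajectory-driven target genes (default 100).
#' @param n_decoy_genes Pseudotime-independent genes (default 100).
#' @param enhancers_per_gene Distal enhancer peaks per gene (default 2).
#' @param promoter_per_gene Promoter peaks per gene (fixed at 1).
#' @param tss_spacing Distance between consecutive TSSs in bp (default
#'   250000).
#' @param enhancer_distance_range Range of enhancer nearest-edge distances
#'   from the TSS in bp (default c(2000, 100000); the minimum must stay >=
#'   2000 so planted links survive the enhancer filter).
#' @param depth_rna,depth_atac Expected counts per cell (defaults 2000 /
#'   4000).
#' @param noise_sd Gaussian rate noise sd (default 0.2).
#' @param edge_density Probability of a planted TF->gene edge (default 0.15);
#'   every target keeps at least one regulator.
#' @param false_match_rate Rate of spurious motif matches in random peaks
#'   (default 0.02).
#' @param frac_repressive Fraction of planted edges with negative weight
#'   (default 0).
#' @param nb_dispersion Optional negative-binomial dispersion; NULL (default)
#'   draws Poisson counts.
#' @param paired If TRUE (default) emit a paired multiome; otherwise duplicate
#'   each cell into an RNA and an ATAC copy with independent counts and record
#'   the true pairs.
#' @param seed Integer RNG seed (default 1).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cells = 2000, n_tfs = 10, n_target_genes = 100,
                       n_decoy_genes = 100, enhancers_per_gene = 2,
                       promoter_per_gene = 1, tss_spacing = 250000,
                       enhancer_distance_range = c(2000, 100000),
                       depth_rna = 2000, depth_atac = 4000, noise_sd = 0.2,
                       edge_density = 0.15, false_match_rate = 0.02,
                       frac_repressive = 0, nb_dispersion = NULL,
                       paired = TRUE, seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_cells, n_tfs, n_target_genes, n_decoy_genes,
              enhancers_per_gene, promoter_per_gene, tss_spacing,
              depth_rna, depth_atac)
  if (any(counts <= 0)) stop_valid("all size/depth parameters must be positive")
  if (promoter_per_gene != 1) stop_valid("promoter_per_gene is fixed at 1")
  if (enhancer_distance_range[1] < 2000) {
    stop_valid("enhancer_distance_range minimum must be >= 2000 bp so planted links survive the enhancer filter")
  }
  if (enhancer_distance_range[1] >= enhancer_distance_range[2]) {
    stop_valid("enhancer_distance_range must be increasing")
  }
  if (edge_density <= 0 || edge_density > 1) stop_valid("edge_density must be in (0,1]")
  if (noise_sd < 0 || false_match_rate < 0 || false_match_rate > 1) {
    stop_valid("invalid noise_sd or false_match_rate")
  }
  structure(cfg, class = "sim_config")
}

# Latent TF activity profile over pseudotime: logistic ramp (up or down) or
# Gaussian bump, standardized to mean 0 / sd 1 over the cells.
latent_profile <- function(t) {
  shape <- sample(c("ramp_up", "ramp_down", "bump"), 1)
  t0 <- stats::runif(1, 20, 80)
  f <- switch(shape,
              ramp_up = 1 / (1 + exp(-(t - t0) / stats::runif(1, 5, 15))),
              ramp_down = 1 / (1 + exp((t - t0) / stats::runif(1, 5, 15))),
              bump = exp(-(t - t0)^2 / (2 * stats::runif(1, 8, 20)^2)))
  as.numeric(scale(f))
}

#' Simulate a multiome dataset with a planted eGRN
#'
#' See [sim_config()] for the generative model. Returns count matrices, peak
#' and gene tables, motif matches, cell metadata and the full ground truth
#' (planted edges and enhancer links, true pseudotime, cluster labels, true
#' pairs in unpaired mode).
#'
#' @param config A [sim_config()].
#' @return A `sim_multiome` list: `rna`, `atac` (sparse count matrices),
#'   `peaks`, `genes`, `motifs`, `cells`, `truth`, `config`.
#' @export
simulate_multiome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_multiome_impl(config))
}

simulate_multiome_impl <- function(cfg) {
  n <- cfg$n_cells
  t <- stats::runif(n, 0, 100)
  qs <- stats::quantile(t, c(0.25, 0.5, 0.75))
  cluster <- paste0("C", findInterval(t, qs) + 1L)
  cell_base <- sprintf("cell%05d", seq_len(n))

  # --- latent TF profiles and expression rates -----------------------------
  f <- t(vapply(seq_len(cfg$n_tfs), function(k) latent_profile(t), numeric(n)))
  tf_ids <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  tf_gene_ids <- sprintf("gTF%02d", seq_len(cfg$n_tfs))
  target_ids <- sprintf("TG%03d", seq_len(cfg$n_target_genes))
  decoy_ids <- sprintf("DG%03d", seq_len(cfg$n_decoy_genes))
  gene_ids <- c(tf_gene_ids, target_ids, decoy_ids)

  noise <- function(nr) matrix(stats::rnorm(nr * n, 0, cfg$noise_sd), nr, n)
  rate_tf <- pmax(softplus(f) + noise(cfg$n_tfs), 0.01)

  W <- matrix(0, cfg$n_tfs, cfg$n_target_genes)
  mask <- matrix(stats::runif(length(W)) < cfg$edge_density, cfg$n_tfs,
                 cfg$n_target_genes)
  for (g in which(colSums(mask) == 0)) mask[sample.int(cfg$n_tfs, 1), g] <- TRUE
  W[mask] <- stats::runif(sum(mask), 0.5, 1.5)
  rep_sign <- mask & matrix(stats::runif(length(W)) < cfg$frac_repressive,
                            nrow(W), ncol(W))
  W[rep_sign] <- -W[rep_sign]

  comb <- crossprod(W, f)                       # targets x cells
  comb <- comb / pmax(apply(comb, 1, stats::sd), 1e-8)
  rate_target <- pmax(softplus(comb) + noise(cfg$n_target_genes), 0.01)
  rate_decoy <- pmax(stats::runif(cfg$n_decoy_genes, 0.5, 2) +
                       noise(cfg$n_decoy_genes), 0.01)

  rate_rna <- rbind(rate_tf, rate_target, rate_decoy)
  rownames(rate_rna) <- gene_ids

  # --- genome layout -------------------------------------------------------
  layout_order <- sample(gene_ids)
  tss <- stats::setNames(150000 + (seq_along(layout_order) - 1) * cfg$tss_spacing,
                         layout_order)[gene_ids]
  strand <- sample(c("+", "-"), length(gene_ids), replace = TRUE)
  body_len <- 10000L
  genes <- tibble::tibble(
    gene_id = gene_ids,
    chrom = "chrS",
    strand = strand,
    tss = as.integer(tss),
    start = as.integer(ifelse(strand == "+", tss, tss - body_len + 1L)),
    end = as.integer(ifelse(strand == "+", tss + body_len, tss + 1L))
  )

  E <- cfg$enhancers_per_gene
  width <- 500L
  peak_rows <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    d <- round(stats::runif(E, cfg$enhancer_distance_range[1],
                            cfg$enhancer_distance_range[2]))
    if (g$strand == "+") {
      enh_end <- g$tss - d + 1L
      enh_start <- enh_end - width
    } else {
      enh_start <- g$tss + d
      enh_end <- enh_start + width
    }
    tibble::tibble(
      gene_id = g$gene_id,
      role = c("promoter", rep("enhancer", E)),
      chrom = "chrS",
      start = as.integer(c(g$tss - 200L, enh_start)),
      end = as.integer(c(g$tss + 300L, enh_end))
    )
  })
  while (anyDuplicated(peak_rows[, c("chrom", "start", "end")])) {
    dup <- duplicated(peak_rows[, c("chrom", "start", "end")])
    peak_rows$start[dup] <- peak_rows$start[dup] + 1L
    peak_rows$end[dup] <- peak_rows$end[dup] + 1L
  }
  peak_rows$peak_id <- peak_id(peak_rows$chrom, peak_rows$start, peak_rows$end)
  peaks <- tibble::tibble(
    peak_id = peak_rows$peak_id,
    chrom = peak_rows$chrom,
    start = peak_rows$start,
    end = peak_rows$end,
    gc = stats::runif(nrow(peak_rows), 0.3, 0.7)
  )

  # --- peak accessibility rates -------------------------------------------
  n_peaks <- nrow(peak_rows)
  rate_atac <- matrix(0, n_peaks, n)
  is_prom <- peak_rows$role == "promoter"
  rate_atac[is_prom, ] <- pmax(stats::runif(sum(is_prom), 1, 3) +
                                 noise(sum(is_prom)), 0.01)
  enh_rows <- which(!is_prom)
  enh_scale <- stats::runif(length(enh_rows), 0.8, 1.2)
  rate_atac[enh_rows, ] <- pmax(
    enh_scale * rate_rna[peak_rows$gene_id[enh_rows], , drop = FALSE] +
      noise(length(enh_rows)),
    0.01
  )
  rownames(rate_atac) <- peak_rows$peak_id

  # --- motif matches -------------------------------------------------------
  planted <- which(mask, arr.ind = TRUE)  # (tf, target) index pairs
  planted_edges <- tibble::tibble(
    tf = tf_ids[planted[, 1]],
    gene = target_ids[planted[, 2]],
    weight = W[planted]
  )
  enh_of <- split(which(!is_prom), peak_rows$gene_id[!is_prom])
  mi <- integer(0)
  mj <- integer(0)
  for (e in seq_len(nrow(planted_edges))) {
    rows <- enh_of[[planted_edges$gene[e]]]
    mi <- c(mi, rows)
    mj <- c(mj, rep(planted[e, 1], length(rows)))
  }
  n_false <- stats::rbinom(1, n_peaks * cfg$n_tfs, cfg$false_match_rate)
  if (n_false > 0) {
    fl <- sample.int(n_peaks * cfg$n_tfs, n_false)
    mi <- c(mi, (fl - 1L) %% n_peaks + 1L)
    mj <- c(mj, (fl - 1L) %/% n_peaks + 1L)
  }
  M <- Matrix::sparseMatrix(i = mi, j = mj, x = 1,
                            dims = c(n_peaks, cfg$n_tfs), use.last.ij = FALSE)
  M@x[] <- 1
  dimnames(M) <- list(peak_rows$peak_id, tf_ids)
  motifs <- motif_matches(M, stats::setNames(tf_gene_ids, tf_ids))

  # --- counts --------------------------------------------------------------
  draw_counts <- function(rate, depth, ids) {
    sf <- exp(stats::rnorm(n, 0, 0.3))
    lam <- t(t(rate) / colSums(rate)) * rep(depth * sf, each = nrow(rate))
    x <- if (is.null(cfg$nb_dispersion)) {
      stats::rpois(length(lam), lam)
    } else {
      stats::rnbinom(length(lam), mu = lam, size = 1 / cfg$nb_dispersion)
    }
    m <- Matrix::Matrix(matrix(x, nrow(rate), n), sparse = TRUE)
    dimnames(m) <- list(rownames(rate), ids)
    methods::as(m, "CsparseMatrix")
  }

  if (cfg$paired) {
    rna_ids <- atac_ids <- cell_base
    cells <- tibble::tibble(cell_id = cell_base, modality = "PAIRED",
                            cluster = cluster, batch = NA_character_)
    true_pairs <- tibble::tibble(rna_cell = cell_base, atac_cell = cell_base)
  } else {
    rna_ids <- paste0(cell_base, "-RNA")
    atac_ids <- paste0(cell_base, "-ATAC")
    cells <- dplyr::bind_rows(
      tibble::tibble(cell_id = rna_ids, modality = "RNA", cluster = cluster,
                     batch = NA_character_),
      tibble::tibble(cell_id = atac_ids, modality = "ATAC", cluster = cluster,
                     batch = NA_character_)
    )
    true_pairs <- tibble::tibble(rna_cell = rna_ids, atac_cell = atac_ids)
  }
  rna <- draw_counts(rate_rna, cfg$depth_rna, rna_ids)
  atac <- draw_counts(rate_atac, cfg$depth_atac, atac_ids)

  dynamic <- c(tf_gene_ids, target_ids)
  planted_links <- tibble::tibble(
    peak_id = peak_rows$peak_id[!is_prom & peak_rows$gene_id %in% dynamic],
    gene_id = peak_rows$gene_id[!is_prom & peak_rows$gene_id %in% dynamic]
  )
  planted_links$tss_distance <- tss_distance(
    peaks$start[match(planted_links$peak_id, peaks$peak_id)],
    peaks$end[match(planted_links$peak_id, peaks$peak_id)],
    genes$tss[match(planted_links$gene_id, genes$gene_id)]
  )

  truth <- list(
    pseudotime = tibble::tibble(cell_id = cell_base, t = t, cluster = cluster),
    planted_edges = planted_edges,
    planted_links = planted_links,
    true_pairs = true_pairs
  )
  structure(list(rna = rna, atac = atac, peaks = peaks, genes = genes,
                 motifs = motifs, cells = cells, truth = truth, config = cfg),
            class = "sim_multiome")
}

#' @export
print.sim_multiome <- function(x, ...) {
  cat(sprintf(
    "sim_multiome: %d genes x %d cells RNA, %d peaks ATAC, %d TFs, %d planted edges (%s)\n",
    nrow(x$rna), ncol(x$rna), nrow(x$atac), length(x$motifs$tf_genes),
    nrow(x$truth$planted_edges),
    if (x$config$paired) "paired" else "unpaired"))
  invisible(x)
}

#' Write a simulated multiome to disk
#'
#' Emits the full fixture set in the package's interchange formats: MTX +
#' sidecars for RNA, ATAC and motif matches, BED4 peaks (4th column = GC
#' fraction), TSV gene annotations, cell table, and the ground-truth tables.
#'
#' @param sim A [simulate_multiome()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_multiome <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_count_matrix(sim$rna, p("rna.mtx"), p("rna_features.tsv"),
                     p("rna_barcodes.tsv"))
  write_count_matrix(sim$atac, p("atac.mtx"), p("atac_features.tsv"),
                     p("atac_barcodes.tsv"))
  write_peaks_bed(sim$peaks, p("peaks.bed"))
  readr::write_tsv(sim$genes, p("genes.tsv"))
  readr::write_tsv(sim$cells, p("cells.tsv"))
  Matrix::writeMM(sim$motifs$matches, p("motifs.mtx"))
  readr::write_tsv(tibble::tibble(tf_id = names(sim$motifs$tf_genes),
                                  gene_id = unname(sim$motifs$tf_genes)),
                   p("motif_tfs.tsv"))
  readr::write_tsv(sim$truth$pseudotime, p("truth_pseudotime.tsv"))
  readr::write_tsv(sim$truth$planted_edges, p("truth_edges.tsv"))
  readr::write_tsv(sim$truth$planted_links, p("truth_links.tsv"))
  readr::write_tsv(sim$truth$true_pairs, p("truth_pairs.tsv"))
  invisible(dir)
}
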