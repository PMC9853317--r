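# Trajectory-conditioned selection of candidate TFs and genes, and
# peak-to-gene correlation links. All correlations are Pearson over
# trajectory bins of smoothed profiles, which keeps the estimates stable and
# the pipeline deterministic.

#' Select candidate TFs by activity-expression correlation
#'
#' A TF whose motif accessibility (deviation z profile) rises and falls with
#' the expression of its own coding gene along the trajectory is both
#' expressed and active; the correlation between the two binned profiles is
#' the selection score. TFs whose coding gene is absent from the expression
#' matrix are skipped with a message.
#'
#' @param activity_binned TF activity [bin_smooth()] result (z-scores).
#' @param expression_binned Gene expression [bin_smooth()] result on the same
#'   trajectory.
#' @param motifs [motif_matches()] object (provides the TF -> gene map).
#' @param cor_cutoff Selection cutoff (default 0.4).
#' @param mode `"positive"` (default; select r >= cutoff) or `"absolute"`
#'   (select |r| >= cutoff, admitting repressor-like profiles).
#' @return Tibble (`tf_id`, `gene_id`, `r`, `selected`).
#' @export
select_tfs <- function(activity_binned, expression_binned, motifs,
                       cor_cutoff = 0.4, mode = c("positive", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(identical(activity_binned$bin_centers, expression_binned$bin_centers))
  tfs <- rownames(activity_binned$values)
  genes <- motifs$tf_genes[tfs]
  present <- !is.na(genes) & genes %in% rownames(expression_binned$values)
  if (any(!present)) {
    rlang::inform(sprintf("skipping %d TF(s) without an expression row: %s",
                          sum(!present),
                          paste(tfs[!present], collapse = ", ")))
  }
  a_std <- standardize_rows(activity_binned$values[tfs[present], , drop = FALSE])
  e_std <- standardize_rows(expression_binned$values[genes[present], , drop = FALSE])
  r <- paired_row_cor(a_std, e_std)
  score <- if (mode == "absolute") abs(r) else r
  tibble::tibble(
    tf_id = tfs[present],
    gene_id = unname(genes[present]),
    r = r,
    selected = !is.na(score) & score >= cor_cutoff
  )
}

#' Select the most trajectory-variable genes
#'
#' Ranks genes by the variance of their smoothed binned expression profile and
#' returns exactly `ceiling(top_fraction * n_genes)` of them; ties are broken
#' by lexicographic gene id so the selection is deterministic.
#'
#' @param expression_binned [bin_smooth()] result.
#' @param top_fraction Fraction in (0, 1] (default 0.1, i.e. the top 10
#'   percent).
#' @return Character vector of gene ids.
#' @export
select_variable_genes <- function(expression_binned, top_fraction = 0.1) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  v <- apply(expression_binned$values, 1, stats::var)
  ids <- rownames(expression_binned$values)
  n_sel <- ceiling(top_fraction * length(ids))
  ids[order(-v, ids)][seq_len(n_sel)]
}

#' Peak-to-gene correlation links
#'
#' Candidate pairs are peaks within `max_distance` bp of a gene's TSS
#' (distance from the nearest covered base, 0 if the peak spans the TSS,
#' strand-aware via the resolved TSS). For each candidate the Pearson
#' correlation between the peak's binned accessibility profile and the gene's
#' binned expression profile is computed, and links with r >= `cor_cutoff`
#' are kept. The enhancer flag is set downstream by [enhancer_links()].
#'
#' @param atac_binned Peak accessibility [bin_smooth()] result.
#' @param expression_binned Gene expression [bin_smooth()] result on the same
#'   trajectory.
#' @param peaks Peak tibble.
#' @param genes Gene annotation tibble (restricted to the genes of interest,
#'   e.g. [select_variable_genes()] output).
#' @param max_distance Candidate window around the TSS in bp (default 250000).
#' @param cor_cutoff Link cutoff (default 0.5).
#' @return Tibble (`peak_id`, `chrom`, `start`, `end`, `gene_id`, `r`,
#'   `tss_distance`, `is_enhancer` = NA until filtered).
#' @export
peak_gene_links <- function(atac_binned, expression_binned, peaks, genes,
                            max_distance = 250000, cor_cutoff = 0.5) {
  stopifnot(identical(atac_binned$bin_centers, expression_binned$bin_centers))
  genes <- dplyr::filter(genes, .data$gene_id %in% rownames(expression_binned$values))
  cand <- purrr::map_dfr(split(genes, genes$chrom), function(gch) {
    pch <- dplyr::filter(peaks, .data$chrom == gch$chrom[1])
    if (nrow(pch) == 0) return(NULL)
    d <- outer(seq_len(nrow(pch)), seq_len(nrow(gch)),
               function(i, j) tss_distance(pch$start[i], pch$end[i], gch$tss[j]))
    hit <- which(d <= max_distance, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    tibble::tibble(
      peak_id = pch$peak_id[hit[, 1]],
      chrom = gch$chrom[1],
      start = pch$start[hit[, 1]],
      end = pch$end[hit[, 1]],
      gene_id = gch$gene_id[hit[, 2]],
      tss_distance = d[hit]
    )
  })
  if (nrow(cand) == 0) {
    return(tibble::tibble(peak_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          gene_id = character(), r = numeric(),
                          tss_distance = integer(), is_enhancer = logical()))
  }
  a_std <- standardize_rows(atac_binned$values)
  e_std <- standardize_rows(expression_binned$values)
  cand$r <- paired_row_cor(a_std[cand$peak_id, , drop = FALSE],
                           e_std[cand$gene_id, , drop = FALSE])
  out <- dplyr::filter(cand, !is.na(.data$r), .data$r >= cor_cutoff)
  out$is_enhancer <- NA
  dplyr::arrange(out[, c("peak_id", "chrom", "start", "end", "gene_id", "r",
                         "tss_distance", "is_enhancer")],
                 .data$gene_id, .data$tss_distance)
}
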