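# Bias-corrected TF motif-deviation z-scores. Observed accessibility in
# motif-matched peaks is compared against the read-fraction expectation, and
# standardized against deviations of GC/mean-accessibility-matched background
# peak sets.

#' Sample background peaks matched on GC and mean accessibility
#'
#' Each peak is characterized by (gc, log1p(mean accessibility)); both
#' features are standardized, and each peak's candidate pool is its
#' `n_neighbors` nearest peaks in this 2-D space (Euclidean, excluding
#' itself). Each of the `n_iterations` background sets draws one candidate per
#' peak uniformly with replacement; sampling is reproducible for a fixed
#' seed.
#'
#' @param peaks Peak tibble with a `gc` column.
#' @param mean_accessibility Numeric vector, per-peak mean of the ATAC counts.
#' @param n_neighbors Candidate pool size (default 50).
#' @param n_iterations Number of background sets (default 50).
#' @param seed Integer RNG seed (default 1).
#' @return A `background_peaks` object: list with `indices` (peaks x
#'   n_iterations integer matrix), `n_iterations`, `seed`.
#' @export
background_peaks <- function(peaks, mean_accessibility, n_neighbors = 50,
                             n_iterations = 50, seed = 1) {
  n <- nrow(peaks)
  if (n_neighbors >= n) stop_valid("n_neighbors (%d) must be < n_peaks (%d)",
                                   n_neighbors, n)
  if (any(is.na(peaks$gc))) stop_valid("background matching needs gc for every peak")
  f <- cbind(scale(peaks$gc), scale(log1p(mean_accessibility)))
  f[is.nan(f)] <- 0  # constant covariate: no contribution
  d2 <- outer(rowSums(f^2), rowSums(f^2), "+") - 2 * tcrossprod(f)
  diag(d2) <- Inf
  pool <- do.call(rbind, lapply(seq_len(n),
                                function(i) order(d2[i, ])[seq_len(n_neighbors)]))
  idx <- withr::with_seed(seed, {
    matrix(pool[cbind(rep(seq_len(n), n_iterations),
                      sample.int(n_neighbors, n * n_iterations, replace = TRUE))],
           nrow = n, ncol = n_iterations)
  })
  structure(list(indices = idx, n_iterations = n_iterations, seed = seed),
            class = "background_peaks")
}

#' Bias-corrected motif-deviation z-scores
#'
#' With X the peaks x cells counts, per-cell totals t_c and read fractions
#' a_p = rowSums(X)/sum(X): observed motif counts O = t(M) X, expectation
#' E\[k,c\] = t_c * sum_p M\[p,k\] a_p, raw deviation Y = (O - E)/E. The same
#' quantity is computed with every matched peak replaced by its background
#' partner (per iteration), and z = (Y - mean_b Y_b) / sd_b Y_b with the
#' sample (n-1) standard deviation.
#'
#' TFs with no matched peak or zero expected reads are dropped with a message
#' (recorded in `dropped`), not NaN-propagated. Entries where the background
#' sd is 0 are set NA.
#'
#' @param atac Peaks x cells count matrix.
#' @param motifs [motif_matches()] object aligned to the rows of `atac`.
#' @param background [background_peaks()] result for the same peaks.
#' @return An `activity_matrix`: list with `z` and `raw_dev` (TFs x cells),
#'   and `dropped` (tibble tf_id, reason).
#' @export
deviation_zscores <- function(atac, motifs, background) {
  M <- motifs$matches
  stopifnot(nrow(M) == nrow(atac), nrow(background$indices) == nrow(atac))
  X <- methods::as(methods::as(atac, "CsparseMatrix"), "dMatrix")
  t_c <- Matrix::colSums(X)
  total <- sum(t_c)
  a <- Matrix::rowSums(X) / total

  n_matched <- Matrix::colSums(M)
  exp_frac <- as.numeric(Matrix::crossprod(M, a))
  drop_none <- n_matched == 0
  drop_zero <- !drop_none & exp_frac == 0
  reason <- ifelse(drop_none, "no matched peaks",
                   ifelse(drop_zero, "zero expected reads", NA_character_))
  dropped <- tibble::tibble(tf_id = colnames(M)[!is.na(reason)],
                            reason = unname(reason[!is.na(reason)]))
  if (nrow(dropped)) {
    rlang::inform(sprintf("dropping %d TF(s): %s", nrow(dropped),
                          paste(dropped$tf_id, collapse = ", ")))
  }
  keep <- !(drop_none | drop_zero)
  M <- M[, keep, drop = FALSE]
  exp_frac <- exp_frac[keep]

  dev_for <- function(Mk) {
    O <- as.matrix(Matrix::crossprod(Mk, X))
    E <- as.numeric(Matrix::crossprod(Mk, a)) %o% t_c
    Y <- (O - E) / E
    Y[E == 0] <- NA_real_
    Y
  }
  Y <- dev_for(M)

  Tm <- methods::as(M, "TsparseMatrix")
  n_it <- background$n_iterations
  sum_b <- 0
  sumsq_b <- 0
  for (b in seq_len(n_it)) {
    Mb <- Matrix::sparseMatrix(i = background$indices[Tm@i + 1L, b],
                               j = Tm@j + 1L, x = Tm@x,
                               dims = dim(M))
    Yb <- dev_for(Mb)
    sum_b <- sum_b + Yb
    sumsq_b <- sumsq_b + Yb^2
  }
  mean_b <- sum_b / n_it
  sd_b <- sqrt(pmax(sumsq_b - n_it * mean_b^2, 0) / (n_it - 1))
  z <- (Y - mean_b) / sd_b
  z[sd_b == 0] <- NA_real_
  dimnames(z) <- dimnames(Y) <- list(colnames(M), colnames(X))
  structure(list(z = z, raw_dev = Y, dropped = dropped),
            class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("activity_matrix: %d TFs x %d cells (%d dropped)\n",
              nrow(x$z), ncol(x$z), nrow(x$dropped)))
  invisible(x)
}
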