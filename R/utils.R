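# Shared numeric helpers. Coordinates are 0-based, half-open ([start, end))
# everywhere in the package; a peak covers bases start .. end-1.

#' Distance from a peak to a transcription start site
#'
#' Minimum distance in bp from any covered base of a peak to the TSS, under
#' the package-wide 0-based half-open convention. A peak covering the TSS has
#' distance 0. Every distance computation in the package routes through this
#' helper so the convention cannot drift.
#'
#' @param start,end Integer vectors, peak coordinates (0-based, half-open).
#' @param tss Integer vector (recycled), 0-based TSS position.
#' @return Integer vector of non-negative distances.
#' @export
tss_distance <- function(start, end, tss) {
  stopifnot(all(start < end))
  d <- ifelse(tss < start, start - tss,
              ifelse(tss >= end, tss - (end - 1L), 0L))
  as.integer(d)
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Library-size normalization (counts per 10k, log1p)
#'
#' @param counts A features x cells sparse or dense count matrix.
#' @param scale_factor Target column sum before `log1p` (default 1e4).
#' @return A dgCMatrix of the same shape.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  cs <- Matrix::colSums(counts)
  cs[cs == 0] <- 1
  out <- counts %*% Matrix::Diagonal(x = scale_factor / cs)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(counts)
  out
}

# Row-standardize a (possibly sparse) matrix to zero mean / unit variance.
# Rows with zero variance become all-zero rows.
standardize_rows <- function(x) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- Inf
  (x - mu) / sdv
}

# Pearson correlation between paired rows of two row-standardized matrices.
# a, b: n x B standardized matrices (same rows pairing). Returns length-n
# vector; NA where either profile was constant.
paired_row_cor <- function(a_std, b_std) {
  B <- ncol(a_std)
  r <- rowSums(a_std * b_std) / (B - 1)
  const <- rowSums(a_std != 0) == 0 | rowSums(b_std != 0) == 0
  r[const] <- NA_real_
  unname(r)
}

stop_format <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "egrnet_format_error")
stop_valid <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "egrnet_validation_error")
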