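# Supervised pseudotime over a user-ordered cluster path, and binning /
# smoothing of cell-level matrices along it. The scheme is deliberately
# simple and deterministic: per-group centroid-to-centroid projections,
# rank-transformed and rescaled to [0, 100].

#' Supervised pseudotime along an ordered cluster path
#'
#' Cells belonging to the ordered groups are placed on a \[0, 100\] pseudotime
#' axis. Group centroids are computed in the embedding; each cell in group i
#' is scored by its scalar projection onto the unit vector from centroid i to
#' centroid i+1 (the last group projects onto the incoming direction),
#' expressed as a fraction of the centroid gap and min-max rescaled within
#' the group to \[0, 1\] (rescaling before clipping preserves within-group
#' order). Raw times (i - 1) + s are then rank-transformed
#' over all member cells and rescaled to \[0, 100\]. Cells outside the path are
#' excluded.
#'
#' With a single group the cells are projected onto the group's first
#' principal axis, oriented toward `terminal_cells` when given (otherwise the
#' axis sign is fixed by its largest-magnitude loading).
#'
#' @param embedding Cells x dims matrix, rownames = cell ids.
#' @param cluster_labels Named character vector, cell id -> cluster label.
#' @param ordered_groups Character vector of cluster labels, from root to
#'   terminus.
#' @param terminal_cells Optional cell ids marking the terminus (used only for
#'   the single-group degenerate path).
#' @return A `trajectory` tibble (`cell_id`, `cluster`, `pseudotime`) with
#'   attribute `ordered_groups`.
#' @export
supervised_pseudotime <- function(embedding, cluster_labels, ordered_groups,
                                  terminal_cells = NULL) {
  labels <- cluster_labels[rownames(embedding)]
  missing <- setdiff(ordered_groups, unique(labels))
  if (length(missing)) {
    stop_valid("group(s) %s absent from cluster labels",
               paste(missing, collapse = ", "))
  }
  member <- labels %in% ordered_groups
  emb <- embedding[member, , drop = FALSE]
  labels <- labels[member]
  m <- length(ordered_groups)
  sizes <- table(factor(labels, levels = ordered_groups))
  if (any(sizes < 2)) stop_valid("every group on the path needs >= 2 cells")

  centroids <- t(vapply(ordered_groups,
                        function(g) colMeans(emb[labels == g, , drop = FALSE]),
                        numeric(ncol(emb))))
  raw <- numeric(nrow(emb))
  for (i in seq_len(m)) {
    in_g <- labels == ordered_groups[i]
    X <- emb[in_g, , drop = FALSE]
    if (m == 1) {
      dir <- stats::prcomp(X, center = TRUE, scale. = FALSE)$rotation[, 1]
      if (!is.null(terminal_cells)) {
        term <- intersect(terminal_cells, rownames(X))
        if (length(term)) {
          p_all <- X %*% dir
          if (mean(p_all[term, ]) < mean(p_all)) dir <- -dir
        }
      } else if (dir[which.max(abs(dir))] < 0) {
        dir <- -dir
      }
      gap <- 1
      origin <- centroids[1, ]
    } else if (i < m) {
      seg <- centroids[i + 1, ] - centroids[i, ]
      gap <- sqrt(sum(seg^2))
      dir <- seg / gap
      origin <- centroids[i, ]
    } else {
      seg <- centroids[i, ] - centroids[i - 1, ]
      gap <- sqrt(sum(seg^2))
      dir <- seg / gap
      origin <- centroids[i, ]
    }
    p <- as.numeric(sweep(X, 2, origin) %*% dir) / gap
    # min-max rescale within the group first, then clip: rescaling preserves
    # the within-group ordering that a hard clip of raw projections would
    # collapse into ties
    rng <- range(p)
    s <- if (diff(rng) > 0) (p - rng[1]) / diff(rng) else rep(0.5, length(p))
    s <- pmin(pmax(s, 0), 1)
    # keep s fractionally below 1 so the last cell of group i never ties the
    # first cell of group i+1
    raw[in_g] <- (i - 1) + s * (1 - 1e-9)
  }
  rk <- rank(raw, ties.method = "average")
  pt <- if (length(rk) > 1) (rk - min(rk)) / (max(rk) - min(rk)) * 100 else 0

  out <- tibble::tibble(cell_id = rownames(emb), cluster = labels,
                        pseudotime = pt)
  structure(out, ordered_groups = ordered_groups,
            class = c("trajectory", class(out)))
}

#' Bin and smooth a matrix along a trajectory
#'
#' Cells are assigned to `n_bins` equal-width pseudotime bins on \[0, 100\];
#' each bin value is the mean over its member cells; empty bins are merged
#' into their nearest non-empty neighbor (i.e. dropped, so `bin_centers` stays
#' strictly increasing with no empty bin); finally each row is smoothed by a
#' moving average of `window` bins with truncated windows at the edges.
#'
#' @param mat Features x cells matrix; columns must cover the trajectory's
#'   member cells (matched by colnames).
#' @param trajectory A [supervised_pseudotime()] result.
#' @param n_bins Number of bins (default 100).
#' @param window Moving-average window in bins (default 5).
#' @return A `binned_matrix`: list with `values` (features x kept bins),
#'   `bin_centers`, `n_bins`, `window`.
#' @export
bin_smooth <- function(mat, trajectory, n_bins = 100, window = 5) {
  if (n_bins < 2) stop_valid("n_bins must be >= 2")
  if (!all(trajectory$cell_id %in% colnames(mat))) {
    stop_valid("matrix columns do not cover trajectory cells")
  }
  mat <- mat[, trajectory$cell_id, drop = FALSE]
  breaks <- seq(0, 100, length.out = n_bins + 1)
  bin <- findInterval(trajectory$pseudotime, breaks, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  keep <- which(counts > 0)
  ind <- Matrix::sparseMatrix(i = seq_along(bin), j = bin,
                              x = 1 / counts[bin],
                              dims = c(length(bin), n_bins))
  means <- as.matrix(mat %*% ind[, keep, drop = FALSE])
  centers <- (breaks[-length(breaks)] + breaks[-1])[keep] / 2

  sm <- smooth_rows(means, window)
  rownames(sm) <- rownames(mat)
  structure(list(values = sm, bin_centers = centers,
                 n_bins = n_bins, window = window),
            class = "binned_matrix")
}

# Truncated-window moving average along columns, per row.
smooth_rows <- function(x, window) {
  if (window <= 1) return(x)
  h <- floor(window / 2)
  B <- ncol(x)
  out <- x
  csum <- t(apply(x, 1, cumsum))
  if (B == 1) return(x)
  for (j in seq_len(B)) {
    lo <- max(1, j - h)
    hi <- min(B, j + h)
    left <- if (lo > 1) csum[, lo - 1] else 0
    out[, j] <- (csum[, hi] - left) / (hi - lo + 1)
  }
  out
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf("binned_matrix: %d features x %d bins (of %d; window %d)\n",
              nrow(x$values), ncol(x$values), x$n_bins, x$window))
  invisible(x)
}
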