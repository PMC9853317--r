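# broom-style accessors and ggplot2 views of the pipeline's result objects.

#' Tidy an eGRN into its edge table
#'
#' @param x An `egrn` object.
#' @param ... Unused.
#' @return Tibble of edges (`tf`, `gene`, `weight`, `self_edge`).
#' @method tidy egrn
#' @export
tidy.egrn <- function(x, ...) {
  tibble::as_tibble(x$edges)
}

#' One-row eGRN summary
#'
#' @param x An `egrn` object.
#' @param ... Unused.
#' @return Tibble with `n_edges`, `n_tfs`, `n_genes`, `mean_weight`,
#'   `top_pagerank_tf` (NA until [annotate_egrn()]).
#' @method glance egrn
#' @export
glance.egrn <- function(x, ...) {
  top <- NA_character_
  if (!is.null(x$nodes) && nrow(x$nodes)) {
    tfs <- dplyr::filter(x$nodes, .data$type == "TF")
    if (nrow(tfs)) top <- tfs$node[which.max(tfs$pagerank)]
  }
  tibble::tibble(
    n_edges = nrow(x$edges),
    n_tfs = length(unique(x$edges$tf)),
    n_genes = length(unique(x$edges$gene)),
    mean_weight = if (nrow(x$edges)) mean(x$edges$weight) else NA_real_,
    top_pagerank_tf = top
  )
}

#' @method tidy trajectory
#' @export
tidy.trajectory <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method tidy cell_pairing
#' @export
tidy.cell_pairing <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method glance cell_pairing
#' @export
glance.cell_pairing <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x), total_cost = attr(x, "total_cost"),
                 mean_cost = mean(x$cost))
}

#' Pseudotime distribution per cluster
#'
#' @param object A `trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trajectory
#' @export
autoplot.trajectory <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  df$cluster <- factor(df$cluster, levels = attr(object, "ordered_groups"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pseudotime, fill = .data$cluster)) +
    ggplot2::geom_histogram(bins = 50, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "pseudotime", y = "cells",
                  title = "Supervised pseudotime by cluster") +
    ggplot2::theme_minimal()
}

#' Regulator importance map (pagerank vs betweenness)
#'
#' TF nodes of an annotated eGRN, colored by the pseudotime of peak activity.
#'
#' @param object An annotated `egrn` (see [annotate_egrn()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot egrn
#' @export
autoplot.egrn <- function(object, ...) {
  if (is.null(object$nodes)) {
    rlang::abort("annotate_egrn() the network first")
  }
  df <- dplyr::filter(object$nodes, .data$type == "TF")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pagerank, y = .data$betweenness,
                                   color = .data$peak_time,
                                   label = .data$node)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::scale_color_viridis_c(name = "peak activity\npseudotime") +
    ggplot2::labs(x = "PageRank", y = "betweenness",
                  title = "Regulator importance") +
    ggplot2::theme_minimal()
}

#' TF dynamics along the trajectory
#'
#' Line plot of a TF's binding-activity z profile, its coding gene's
#' expression, and (optionally) the mean expression of its targets — each
#' z-score-scaled across bins.
#'
#' @param tf TF id.
#' @param activity_binned,expression_binned [bin_smooth()] results.
#' @param motifs [motif_matches()] object (TF -> gene map).
#' @param egrn Optional `egrn`; adds the mean target-expression track.
#' @return A ggplot.
#' @export
plot_tf_dynamics <- function(tf, activity_binned, expression_binned, motifs,
                             egrn = NULL) {
  zscale <- function(x) as.numeric(scale(x))
  tracks <- list(activity = zscale(activity_binned$values[tf, ]))
  gene <- motifs$tf_genes[[tf]]
  if (!is.na(gene) && gene %in% rownames(expression_binned$values)) {
    tracks$expression <- zscale(expression_binned$values[gene, ])
  }
  if (!is.null(egrn)) {
    tg <- intersect(egrn$edges$gene[egrn$edges$tf == tf],
                    rownames(expression_binned$values))
    if (length(tg)) {
      tracks$targets <- zscale(colMeans(
        expression_binned$values[tg, , drop = FALSE]))
    }
  }
  df <- purrr::imap_dfr(tracks, function(v, nm) {
    tibble::tibble(pseudotime = activity_binned$bin_centers, track = nm,
                   value = v)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pseudotime, y = .data$value,
                                   color = .data$track)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(title = tf, x = "pseudotime", y = "z-scored value") +
    ggplot2::theme_minimal()
}
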