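# Quantitative GRN (TF activity x gene expression correlations), the 2 kb
# enhancer constraint, assembly of the final enhancer-based GRN, and
# regulator-ranking statistics.

#' Quantitative GRN: TF activity vs gene expression correlations
#'
#' @param activity_binned TF activity [bin_smooth()] result (z-scores).
#' @param expression_binned Gene expression [bin_smooth()] result on the same
#'   trajectory.
#' @param selected_tfs,selected_genes Ids of the TFs/genes to include.
#' @return A `quant_grn` object: list with `r_matrix` (TFs x genes, Pearson
#'   over bins; NA where a profile was constant).
#' @export
quantitative_grn <- function(activity_binned, expression_binned,
                             selected_tfs, selected_genes) {
  stopifnot(length(selected_tfs) > 0, length(selected_genes) > 0,
            identical(activity_binned$bin_centers, expression_binned$bin_centers))
  A <- standardize_rows(activity_binned$values[selected_tfs, , drop = FALSE])
  E <- standardize_rows(expression_binned$values[selected_genes, , drop = FALSE])
  B <- ncol(A)
  R <- tcrossprod(A, E) / (B - 1)
  R[rowSums(A != 0) == 0, ] <- NA_real_
  R[, rowSums(E != 0) == 0] <- NA_real_
  dimnames(R) <- list(selected_tfs, selected_genes)
  structure(list(r_matrix = R), class = "quant_grn")
}

#' Apply the enhancer definition to peak-gene links
#'
#' Enhancers are linked peaks at least `min_tss_distance` bp (default 2000)
#' from the target gene's TSS; links closer than that (promoter-proximal) are
#' removed and the kept links get `is_enhancer = TRUE`.
#'
#' @param links [peak_gene_links()] tibble.
#' @param min_tss_distance Minimum TSS distance in bp (default 2000;
#'   "at least", so a link at exactly 2000 bp is kept).
#' @return Filtered links tibble.
#' @export
enhancer_links <- function(links, min_tss_distance = 2000) {
  out <- dplyr::filter(links, .data$tss_distance >= min_tss_distance)
  out$is_enhancer <- TRUE
  out
}

#' Assemble the enhancer-based GRN
#'
#' A TF -> gene edge is included iff (1) the quantitative-GRN correlation
#' passes `weight_cutoff` (r >= cutoff in positive mode, |r| >= cutoff in
#' absolute mode), (2) the gene has at least one enhancer link, and (3) the
#' TF's motif matches at least one of the gene's linked enhancer peaks. Edge
#' weight is the correlation. TF self-edges (a TF regulating its own coding
#' gene) are permitted and flagged.
#'
#' @param qgrn [quantitative_grn()] result.
#' @param enh_links [enhancer_links()] tibble.
#' @param motifs [motif_matches()] object.
#' @param weight_cutoff Correlation cutoff (default 0.4).
#' @param mode `"positive"` (default) or `"absolute"`.
#' @return An `egrn` object: list with `edges` tibble (`tf`, `gene`, `weight`,
#'   `self_edge`) and `nodes` (NULL until [annotate_egrn()]).
#' @export
assemble_egrn <- function(qgrn, enh_links, motifs, weight_cutoff = 0.4,
                          mode = c("positive", "absolute")) {
  mode <- match.arg(mode)
  R <- qgrn$r_matrix
  M <- motifs$matches
  edges <- tibble::tibble(tf = character(), gene = character(),
                          weight = numeric(), self_edge = logical())
  genes_with_enh <- intersect(colnames(R), unique(enh_links$gene_id))
  if (length(genes_with_enh) && nrow(enh_links)) {
    el <- dplyr::filter(enh_links, .data$gene_id %in% genes_with_enh,
                        .data$peak_id %in% rownames(M))
    if (nrow(el)) {
      # gene x peak incidence of linked enhancers, then gene x TF motif cover
      gidx <- match(el$gene_id, genes_with_enh)
      pidx <- match(el$peak_id, rownames(M))
      inc <- Matrix::sparseMatrix(i = gidx, j = pidx, x = 1,
                                  dims = c(length(genes_with_enh), nrow(M)))
      cover <- (inc %*% M) > 0  # gene x TF: motif in >= 1 linked enhancer
      rownames(cover) <- genes_with_enh
      Rsub <- R[intersect(rownames(R), colnames(M)), genes_with_enh, drop = FALSE]
      score <- if (mode == "absolute") abs(Rsub) else Rsub
      pass <- !is.na(score) & score >= weight_cutoff &
        t(as.matrix(cover[, rownames(Rsub), drop = FALSE]))
      hit <- which(pass, arr.ind = TRUE)
      if (nrow(hit)) {
        tf <- rownames(Rsub)[hit[, 1]]
        gene <- colnames(Rsub)[hit[, 2]]
        edges <- tibble::tibble(
          tf = tf, gene = gene,
          weight = Rsub[hit],
          self_edge = unname(!is.na(motifs$tf_genes[tf]) &
                               motifs$tf_genes[tf] == gene)
        )
        edges <- dplyr::arrange(edges, .data$tf, .data$gene)
      }
    }
  }
  if (nrow(edges) == 0) rlang::warn("assembled eGRN has no edges")
  structure(list(edges = edges, nodes = NULL), class = "egrn")
}

#' PageRank and betweenness for eGRN nodes
#'
#' PageRank is computed by power iteration on the directed graph with edge
#' weights |w| (out-weights row-normalized; dangling nodes teleport
#' uniformly; damping `damping`), iterated until the L1 change is below
#' 1e-10. Betweenness is computed on the directed graph with unit-length
#' edges (unweighted shortest paths) — correlation weights have no natural
#' length interpretation.
#'
#' @param egrn An `egrn` object.
#' @param damping PageRank damping factor (default 0.85).
#' @return Tibble (`node`, `type` TF/gene, `pagerank`, `betweenness`).
#' @export
network_statistics <- function(egrn, damping = 0.85) {
  edges <- egrn$edges
  nodes <- unique(c(edges$tf, edges$gene))
  if (length(nodes) == 0) {
    return(tibble::tibble(node = character(), type = character(),
                          pagerank = numeric(), betweenness = numeric()))
  }
  pr <- pagerank_power(edges$tf, edges$gene, abs(edges$weight), nodes,
                       damping = damping)
  g <- egrn_igraph(egrn)
  btw <- igraph::betweenness(g, directed = TRUE, weights = NA)
  tibble::tibble(
    node = nodes,
    type = ifelse(nodes %in% edges$tf, "TF", "gene"),
    pagerank = unname(pr[nodes]),
    betweenness = unname(btw[nodes])
  )
}

# Power-iteration PageRank with |w| edge weights, row-normalized transition
# matrix, uniform teleport for dangling nodes; stops when L1 change < tol.
pagerank_power <- function(from, to, w, nodes, damping = 0.85, tol = 1e-10,
                           max_iter = 10000) {
  n <- length(nodes)
  A <- Matrix::sparseMatrix(i = match(from, nodes), j = match(to, nodes),
                            x = w, dims = c(n, n))
  out_w <- Matrix::rowSums(A)
  dangling <- out_w == 0
  scale <- ifelse(dangling, 1, out_w)
  P <- Matrix::Diagonal(x = 1 / scale) %*% A
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    xnew <- as.numeric(damping * (Matrix::crossprod(P, x) +
                                    sum(x[dangling]) / n) + (1 - damping) / n)
    if (sum(abs(xnew - x)) < tol) {
      x <- xnew
      break
    }
    x <- xnew
  }
  stats::setNames(x, nodes)
}

#' Pseudotime of peak TF activity
#'
#' For each TF, the bin center at which its smoothed activity profile is
#' maximal; ties (including flat profiles) resolve to the earliest bin, with
#' flat profiles flagged.
#'
#' @param activity_binned TF activity [bin_smooth()] result.
#' @return Tibble (`tf_id`, `peak_time`, `is_flat`).
#' @export
tf_peak_time <- function(activity_binned) {
  v <- activity_binned$values
  idx <- apply(v, 1, which.max)
  flat <- apply(v, 1, function(r) diff(range(r)) == 0)
  tibble::tibble(
    tf_id = rownames(v),
    peak_time = activity_binned$bin_centers[idx],
    is_flat = unname(flat)
  )
}

#' Attach node statistics and peak activity times to an eGRN
#'
#' Convenience wrapper running [network_statistics()] and [tf_peak_time()]
#' and storing the joined table in `egrn$nodes`.
#'
#' @param egrn An `egrn` object.
#' @param activity_binned TF activity [bin_smooth()] result (for peak times;
#'   optional).
#' @param damping PageRank damping (default 0.85).
#' @return The `egrn` with a populated `nodes` tibble.
#' @export
annotate_egrn <- function(egrn, activity_binned = NULL, damping = 0.85) {
  ns <- network_statistics(egrn, damping = damping)
  ns$peak_time <- NA_real_
  if (!is.null(activity_binned)) {
    pt <- tf_peak_time(activity_binned)
    idx <- match(ns$node, pt$tf_id)
    ns$peak_time <- ifelse(ns$type == "TF" & !is.na(idx), pt$peak_time[idx],
                           NA_real_)
  }
  egrn$nodes <- ns
  egrn
}

#' @export
print.egrn <- function(x, ...) {
  cat(sprintf("egrn: %d edges, %d TFs -> %d genes%s\n",
              nrow(x$edges), length(unique(x$edges$tf)),
              length(unique(x$edges$gene)),
              if (is.null(x$nodes)) "" else " (annotated)"))
  invisible(x)
}

#' Precision/recall of an edge set against a reference
#'
#' @param edges Tibble with `tf`, `gene` columns (e.g. `egrn$edges`).
#' @param truth_edges Tibble with `tf`, `gene` reference edges.
#' @return Tibble (`n_edges`, `n_truth`, `recall`, `precision`).
#' @export
edge_metrics <- function(edges, truth_edges) {
  key <- paste(edges$tf, edges$gene)
  tkey <- paste(truth_edges$tf, truth_edges$gene)
  tp <- sum(key %in% tkey)
  tibble::tibble(
    n_edges = length(key),
    n_truth = length(tkey),
    recall = tp / length(tkey),
    precision = if (length(key)) tp / length(key) else NA_real_
  )
}
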