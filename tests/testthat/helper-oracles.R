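# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (loops, enumeration) so they cannot share a defect with
# the vectorized implementations they check.

# ---- fixtures --------------------------------------------------------------

make_counts <- function(nr, nc, prefix_r = "f", prefix_c = "c", lambda = 2,
                        seed = 1) {
  withr::with_seed(seed, {
    m <- Matrix::Matrix(matrix(rpois(nr * nc, lambda), nr, nc), sparse = TRUE)
    dimnames(m) <- list(sprintf("%s%02d", prefix_r, seq_len(nr)),
                        sprintf("%s%02d", prefix_c, seq_len(nc)))
    methods::as(m, "CsparseMatrix")
  })
}

make_peaks <- function(n, chrom = "chr1", width = 500L, gap = 5000L,
                       seed = 1) {
  start <- seq(10000L, by = gap, length.out = n)
  withr::with_seed(seed, tibble::tibble(
    peak_id = sprintf("%s:%d-%d", chrom, start, start + width),
    chrom = chrom, start = start, end = start + width,
    gc = runif(n, 0.3, 0.7)
  ))
}

make_binned <- function(values, ids) {
  rownames(values) <- ids
  structure(list(values = values,
                 bin_centers = seq(0.5, 99.5, length.out = ncol(values)),
                 n_bins = ncol(values), window = 1),
            class = "binned_matrix")
}

# ---- oracles ---------------------------------------------------------------

# all permutations of 1..n
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- all_perms(n)
  min(apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)])))
}

# two-pass Pearson, scalar loop
brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# chromVAR-style deviations via explicit triple loops
brute_deviation_z <- function(X, M, bg_indices) {
  X <- as.matrix(X)
  M <- as.matrix(M)
  n_p <- nrow(X); n_c <- ncol(X); n_k <- ncol(M)
  t_c <- colSums(X)
  a <- rowSums(X) / sum(X)
  dev <- function(Mk) {
    Y <- matrix(NA_real_, n_k, n_c)
    for (k in seq_len(n_k)) {
      for (cc in seq_len(n_c)) {
        O <- 0; Ex <- 0
        for (p in seq_len(n_p)) {
          O <- O + Mk[p, k] * X[p, cc]
          Ex <- Ex + Mk[p, k] * a[p]
        }
        Ex <- t_c[cc] * Ex
        Y[k, cc] <- (O - Ex) / Ex
      }
    }
    Y
  }
  Y <- dev(M)
  n_it <- ncol(bg_indices)
  Yb <- array(NA_real_, c(n_k, n_c, n_it))
  for (b in seq_len(n_it)) {
    Mb <- matrix(0, n_p, n_k)
    for (k in seq_len(n_k)) {
      for (p in which(M[, k] == 1)) {
        q <- bg_indices[p, b]
        Mb[q, k] <- Mb[q, k] + 1
      }
    }
    Yb[, , b] <- dev(Mb)
  }
  mb <- apply(Yb, c(1, 2), mean)
  sb <- apply(Yb, c(1, 2), sd)
  (Y - mb) / sb
}

# directed betweenness by exhaustive simple-path enumeration
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  all_paths <- function(s, t) {
    res <- list()
    rec <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        res[[length(res) + 1]] <<- path
        return(invisible())
      }
      for (w in which(adj[v, ] > 0)) if (!(w %in% path)) rec(c(path, w))
    }
    rec(s)
    res
  }
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      ps <- all_paths(s, t)
      if (!length(ps)) next
      lens <- vapply(ps, length, integer(1))
      sp <- ps[lens == min(lens)]
      for (v in setdiff(seq_len(n), c(s, t))) {
        btw[v] <- btw[v] +
          sum(vapply(sp, function(p) v %in% p, logical(1))) / length(sp)
      }
    }
  }
  btw
}

# eGRN rule check by explicit triple loop over (TF, gene, enhancer)
brute_egrn_edges <- function(r_matrix, enh_links, M, tf_genes, cutoff,
                             mode = "positive") {
  out <- list()
  for (k in rownames(r_matrix)) {
    if (!k %in% colnames(M)) next
    for (g in colnames(r_matrix)) {
      r <- r_matrix[k, g]
      if (is.na(r)) next
      score <- if (mode == "absolute") abs(r) else r
      if (score < cutoff) next
      enh <- enh_links$peak_id[enh_links$gene_id == g]
      if (!length(enh)) next
      bound <- FALSE
      for (p in enh) if (p %in% rownames(M) && M[p, k] == 1) bound <- TRUE
      if (bound) out[[length(out) + 1]] <- tibble::tibble(tf = k, gene = g,
                                                          weight = r)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(tf = character(), gene = character(),
                          weight = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), tf, gene)
}

# mean silhouette width from scratch (Euclidean)
brute_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  sil <- numeric(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(labels) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    sil[i] <- (b - a) / max(a, b)
  }
  mean(sil)
}
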