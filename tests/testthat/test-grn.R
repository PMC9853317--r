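test_that("quantitative GRN equals brute-force Pearson and is bin-order invariant", {
  withr::with_seed(31, {
    B <- 20
    A <- matrix(rnorm(5 * B), 5)
    E <- matrix(rnorm(7 * B), 7)
    E[7, ] <- 2  # constant profile: undefined correlation
    act_b <- make_binned(A, sprintf("TF%d", 1:5))
    expr_b <- make_binned(E, sprintf("g%d", 1:7))
    q <- quantitative_grn(act_b, expr_b, sprintf("TF%d", 1:5),
                          sprintf("g%d", 1:7))
    for (k in 1:5) {
      for (g in 1:6) {
        expect_equal(q$r_matrix[k, g], brute_pearson(A[k, ], E[g, ]),
                     tolerance = 1e-10)
      }
    }
    expect_true(all(is.na(q$r_matrix[, "g7"])))
    expect_true(all(abs(q$r_matrix[, 1:6]) <= 1))

    # identical profiles give correlation 1
    act_id <- make_binned(E[1:2, ], c("TFa", "TFb"))
    q_id <- quantitative_grn(act_id, expr_b, c("TFa", "TFb"), "g1")
    expect_equal(q_id$r_matrix["TFa", "g1"], 1, tolerance = 1e-12)

    # permuting bins identically in both matrices leaves r unchanged
    perm <- sample(B)
    act_p <- make_binned(A[, perm], sprintf("TF%d", 1:5))
    expr_p <- make_binned(E[, perm], sprintf("g%d", 1:7))
    q_p <- quantitative_grn(act_p, expr_p, sprintf("TF%d", 1:5),
                            sprintf("g%d", 1:7))
    expect_equal(q_p$r_matrix, q$r_matrix, tolerance = 1e-12)
  })
})

test_that("the enhancer rule keeps links at exactly the minimum distance", {
  links <- tibble::tibble(
    peak_id = c("a", "b", "c"), chrom = "chr1",
    start = 0L, end = 10L, gene_id = "g",
    r = 0.9, tss_distance = c(1999L, 2000L, 2001L), is_enhancer = NA
  )
  kept <- enhancer_links(links, min_tss_distance = 2000)
  expect_setequal(kept$peak_id, c("b", "c"))
  expect_true(all(kept$is_enhancer))
  expect_equal(nrow(enhancer_links(links, min_tss_distance = 0)), 3)
})

test_that("eGRN assembly applies all three rules", {
  r <- matrix(c(0.9, 0.9, 0.2), 1, 3,
              dimnames = list("TF1", c("g1", "g2", "g3")))
  qgrn <- structure(list(r_matrix = r), class = "quant_grn")
  M <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(3, 1),
                            dimnames = list(c("pA", "pB", "pC"), "TF1"))
  motifs <- motif_matches(M, c(TF1 = "gTF1"))
  enh <- tibble::tibble(
    peak_id = c("pA", "pB", "pC"), chrom = "chr1", start = 0L, end = 10L,
    gene_id = c("g1", "g2", "g3"), r = 0.8,
    tss_distance = 5000L, is_enhancer = TRUE
  )
  egrn <- assemble_egrn(qgrn, enh, motifs, weight_cutoff = 0.4)
  # g1: r ok, motif in its enhancer -> edge; g2: r ok but motif not in pB;
  # g3: motif-free and r below cutoff
  expect_equal(egrn$edges$gene, "g1")
  expect_equal(egrn$edges$weight, 0.9)

  # a gene without any enhancer link never gains an edge
  egrn2 <- assemble_egrn(qgrn, enh[0, ], motifs, weight_cutoff = 0.4) |>
    suppressWarnings()
  expect_equal(nrow(egrn2$edges), 0)
})

test_that("eGRN assembly equals an exhaustive rule check on random instances", {
  withr::with_seed(41, {
    for (rep in 1:8) {
      n_tf <- sample(3:6, 1)
      n_g <- sample(5:15, 1)
      n_p <- sample(10:30, 1)
      tfs <- sprintf("TF%d", seq_len(n_tf))
      gs <- sprintf("g%d", seq_len(n_g))
      ps <- sprintf("p%d", seq_len(n_p))
      r <- matrix(runif(n_tf * n_g, -1, 1), n_tf, dimnames = list(tfs, gs))
      M <- Matrix::Matrix(matrix(rbinom(n_p * n_tf, 1, 0.3), n_p),
                          sparse = TRUE, dimnames = list(ps, tfs))
      motifs <- motif_matches(methods::as(M, "CsparseMatrix"),
                              setNames(paste0("g", seq_len(n_tf)), tfs))
      n_l <- sample(5:20, 1)
      enh <- tibble::tibble(
        peak_id = sample(ps, n_l, replace = TRUE),
        chrom = "chr1", start = 0L, end = 10L,
        gene_id = sample(gs, n_l, replace = TRUE),
        r = runif(n_l, 0.5, 1), tss_distance = 3000L, is_enhancer = TRUE
      )
      qgrn <- structure(list(r_matrix = r), class = "quant_grn")
      for (mode in c("positive", "absolute")) {
        egrn <- suppressWarnings(assemble_egrn(qgrn, enh, motifs,
                                               weight_cutoff = 0.4,
                                               mode = mode))
        oracle <- brute_egrn_edges(r, enh, as.matrix(M), motifs$tf_genes,
                                   0.4, mode)
        expect_equal(egrn$edges[, c("tf", "gene", "weight")], oracle)
      }
    }
  })
})

test_that("network statistics match their contracts and the brute-force oracle", {
  # single isolated node
  pr1 <- egrnet:::pagerank_power(character(), character(), numeric(), "solo")
  expect_equal(unname(pr1), 1)

  # two-node cycle splits pagerank evenly
  egrn_cycle <- structure(list(edges = tibble::tibble(
    tf = c("A", "B"), gene = c("B", "A"), weight = c(0.8, 0.6),
    self_edge = FALSE), nodes = NULL), class = "egrn")
  ns <- network_statistics(egrn_cycle)
  expect_equal(ns$pagerank, c(0.5, 0.5), tolerance = 1e-9)

  withr::with_seed(51, {
    for (rep in 1:20) {
      n <- sample(4:8, 1)
      adj <- matrix(rbinom(n * n, 1, 0.3), n)
      diag(adj) <- 0
      if (sum(adj) == 0) adj[1, 2] <- 1
      # an eGRN has no isolated vertices: restrict to nodes with edges
      used <- sort(unique(as.vector(which(adj == 1, arr.ind = TRUE))))
      adj <- adj[used, used, drop = FALSE]
      n <- length(used)
      idx <- which(adj == 1, arr.ind = TRUE)
      nodes <- sprintf("n%d", seq_len(n))
      w <- runif(nrow(idx), 0.4, 1)
      egrn <- structure(list(edges = tibble::tibble(
        tf = nodes[idx[, 1]], gene = nodes[idx[, 2]], weight = w,
        self_edge = FALSE), nodes = NULL), class = "egrn")
      ns <- network_statistics(egrn)
      expect_equal(sum(ns$pagerank), 1, tolerance = 1e-9)
      oracle <- brute_betweenness(adj)
      expect_equal(ns$betweenness[match(nodes, ns$node)], oracle,
                   tolerance = 1e-9)
      # independent cross-check of the power iteration
      g <- igraph::graph_from_data_frame(
        data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]]),
        vertices = nodes)
      pr_ig <- igraph::page_rank(g, weights = abs(w), damping = 0.85)$vector
      expect_equal(ns$pagerank[match(nodes, ns$node)], unname(pr_ig),
                   tolerance = 1e-6)
    }
  })
})

test_that("TF peak-activity times follow the argmax with earliest-bin ties", {
  withr::with_seed(61, {
    B <- 50
    V <- matrix(rnorm(6 * B), 6)
    V[5, ] <- 1                   # flat
    V[6, ] <- seq_len(B)          # monotone increasing
    ab <- make_binned(V, sprintf("TF%d", 1:6))
    pt <- tf_peak_time(ab)
    for (k in 1:4) {
      expect_equal(pt$peak_time[k], ab$bin_centers[which.max(V[k, ])])
    }
    expect_equal(pt$peak_time[5], ab$bin_centers[1])
    expect_true(pt$is_flat[5])
    expect_equal(pt$peak_time[6], ab$bin_centers[B])
  })
})

test_that("annotated eGRNs expose tidy and glance views", {
  egrn <- structure(list(edges = tibble::tibble(
    tf = c("A", "A"), gene = c("g1", "g2"), weight = c(0.9, 0.7),
    self_edge = FALSE), nodes = NULL), class = "egrn")
  egrn <- annotate_egrn(egrn)
  expect_equal(nrow(tidy(egrn)), 2)
  gl <- glance(egrn)
  expect_equal(gl$n_edges, 2)
  expect_equal(gl$top_pagerank_tf, "A")
  expect_equal(sum(egrn$nodes$pagerank), 1, tolerance = 1e-9)
})
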