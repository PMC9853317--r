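test_that("gene activity sums peak counts over strand-aware gene windows", {
  peaks <- tibble::tibble(
    peak_id = c("chr1:1000-1500", "chr1:3000-3500", "chr1:8000-8200"),
    chrom = "chr1", start = c(1000L, 3000L, 8000L),
    end = c(1500L, 3500L, 8200L), gc = 0.5
  )
  atac <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(1, 1, 2), x = c(7, 2, 4),
                               dims = c(3, 2),
                               dimnames = list(peaks$peak_id, c("c1", "c2")))
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                          strand = "+", tss = c(900L, 3400L),
                          start = c(900L, 3400L), end = c(2000L, 4000L))
  act <- gene_activity_scores(atac, peaks, genes, upstream_bp = 0)
  # peak 1 inside gA body: 7 in c1; peak 2 overlaps both gA? no: gA ends 2000
  expect_equal(act["gA", "c1"], 7)
  expect_equal(act["gB", "c1"], 2)  # peak2 overlaps gB body start

  # a peak overlapping two gene windows counts for both
  genes2 <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                           strand = "+", tss = c(1100L, 1400L),
                           start = c(1100L, 1400L), end = c(1300L, 1600L))
  act2 <- gene_activity_scores(atac, peaks, genes2, upstream_bp = 0)
  expect_equal(act2["gA", "c1"], 7)
  expect_equal(act2["gB", "c1"], 7)

  # brute-force interval overlap over all peak-gene pairs
  up <- 500
  win <- cbind(ifelse(genes$strand == "+", genes$start - up, genes$start),
               ifelse(genes$strand == "+", genes$end, genes$end + up))
  act3 <- gene_activity_scores(atac, peaks, genes, upstream_bp = up)
  for (gi in seq_len(nrow(genes))) {
    for (ci in 1:2) {
      exp_val <- 0
      for (pi in seq_len(nrow(peaks))) {
        if (peaks$start[pi] < win[gi, 2] && peaks$end[pi] > win[gi, 1]) {
          exp_val <- exp_val + atac[pi, ci]
        }
      }
      expect_equal(act3[gi, ci], exp_val)
    }
  }

  # upstream_bp = 0 and peak strictly upstream of TSS contributes nothing
  genes_up <- tibble::tibble(gene_id = "gC", chrom = "chr1", strand = "+",
                             tss = 2000L, start = 2000L, end = 2500L)
  expect_equal(sum(gene_activity_scores(atac, peaks, genes_up,
                                        upstream_bp = 0)["gC", ]), 0)

  # gene chromosome without peaks warns and yields a zero row
  genes_chr <- dplyr::bind_rows(genes,
                                tibble::tibble(gene_id = "gX", chrom = "chrZ",
                                               strand = "+", tss = 10L,
                                               start = 10L, end = 20L))
  expect_warning(actx <- gene_activity_scores(atac, peaks, genes_chr), "chrZ")
  expect_equal(sum(actx["gX", ]), 0)
})

test_that("co-embedding aligns identical modalities and is order-equivariant", {
  rna <- make_counts(60, 40, lambda = 3, seed = 7)
  emb <- joint_embedding(rna, rna, n_dims = 5, n_features = 50)
  # identical inputs: each cell's nearest cross-modality neighbor is itself
  d <- as.matrix(dist(rbind(emb$rna, emb$atac)))
  cross <- d[seq_len(40), 40 + seq_len(40)]
  expect_true(all(apply(cross, 1, which.min) == seq_len(40)))

  perm <- withr::with_seed(2, sample(40))
  emb_p <- joint_embedding(rna[, perm], rna, n_dims = 5, n_features = 50)
  expect_equal(emb_p$rna, emb$rna[perm, ], tolerance = 1e-8)
  expect_equal(emb_p$atac, emb$atac, tolerance = 1e-8)

  expect_error(joint_embedding(rna[1:3, ], rna[1:3, ], n_dims = 5), "shared")
})

test_that("co-embedding separates simulated clusters (positive silhouette)", {
  withr::with_seed(11, {
    n <- 40
    prog <- rbind(cbind(matrix(5, 20, n), matrix(0.5, 20, n)),
                  cbind(matrix(0.5, 20, n), matrix(5, 20, n)))
    labels <- rep(c("A", "B"), each = n)
    rna <- Matrix::Matrix(matrix(rpois(length(prog), prog), nrow(prog)),
                          sparse = TRUE)
    act <- Matrix::Matrix(matrix(rpois(length(prog), prog), nrow(prog)),
                          sparse = TRUE)
    dimnames(rna) <- list(sprintf("g%02d", 1:40), sprintf("r%02d", 1:(2 * n)))
    dimnames(act) <- list(sprintf("g%02d", 1:40), sprintf("a%02d", 1:(2 * n)))
    emb <- joint_embedding(rna, act, n_dims = 4, n_features = 40)
    expect_gt(brute_silhouette(emb$rna, labels), 0)
    expect_gt(brute_silhouette(rbind(emb$rna, emb$atac), c(labels, labels)), 0)
  })
})

test_that("minimum-cost matching is exact and one-to-one", {
  m <- min_cost_matching(matrix(c(0, 5, 5, 0), 2, byrow = TRUE))
  expect_equal(m$total_cost, 0)
  expect_equal(m$pairs[, "col"], c(1, 2))

  withr::with_seed(5, {
    for (i in 1:10) {
      n <- sample(4:6, 1)
      C <- matrix(runif(n * n), n)
      m <- min_cost_matching(C)
      expect_equal(m$total_cost, brute_assignment(C), tolerance = 1e-12)
      expect_equal(anyDuplicated(m$pairs[, "col"]), 0)
    }
  })
})

test_that("pair_cells matches identical embeddings to themselves at zero cost", {
  emb <- withr::with_seed(3, matrix(rnorm(30 * 4), 30))
  emb <- emb / sqrt(rowSums(emb^2))
  rownames(emb) <- sprintf("c%02d", 1:30)
  e2 <- emb
  rownames(e2) <- sprintf("d%02d", 1:30)
  p <- pair_cells(emb, e2, k_candidates = 5)
  expect_equal(substring(p$rna_cell, 2), substring(p$atac_cell, 2))
  expect_lt(attr(p, "total_cost"), 1e-6)
  expect_equal(nrow(p), 30)
  expect_equal(anyDuplicated(p$atac_cell), 0)
})

test_that("restricted matching beats random permutations", {
  withr::with_seed(9, {
    emb_r <- matrix(rnorm(50 * 5), 50)
    emb_a <- matrix(rnorm(50 * 5), 50)
    rownames(emb_r) <- sprintf("r%02d", 1:50)
    rownames(emb_a) <- sprintf("a%02d", 1:50)
    p <- pair_cells(emb_r, emb_a, k_candidates = 10)
    cost <- as.matrix(dist(rbind(emb_r, emb_a)))[1:50, 51:100]
    rand <- replicate(1000, sum(cost[cbind(1:50, sample(50))]))
    expect_lte(attr(p, "total_cost"), min(rand))
  })
})

test_that("pairing evaluation matches analytic expectations", {
  truth <- tibble::tibble(rna_cell = sprintf("r%d", 1:8),
                          atac_cell = sprintf("a%d", 1:8))
  labels <- setNames(rep(c("A", "B"), each = 8),
                     c(sprintf("r%d", 1:4), sprintf("a%d", 1:4),
                       sprintf("r%d", 5:8), sprintf("a%d", 5:8)))
  ev <- evaluate_pairing(truth, truth, labels)
  expect_equal(ev$exact_pair_recovery, 8)
  expect_equal(ev$celltype_accuracy, 1)

  crossed <- tibble::tibble(rna_cell = sprintf("r%d", 1:4),
                            atac_cell = sprintf("a%d", 5:8))
  expect_equal(evaluate_pairing(crossed, truth, labels)$celltype_accuracy, 0)

  # random matching on balanced 4-cluster data: expected accuracy 1/4
  withr::with_seed(21, {
    n <- 4000
    lbl <- rep(paste0("K", 1:4), each = n / 4)
    labels2 <- setNames(c(lbl, lbl), c(sprintf("r%d", 1:n), sprintf("a%d", 1:n)))
    rand <- tibble::tibble(rna_cell = sprintf("r%d", 1:n),
                           atac_cell = sprintf("a%d", sample(n)))
    acc <- evaluate_pairing(rand, rand[0, ], labels2)$celltype_accuracy
    expect_lt(abs(acc - 0.25), 0.03)
  })
})
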