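test_that("TF selection follows the activity-expression correlation", {
  B <- 30
  prof <- sin(seq(0, pi, length.out = B))
  act <- make_binned(rbind(prof, -prof, prof + 0.01 * seq_len(B)),
                     c("TFup", "TFdown", "TFnear"))
  expr <- make_binned(rbind(prof, prof, prof), c("gUp", "gDown", "gNear"))
  motifs <- motif_matches(
    Matrix::sparseMatrix(i = 1:3, j = 1:3, x = 1, dims = c(3, 3),
                         dimnames = list(c("p1", "p2", "p3"),
                                         c("TFup", "TFdown", "TFnear"))),
    c(TFup = "gUp", TFdown = "gDown", TFnear = "gMissing"))

  expect_message(sel <- select_tfs(act, expr, motifs, cor_cutoff = 0.4),
                 "TFnear")
  expect_equal(nrow(sel), 2)
  expect_equal(sel$r[sel$tf_id == "TFup"], 1, tolerance = 1e-12)
  expect_true(sel$selected[sel$tf_id == "TFup"])
  expect_equal(sel$r[sel$tf_id == "TFdown"], -1, tolerance = 1e-12)
  expect_false(sel$selected[sel$tf_id == "TFdown"])

  sel_abs <- suppressMessages(select_tfs(act, expr, motifs, cor_cutoff = 0.4,
                                         mode = "absolute"))
  expect_true(all(sel_abs$selected))
})

test_that("planted driver TFs are selected and shuffled decoys are not", {
  withr::with_seed(17, {
    sim <- simulate_multiome(sim_config(n_cells = 500, n_tfs = 6,
                                        n_target_genes = 30,
                                        n_decoy_genes = 30, seed = 17))
    emb <- pca_embedding(sim$rna)
    labels <- setNames(sim$cells$cluster, sim$cells$cell_id)
    tr <- supervised_pseudotime(emb, labels, paste0("C", 1:4))
    bg <- background_peaks(sim$peaks, Matrix::rowMeans(sim$atac),
                           n_neighbors = 50, n_iterations = 20, seed = 17)
    act <- deviation_zscores(sim$atac, sim$motifs, bg)
    act_b <- bin_smooth(act$z, tr)
    expr_b <- bin_smooth(log_normalize(sim$rna), tr)
    sel <- select_tfs(act_b, expr_b, sim$motifs, cor_cutoff = 0.4)
    expect_true(all(sel$selected))

    # decoy TFs: shuffle each activity profile; >= 90% must drop out
    shuf <- act_b
    shuf$values <- t(apply(act_b$values, 1, sample))
    rownames(shuf$values) <- rownames(act_b$values)
    sel_decoy <- select_tfs(shuf, expr_b, sim$motifs, cor_cutoff = 0.4)
    expect_gte(mean(!sel_decoy$selected), 0.9)
  })
})

test_that("variable-gene selection returns exactly ceil(q * N), deterministically", {
  withr::with_seed(3, {
    N <- 157
    vals <- matrix(rnorm(N * 20), N)
    vals[1:5, ] <- 7  # constant genes: zero variance
    ids <- sprintf("g%03d", seq_len(N))
    eb <- make_binned(vals, ids)
    for (q in c(0.01, 0.1, 0.33, 1)) {
      expect_length(select_variable_genes(eb, q), ceiling(q * N))
    }
    expect_false(any(ids[1:5] %in% select_variable_genes(eb, 0.5)))

    # deterministic tie-break on equal variances
    tie <- make_binned(rbind(c(1, 2, 1, 2), c(2, 1, 2, 1), c(0, 0, 0, 0)),
                       c("zB", "zA", "zC"))
    expect_equal(select_variable_genes(tie, 0.5), c("zA", "zB"))
  })
})

test_that("peak-gene links respect the distance window and correlation cutoff", {
  B <- 25
  prof <- cos(seq(0, 2 * pi, length.out = B))
  peaks <- tibble::tibble(
    peak_id = c("chr1:10000-10500", "chr1:260001-260501", "chr1:50000-50500"),
    chrom = "chr1",
    start = c(10000L, 260001L, 50000L),
    end = c(10500L, 260501L, 50500L),
    gc = 0.5
  )
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                          strand = "+", tss = c(0L, 0L))
  atac_b <- make_binned(rbind(prof, prof, -prof), peaks$peak_id)
  expr_b <- make_binned(rbind(prof, prof), genes$gene_id)

  links <- peak_gene_links(atac_b, expr_b, peaks, genes,
                           max_distance = 250000, cor_cutoff = 0.5)
  # peak 2 sits at distance 260001 - 1 + ... beyond the window: never a candidate
  expect_false("chr1:260001-260501" %in% links$peak_id)
  # peak 3 anti-correlates: filtered by the cutoff
  expect_false("chr1:50000-50500" %in% links$peak_id)
  # peak 1 correlates perfectly with both genes at distance 10000
  expect_equal(sum(links$peak_id == "chr1:10000-10500"), 2)
  expect_equal(links$r, rep(1, 2), tolerance = 1e-12)
  expect_equal(unique(links$tss_distance), 10000L)

  # boundary: a peak at exactly max_distance is a candidate; +1 bp is not
  peaks_b <- tibble::tibble(
    peak_id = c("chr1:250000-250500", "chr1:250001-250501"),
    chrom = "chr1", start = c(250000L, 250001L), end = c(250500L, 250501L),
    gc = 0.5
  )
  atac_b2 <- make_binned(rbind(prof, prof), peaks_b$peak_id)
  links_b <- peak_gene_links(atac_b2, expr_b, peaks_b, genes,
                             max_distance = 250000, cor_cutoff = 0.5)
  expect_true("chr1:250000-250500" %in% links_b$peak_id)
  expect_false("chr1:250001-250501" %in% links_b$peak_id)
})

test_that("link correlations equal brute-force two-pass Pearson", {
  withr::with_seed(23, {
    B <- 40
    n_p <- 6
    peaks <- make_peaks(n_p)
    genes <- tibble::tibble(gene_id = sprintf("g%d", 1:4), chrom = "chr1",
                            strand = "+",
                            tss = as.integer(seq(12000, 40000, length.out = 4)))
    A <- matrix(rnorm(n_p * B), n_p)
    E <- matrix(rnorm(4 * B), 4)
    atac_b <- make_binned(A, peaks$peak_id)
    expr_b <- make_binned(E, genes$gene_id)
    links <- peak_gene_links(atac_b, expr_b, peaks, genes,
                             max_distance = 1e6, cor_cutoff = -1)
    for (i in seq_len(nrow(links))) {
      expect_equal(links$r[i],
                   brute_pearson(A[match(links$peak_id[i], peaks$peak_id), ],
                                 E[match(links$gene_id[i], genes$gene_id), ]),
                   tolerance = 1e-10)
    }
    # every link satisfies its own postconditions
    expect_true(all(links$tss_distance <= 1e6))
    expect_true(all(links$r >= -1))
  })
})

test_that("planted enhancer-gene couplings are recovered along the trajectory", {
  withr::with_seed(19, {
    sim <- simulate_multiome(sim_config(n_cells = 600, n_tfs = 5,
                                        n_target_genes = 40,
                                        n_decoy_genes = 40, seed = 19))
    emb <- pca_embedding(sim$rna)
    labels <- setNames(sim$cells$cluster, sim$cells$cell_id)
    tr <- supervised_pseudotime(emb, labels, paste0("C", 1:4))
    atac_b <- bin_smooth(log_normalize(sim$atac), tr)
    expr_b <- bin_smooth(log_normalize(sim$rna), tr)
    dyn_genes <- dplyr::filter(sim$genes, !grepl("^DG", .data$gene_id))
    links <- peak_gene_links(atac_b, expr_b, sim$peaks, dyn_genes)
    key <- paste(links$peak_id, links$gene_id)
    tkey <- paste(sim$truth$planted_links$peak_id,
                  sim$truth$planted_links$gene_id)
    recall <- mean(tkey %in% key)
    expect_gte(recall, 0.8)

    # planted links correlate more strongly than decoy peak-gene pairs
    decoy_r <- links$r[!(key %in% tkey)]
    planted_r <- links$r[key %in% tkey]
    if (length(decoy_r)) {
      expect_gt(median(planted_r), median(decoy_r))
    }
  })
})
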