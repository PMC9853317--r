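# Pipeline orchestration: a single nested config (YAML on disk) drives
# simulate -> integrate -> trajectory -> activity -> select/link -> grn ->
# export, with per-stage logging into a MANIFEST and all randomness flowing
# from one root seed.

sim_defaults <- function() {
  lapply(formals(sim_config), function(x) if (is.language(x)) eval(x) else x)
}

#' Default pipeline configuration
#'
#' Every tunable of every stage, at its documented default. `activity$seed`
#' and `simulate$seed` default to NULL, meaning they inherit the root `seed`.
#'
#' @return Nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1,
    paired = TRUE,
    io = list(rna_mtx = NULL, rna_features = NULL, rna_barcodes = NULL,
              atac_mtx = NULL, atac_features = NULL, atac_barcodes = NULL,
              peaks_bed = NULL, genes_tsv = NULL, motif_mtx = NULL,
              motif_tfs = NULL, cells_tsv = NULL, out_dir = NULL),
    simulate = c(list(enabled = FALSE), within(sim_defaults(), rm(paired, seed))),
    integration = list(k_candidates = 10, n_dims = 20, n_features = 2000,
                       upstream_bp = 1e5),
    trajectory = list(groups = NULL, n_bins = 100, window = 5),
    activity = list(n_iterations = 50, n_neighbors = 50, seed = NULL),
    linking = list(tf_cor_cutoff = 0.4, tf_cor_mode = "positive",
                   link_cor_cutoff = 0.5, max_distance = 250000,
                   top_fraction = 0.1),
    grn = list(weight_cutoff = 0.4, weight_mode = "positive",
               min_tss_distance = 2000, damping = 0.85)
  ), class = "pipeline_config")
}

#' Build a pipeline configuration
#'
#' Merges user overrides into [default_config()], rejecting unknown keys at
#' any nesting level.
#'
#' @param ... Named top-level sections or scalars (e.g. `seed = 7`,
#'   `linking = list(top_fraction = 0.2)`).
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  merge_config(default_config(), list(...))
}

merge_config <- function(base, user, path = "") {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    stop_valid("unknown config key(s): %s",
               paste0(path, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], as.list(user[[k]]),
                                path = paste0(path, k, "."))
    } else {
      base[k] <- list(user[[k]])  # preserves deliberate NULLs
    }
  }
  base
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file.
#' @return For `read_pipeline_config`, a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config_from_list(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_pipeline_config
#' @param x Plain nested list of overrides.
#' @export
pipeline_config_from_list <- function(x) {
  merge_config(default_config(), x)
}

#' Run the full eGRN inference pipeline
#'
#' Stages: (optional) simulate -> integrate + pair (skipped for paired data)
#' -> supervised pseudotime -> TF motif-deviation activity -> binning ->
#' TF/gene selection and peak-gene linking -> enhancer-constrained GRN
#' assembly -> statistics and export. Each stage appends a MANIFEST row
#' (stage, status, parameters, input hash, output size); on failure the
#' MANIFEST marks the failed stage before the error propagates.
#'
#' @param config A [pipeline_config()] (or plain list of overrides).
#' @param data Optional in-memory [simulate_multiome()] object (bypasses file
#'   input and the simulate stage).
#' @param pairing Optional precomputed pairing tibble (`rna_cell`,
#'   `atac_cell`), e.g. ground-truth pairs; skips co-embedding/matching.
#' @param out_dir Output directory for artifacts; default `config$io$out_dir`;
#'   NULL keeps everything in memory.
#' @return An `egrn_pipeline` list: `egrn`, `qgrn`, `trajectory`, `pairing`,
#'   `activity`, `binned` (activity/expression/accessibility), `tf_selection`,
#'   `variable_genes`, `links`, `enh_links`, `manifest`, `config`, `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), data = NULL,
                         pairing = NULL, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    config <- pipeline_config_from_list(config)
  }
  out_dir <- out_dir %||% config$io$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- tibble::tibble(stage = character(), status = character(),
                             detail = character(), input_hash = character())
  log_stage <- function(stage, status, detail, hash = "") {
    manifest <<- dplyr::bind_rows(manifest, tibble::tibble(
      stage = stage, status = status, detail = detail, input_hash = hash))
    if (!is.null(out_dir)) {
      readr::write_tsv(manifest, file.path(out_dir, "MANIFEST.tsv"))
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_stage(name, "failed", conditionMessage(e))
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)), parent = e)
    })
  }

  # --- input ---------------------------------------------------------------
  d <- stage("input", {
    if (is.null(data)) {
      if (isTRUE(config$simulate$enabled)) {
        sim_args <- within(config$simulate, rm(enabled))
        sim_args$paired <- config$paired
        sim_args$seed <- config$seed
        data <- simulate_multiome(do.call(sim_config, sim_args))
      } else {
        io <- config$io
        peaks <- read_peaks_bed(io$peaks_bed)
        data <- list(
          rna = read_count_matrix(io$rna_mtx, io$rna_features, io$rna_barcodes),
          atac = read_count_matrix(io$atac_mtx, io$atac_features, io$atac_barcodes),
          peaks = peaks,
          genes = read_gene_annotations(io$genes_tsv),
          motifs = read_motif_matches(io$motif_mtx, io$motif_tfs, peaks$peak_id),
          cells = read_cell_table(io$cells_tsv)
        )
      }
    }
    data
  })
  log_stage("input", "ok",
            sprintf("rna %dx%d; atac %dx%d", nrow(d$rna), ncol(d$rna),
                    nrow(d$atac), ncol(d$atac)),
            rlang::hash(list(dim(d$rna), dim(d$atac))))

  paired <- all(d$cells$modality == "PAIRED")
  clusters <- stats::setNames(d$cells$cluster, d$cells$cell_id)

  # --- integration / pairing ----------------------------------------------
  emb_for_traj <- NULL
  if (paired) {
    log_stage("integrate", "skipped", "paired protocol; integration bypassed")
    rna_p <- d$rna
    atac_p <- d$atac
    labels <- clusters[colnames(rna_p)]
  } else {
    res <- stage("integrate", {
      if (is.null(pairing)) {
        act <- gene_activity_scores(d$atac, d$peaks, d$genes,
                                    upstream_bp = config$integration$upstream_bp)
        emb <- joint_embedding(d$rna, act,
                               n_dims = config$integration$n_dims,
                               n_features = config$integration$n_features)
        pairing <- pair_cells(emb$rna, emb$atac,
                              k_candidates = config$integration$k_candidates)
      } else {
        emb <- NULL
      }
      list(pairing = pairing, emb = emb)
    })
    pairing <- res$pairing
    # pseudo-multimodal dataset keyed by the RNA cell of each pair
    rna_p <- d$rna[, pairing$rna_cell, drop = FALSE]
    atac_p <- d$atac[, pairing$atac_cell, drop = FALSE]
    colnames(atac_p) <- pairing$rna_cell
    labels <- clusters[colnames(rna_p)]
    if (!is.null(res$emb)) {
      emb_for_traj <- res$emb$rna[pairing$rna_cell, , drop = FALSE]
    }
    log_stage("integrate", "ok", sprintf("%d pairs", nrow(pairing)),
              rlang::hash(pairing))
    if (!is.null(out_dir)) {
      readr::write_tsv(pairing, file.path(out_dir, "pairing.tsv"))
    }
  }

  # --- trajectory ----------------------------------------------------------
  traj <- stage("trajectory", {
    if (is.null(emb_for_traj)) {
      emb_for_traj <- pca_embedding(rna_p,
                                    n_dims = config$integration$n_dims,
                                    n_features = config$integration$n_features)
    }
    groups <- config$trajectory$groups %||% sort(unique(labels))
    supervised_pseudotime(emb_for_traj, labels, groups)
  })
  log_stage("trajectory", "ok", sprintf("%d cells on path", nrow(traj)),
            rlang::hash(traj$pseudotime))
  if (!is.null(out_dir)) {
    readr::write_tsv(traj, file.path(out_dir, "trajectory.tsv"))
  }

  # --- TF activity ---------------------------------------------------------
  act <- stage("activity", {
    bg <- background_peaks(d$peaks, Matrix::rowMeans(atac_p),
                           n_neighbors = config$activity$n_neighbors,
                           n_iterations = config$activity$n_iterations,
                           seed = config$activity$seed %||% config$seed)
    deviation_zscores(atac_p, d$motifs, bg)
  })
  log_stage("activity", "ok",
            sprintf("%d TFs scored, %d dropped", nrow(act$z), nrow(act$dropped)),
            rlang::hash(dim(act$z)))

  # --- binning -------------------------------------------------------------
  binned <- stage("binning", {
    z <- act$z
    bad <- rowSums(is.na(z)) > 0
    if (any(bad)) {
      rlang::inform(sprintf("excluding %d TF(s) with undefined z-scores from binning",
                            sum(bad)))
      z <- z[!bad, , drop = FALSE]
    }
    nb <- config$trajectory$n_bins
    wd <- config$trajectory$window
    list(
      activity = bin_smooth(z, traj, n_bins = nb, window = wd),
      expression = bin_smooth(log_normalize(rna_p), traj, n_bins = nb, window = wd),
      accessibility = bin_smooth(log_normalize(atac_p), traj, n_bins = nb,
                                 window = wd)
    )
  })
  log_stage("binning", "ok",
            sprintf("%d bins", length(binned$expression$bin_centers)),
            rlang::hash(binned$expression$bin_centers))

  # --- selection and linking -----------------------------------------------
  link_res <- stage("link", {
    sel <- select_tfs(binned$activity, binned$expression, d$motifs,
                      cor_cutoff = config$linking$tf_cor_cutoff,
                      mode = config$linking$tf_cor_mode)
    vg <- select_variable_genes(binned$expression,
                                top_fraction = config$linking$top_fraction)
    links <- peak_gene_links(binned$accessibility, binned$expression, d$peaks,
                             dplyr::filter(d$genes, .data$gene_id %in% vg),
                             max_distance = config$linking$max_distance,
                             cor_cutoff = config$linking$link_cor_cutoff)
    list(sel = sel, vg = vg, links = links)
  })
  log_stage("link", "ok",
            sprintf("%d TFs selected; %d genes; %d links",
                    sum(link_res$sel$selected), length(link_res$vg),
                    nrow(link_res$links)),
            rlang::hash(link_res$links$r))
  if (!is.null(out_dir)) {
    readr::write_tsv(link_res$sel, file.path(out_dir, "tf_selection.tsv"))
    readr::write_tsv(link_res$links, file.path(out_dir, "links.tsv"))
  }

  # --- GRN assembly --------------------------------------------------------
  grn_res <- stage("grn", {
    enh <- enhancer_links(link_res$links,
                          min_tss_distance = config$grn$min_tss_distance)
    sel_ids <- link_res$sel$tf_id[link_res$sel$selected]
    if (length(sel_ids) == 0 || length(link_res$vg) == 0) {
      rlang::warn("no selected TFs or genes; eGRN is empty")
      egrn <- structure(list(edges = tibble::tibble(
        tf = character(), gene = character(), weight = numeric(),
        self_edge = logical()), nodes = NULL), class = "egrn")
      qgrn <- NULL
    } else {
      qgrn <- quantitative_grn(binned$activity, binned$expression,
                               sel_ids, link_res$vg)
      egrn <- assemble_egrn(qgrn, enh, d$motifs,
                            weight_cutoff = config$grn$weight_cutoff,
                            mode = config$grn$weight_mode)
    }
    egrn <- annotate_egrn(egrn, binned$activity, damping = config$grn$damping)
    list(enh = enh, qgrn = qgrn, egrn = egrn)
  })
  log_stage("grn", "ok", sprintf("%d edges", nrow(grn_res$egrn$edges)),
            rlang::hash(grn_res$egrn$edges))
  if (!is.null(out_dir)) {
    write_grn(grn_res$egrn,
              edgelist_path = file.path(out_dir, "egrn_edges.tsv"),
              graphml_path = file.path(out_dir, "egrn.graphml"))
    readr::write_tsv(grn_res$egrn$nodes, file.path(out_dir, "egrn_nodes.tsv"))
  }

  structure(list(
    egrn = grn_res$egrn, qgrn = grn_res$qgrn, enh_links = grn_res$enh,
    links = link_res$links, tf_selection = link_res$sel,
    variable_genes = link_res$vg, binned = binned, activity = act,
    trajectory = traj, pairing = if (paired) NULL else pairing,
    data = d, manifest = manifest, config = config, out_dir = out_dir
  ), class = "egrn_pipeline")
}

#' @export
print.egrn_pipeline <- function(x, ...) {
  cat(sprintf("egrn_pipeline: %d cells, %d TFs selected, %d genes, %d eGRN edges\n",
              nrow(x$trajectory), sum(x$tf_selection$selected),
              length(x$variable_genes), nrow(x$egrn$edges)))
  invisible(x)
}
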