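#' Default end-to-end pipeline configuration
#'
#' Bundles the simulation configuration with every stage parameter at its
#' standard value (5 kb windows, k = 15 KNN, Louvain resolution 1, cluster
#' floor 50 cells, 5% high-quality peak fraction, Jensen-Shannon top-N,
#' 1,000 overlap permutations, 50 x 20 pseudo-bulk panel, 10-fold CV,
#' aggregation k = 30, 500 kb windows with 250 kb constraint, edge cutoff
#' 0.1, 10,000 bootstrap replicates) and a single global seed from which
#' every stochastic stage derives its own stream.
#'
#' @param seed Global integer seed.
#' @param sim A [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param ... Overrides for individual stage parameters.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = NULL, ...) {
  cfg <- list(
    seed = seed,
    sim = sim %||% sim_config(seed = seed),
    window = 5000, lsi_d = 40, knn_k = 15, resolution = 1, min_cells = 50,
    hq_frac = 0.05, n_variable = 50000, top_specific = 20000,
    n_perm = 1000, cells_per_rep = 50, panel_reps = 20, cv_folds = 10,
    agg_k = 30, coaccess_window = 5e5, coaccess_constraint = 2.5e5,
    penalty_scale = 0.2, edge_cutoff = 0.1, bootstrap_reps = 10000
  )
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the cell-of-origin tracing pipeline end to end
#'
#' Stages run in dependency order on fully synthetic inputs: simulate ->
#' barcode QC -> LSA clustering -> peak specificity -> origin mapping
#' (correlation + similarity) -> co-accessibility / gene activity ->
#' origin-derived features -> bulk subgrouping -> label-enrichment test.
#' Each stage writes its outputs under `outdir` once and is skipped on
#' re-run if its outputs already exist (write-once resume); a manifest JSON
#' records parameters, seeds, and md5 checksums of every output file.
#'
#' @param config A [pipeline_config()].
#' @param outdir Run directory (created if missing).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the in-memory results of each stage and
#'   the manifest path.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("run_"),
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  res <- list(outdir = outdir)
  done <- function(...) all(file.exists(file.path(outdir, c(...))))

  genome <- toy_genome(seed = config$seed)

  ## --- simulate ---------------------------------------------------------
  say("stage: simulate")
  sim <- simulate_fragments(genome, config$sim)
  pk <- simulate_peak_matrix(genome, config$sim)
  tum <- simulate_bulk_tumors(pk, config$sim, genome)
  expr <- simulate_expression(config$sim)
  if (!done("fragments.tsv")) {
    write_fragments(sim$fragments, file.path(outdir, "fragments.tsv"))
    write_bed(pk$peaks, file.path(outdir, "peaks.bed"))
    write_mtx(pk$counts, file.path(outdir, "peak_matrix"))
    utils::write.table(sim$barcodes, file.path(outdir, "barcode_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res$sim <- sim; res$peak_sim <- pk; res$tumors <- tum; res$expr <- expr

  ## --- barcode QC -------------------------------------------------------
  say("stage: qc")
  qc <- barcode_qc_table(sim$fragments, genome)
  cutoffs <- fit_qc_cutoffs(qc, seed = stage_seed(config$seed, "qc"))
  filt <- filter_barcodes(qc, cutoffs)
  if (!done("qc_table.tsv")) {
    utils::write.table(qc, file.path(outdir, "qc_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(thresholds = lapply(cutoffs, function(x) x$threshold),
           provenance = lapply(cutoffs, function(x) x$provenance),
           n_retained = length(filt$retained),
           n_failed = as.list(filt$n_failed)),
      file.path(outdir, "qc_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  res$qc <- qc; res$cutoffs <- cutoffs; res$retained <- filt$retained

  ## --- clustering -------------------------------------------------------
  say("stage: cluster")
  frags_kept <- sim$fragments[sim$fragments$barcode %in% filt$retained, ]
  clus <- lsa_cluster_cells(frags_kept, genome, window = config$window,
                            d = config$lsi_d, k = config$knn_k,
                            resolution = config$resolution,
                            min_cells = config$min_cells,
                            seed = stage_seed(config$seed, "louvain"))
  if (!done("clusters.tsv")) {
    utils::write.table(
      data.frame(barcode = names(clus$clusters), cluster = clus$clusters),
      file.path(outdir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  res$clusters <- clus$clusters

  ## --- peak specificity (on the simulated peak matrix + true types) -----
  say("stage: peaks")
  hq <- select_high_quality_peaks(pk$counts, pk$cell_types,
                                  min_frac = config$hq_frac)
  pr <- proportion_matrix(pk$counts[hq, , drop = FALSE], pk$cell_types)
  varpk <- select_variable_peaks(pr, n = config$n_variable)
  spec <- js_specificity(pr, peaks = varpk)
  specific <- select_specific_peaks(spec, top_n = config$top_specific)
  if (!done("specific_peaks.tsv")) {
    utils::write.table(specific, file.path(outdir, "specific_peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res$specific <- specific

  ## --- origin mapping ---------------------------------------------------
  say("stage: map-origin")
  shared <- intersect(rownames(tum$counts), hq)
  tum_norm <- quantile_normalize(logcpm_normalize(tum$counts[shared, ]))
  types <- sort(unique(pk$cell_types))
  prof <- vapply(types, function(t) {
    Matrix::rowSums(pk$counts[shared, pk$cell_types == t, drop = FALSE])
  }, numeric(length(shared)))
  prof_norm <- quantile_normalize(logcpm_normalize(prof))
  cor_res <- correlate_samples_celltypes(tum_norm, prof_norm,
                                         intersect(varpk, shared))
  panel <- build_pseudobulk_panel(pk$counts[shared, ], pk$cell_types,
                                  cells_per_rep = config$cells_per_rep,
                                  reps = config$panel_reps,
                                  seed = stage_seed(config$seed, "panel"))
  feats <- intersect(specific$peak, shared)
  fracs <- table(pk$cell_types) / length(pk$cell_types)
  models <- train_similarity_models(panel$panel, panel$labels, feats,
                                    cell_fractions = as.list(fracs),
                                    nfolds = config$cv_folds,
                                    seed = stage_seed(config$seed, "simmod"))
  simil <- predict_similarity(models, tum_norm)
  if (!done("similarity.tsv")) {
    utils::write.table(as.data.frame(simil$scores),
                       file.path(outdir, "similarity.tsv"), sep = "\t",
                       quote = FALSE)
    utils::write.table(as.data.frame(cor_res$group_cor),
                       file.path(outdir, "correlation.tsv"), sep = "\t",
                       quote = FALSE)
  }
  res$correlation <- cor_res; res$similarity <- simil

  ## --- co-accessibility + gene activity ---------------------------------
  say("stage: network")
  keep_cells <- colnames(pk$counts)
  sub <- pk$counts[hq, keep_cells]
  gb <- genebody_accessibility(sub, pk$peaks, genome)
  pr_mat <- log_tfidf(methods::as(Matrix::Matrix(gb$mat > 0, sparse = TRUE),
                                  "dMatrix"))
  red <- lsa_reduce(pr_mat, d = min(20, min(dim(pr_mat)) - 1))
  agg <- aggregate_cells(gb$mat, red$embedding, k = config$agg_k,
                         seed = stage_seed(config$seed, "aggregate"))
  net <- coaccessibility(agg, gb$nodes[match(rownames(gb$mat),
                                             gb$nodes$id), ],
                         window = config$coaccess_window,
                         constraint = config$coaccess_constraint,
                         penalty_scale = config$penalty_scale,
                         cutoff = config$edge_cutoff)
  act <- gene_activity(net, gb$mat, gb$nodes)
  if (!done("coaccess_edges.tsv")) {
    utils::write.table(net$edges, file.path(outdir, "coaccess_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_mtx(act, file.path(outdir, "gene_activity"))
  }
  res$network <- net; res$activity <- act

  ## --- features + subgrouping + enrichment ------------------------------
  say("stage: features/subtype/test-enrichment")
  labels <- subgroup_bulk_samples(expr$expr, expr$markers)
  host <- paste0(config$sim$cimp_host, "_Like")
  n_sub <- sum(labels == host)
  obs <- sum(expr$samples$cimp[labels[expr$samples$sample] == host])
  enr <- cimp_bootstrap_test(N = config$sim$n_expr_samples, n = n_sub,
                             m = config$sim$n_cimp, observed = obs,
                             reps = config$bootstrap_reps,
                             seed = stage_seed(config$seed, "bootstrap"))
  if (!done("enrichment.json")) {
    utils::write.table(data.frame(sample = names(labels), label = labels),
                       file.path(outdir, "sample_labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(enr), file.path(outdir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res$subgroups <- labels; res$enrichment <- enr

  ## --- manifest ---------------------------------------------------------
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    seed = config$seed,
    parameters = config[setdiff(names(config), c("sim", "seed"))],
    sim = unclass(config$sim),
    checksums = as.list(tools::md5sum(file.path(outdir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  res$manifest <- file.path(outdir, "manifest.json")
  invisible(res)
}
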