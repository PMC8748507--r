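# Shared simulations, computed lazily once per test run. Sizes are chosen so
# the whole suite stays desk-scale while keeping the planted signals at the
# generator defaults.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, make(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# fragment-level simulation used by QC tests: genuine cells vs background
fx_qc <- function() fixture("qc", function() {
  genome <- toy_genome(seed = 1)
  config <- sim_config(seed = 101,
                       cells_per_type = c(type1 = 60, type2 = 60, type3 = 60),
                       n_background = 90)
  sim <- simulate_fragments(genome, config)
  qc <- barcode_qc_table(sim$fragments, genome)
  list(genome = genome, config = config, sim = sim, qc = qc)
})

# peak-by-cell simulation with default planted structure
fx_peaks <- function() fixture("peaks", function() {
  genome <- toy_genome(seed = 1)
  config <- sim_config(seed = 202)
  pk <- simulate_peak_matrix(genome, config)
  list(genome = genome, config = config, pk = pk)
})

# purity-0.7 tumors over the default peak simulation (100 tumors)
fx_tumors <- function() fixture("tumors", function() {
  px <- fx_peaks()
  config <- sim_config(seed = 202, purity = 0.7,
                       n_tumors_per_origin = c(50, 50))
  tum <- simulate_bulk_tumors(px$pk, config, px$genome)
  hq <- select_high_quality_peaks(px$pk$counts, px$pk$cell_types)
  shared <- intersect(rownames(tum$counts), hq)
  tumor_norm <- quantile_normalize(logcpm_normalize(tum$counts[shared, ]))
  types <- sort(unique(px$pk$cell_types))
  prof <- vapply(types, function(t) {
    Matrix::rowSums(px$pk$counts[shared, px$pk$cell_types == t, drop = FALSE])
  }, numeric(length(shared)))
  prof_norm <- quantile_normalize(logcpm_normalize(prof))
  list(config = config, tum = tum, hq = hq, shared = shared,
       tumor_norm = tumor_norm, prof_norm = prof_norm)
})

# two identical end-to-end pipeline runs, shared by the smoke, resume and
# determinism checks
fx_pipeline <- function() fixture("pipeline", function() {
  cfg <- pipeline_config(
    seed = 31,
    sim = sim_config(seed = 31,
                     cells_per_type = c(type1 = 60, type2 = 60),
                     n_background = 80, n_peaks = 600,
                     specific_per_type = 80, n_shared = 60,
                     n_tumors_per_origin = 6))
  dir1 <- file.path(tempdir(), "oa_run1")
  dir2 <- file.path(tempdir(), "oa_run2")
  unlink(c(dir1, dir2), recursive = TRUE)
  r1 <- suppressWarnings(run_pipeline(cfg, outdir = dir1))
  r2 <- suppressWarnings(run_pipeline(cfg, outdir = dir2))
  list(cfg = cfg, r1 = r1, r2 = r2, dir1 = dir1, dir2 = dir2)
})

# hand-built genome with known gene coordinates for interval arithmetic
manual_genome <- function(len = 100000, genes) {
  g <- toy_genome(chrom_lengths = c(chrT = len), n_genes = 1, seed = 1)
  g$genes <- genes
  g
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  t <- table(a, b)
  n <- sum(t)
  sij <- sum(choose(t, 2))
  si <- sum(choose(rowSums(t), 2))
  sj <- sum(choose(colSums(t), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# area under the ROC curve for scores against binary labels
auroc <- function(scores, positive) {
  r <- rank(scores)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# mean silhouette width for a 2-group labeling under a distance matrix
mean_silhouette <- function(d, cl) {
  d <- as.matrix(d)
  vapply(seq_along(cl), function(i) {
    own <- cl == cl[i]; own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(g) {
      mean(d[i, cl == g])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)) |> mean()
}
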