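test_that("fragment simulation is deterministic and conserves config", {
  genome <- toy_genome(seed = 1)
  config <- sim_config(seed = 7, cells_per_type = c(type1 = 5, type2 = 5),
                       n_background = 5, depth_meanlog = log(300),
                       bg_depth_meanlog = log(100))
  a <- simulate_fragments(genome, config)
  b <- simulate_fragments(genome, config)
  expect_identical(a$fragments, b$fragments)
  expect_identical(a$barcodes, b$barcodes)

  expect_equal(nrow(a$barcodes), 15)
  expect_equal(sum(a$barcodes$label == "cell"), 10)
  expect_equal(as.vector(table(a$barcodes$cell_type)), c(5, 5))

  # dedup contract: no two records share chrom+start+end+barcode
  key <- with(a$fragments, paste(chrom, start, end, barcode))
  expect_equal(anyDuplicated(key), 0L)

  config2 <- sim_config(seed = 8, cells_per_type = c(type1 = 5, type2 = 5),
                        n_background = 5, depth_meanlog = log(300),
                        bg_depth_meanlog = log(100))
  c_ <- simulate_fragments(genome, config2)
  expect_false(identical(a$fragments, c_$fragments))
})

test_that("empty genome is rejected", {
  config <- sim_config(seed = 1)
  expect_error(simulate_fragments(list(), config), "empty genome")
  expect_error(toy_genome(chrom_lengths = numeric(0)), "empty genome")
})

test_that("genuine and background barcodes separate by total fragments (AUROC > 0.95)", {
  genome <- toy_genome(seed = 1)
  # genuine depth ~10x background, 100 + 100 barcodes
  config <- sim_config(seed = 11,
                       cells_per_type = c(type1 = 50, type2 = 50),
                       n_background = 100,
                       depth_meanlog = log(2000), depth_sdlog = 0.3,
                       bg_depth_meanlog = log(200), bg_depth_sdlog = 0.3)
  sim <- simulate_fragments(genome, config)
  counts <- table(sim$fragments$barcode)
  lab <- sim$barcodes$label[match(names(counts), sim$barcodes$barcode)]
  expect_gt(auroc(as.numeric(counts), lab == "cell"), 0.95)
})

test_that("peak matrix carries planted type structure and exact labels", {
  px <- fx_peaks()
  pk <- px$pk
  config <- px$config

  # ground-truth labels reproduce the generating assignment exactly
  expect_equal(unname(table(pk$cell_types)[names(config$cells_per_type)]),
               unname(config$cells_per_type),
               ignore_attr = TRUE)

  # binomial mean: own-type accessibility ~ p_own per cell
  own_peaks <- pk$peaks$peak_id[pk$peaks$role == "type1"]
  own_cells <- names(pk$cell_types)[pk$cell_types == "type1"]
  acc_frac <- mean(as.matrix(pk$counts[own_peaks, own_cells]) > 0)
  expect_lt(abs(acc_frac - config$p_own), 0.03)
  other_cells <- names(pk$cell_types)[pk$cell_types != "type1"]
  other_frac <- mean(as.matrix(pk$counts[own_peaks, other_cells]) > 0)
  expect_lt(abs(other_frac - config$p_other), 0.02)

  # per-type specific peak sets are disjoint by construction
  roles <- split(pk$peaks$peak_id, pk$peaks$role)
  types <- names(config$cells_per_type)
  for (i in seq_along(types)) {
    for (j in seq_len(i - 1)) {
      expect_length(intersect(roles[[types[i]]], roles[[types[j]]]), 0)
    }
  }
})

test_that("with zero shared peaks, between-type mean profiles are uncorrelated", {
  genome <- toy_genome(seed = 1)
  config <- sim_config(seed = 33, cells_per_type = c(type1 = 80, type2 = 80),
                       n_shared = 0, specific_per_type = 200)
  pk <- simulate_peak_matrix(genome, config)
  m1 <- Matrix::rowMeans(pk$counts[, pk$cell_types == "type1"])
  m2 <- Matrix::rowMeans(pk$counts[, pk$cell_types == "type2"])
  expect_lt(abs(cor(m1, m2)), 0.1)

  # contrast: with housekeeping peaks the profiles correlate positively
  cfg_shared <- sim_config(seed = 33,
                           cells_per_type = c(type1 = 80, type2 = 80))
  pk_sh <- simulate_peak_matrix(genome, cfg_shared)
  s1 <- Matrix::rowMeans(pk_sh$counts[, pk_sh$cell_types == "type1"])
  s2 <- Matrix::rowMeans(pk_sh$counts[, pk_sh$cell_types == "type2"])
  expect_gt(cor(s1, s2), 0.3)
})

test_that("bulk tumors at purity 1 correlate best with their origin", {
  px <- fx_peaks()
  config <- sim_config(seed = 44, purity = 1, n_private_peaks = 0,
                       n_tumors_per_origin = 5)
  tum <- simulate_bulk_tumors(px$pk, config, px$genome)
  types <- sort(unique(px$pk$cell_types))
  prof <- vapply(types, function(t) {
    Matrix::rowMeans(px$pk$counts[, px$pk$cell_types == t, drop = FALSE])
  }, numeric(nrow(px$pk$counts)))
  shared <- px$pk$peaks$peak_id
  cc <- cor(as.matrix(tum$counts[shared, ]), prof)
  best <- colnames(cc)[max.col(cc)]
  expect_equal(best, unname(tum$origins))
})

test_that("purity at or below 0.5 is rejected", {
  expect_error(sim_config(seed = 1, purity = 0.5), "purity")
  expect_error(sim_config(seed = 1, purity = 0.2), "purity")
})

test_that("expression cohort matches the 255/41/8 geometry with CIMP in the host subgroup", {
  ex <- simulate_expression(sim_config(seed = 55))
  expect_equal(nrow(ex$samples), 255)
  expect_equal(sum(ex$samples$subgroup == "a2"), 41)
  expect_equal(sum(ex$samples$cimp), 8)
  expect_true(all(ex$samples$subgroup[ex$samples$cimp] == "a2"))

  # determinism
  ex2 <- simulate_expression(sim_config(seed = 55))
  expect_identical(ex$expr, ex2$expr)

  # CIMP count larger than its host subgroup is impossible
  expect_error(sim_config(seed = 1, n_cimp = 50), "host subgroup")
})

test_that("a null expression cohort has no stable 2-cluster structure", {
  ex <- simulate_expression(sim_config(seed = 66, expr_effect = 0))
  genes <- unlist(ex$markers)
  z <- t(scale(t(ex$expr[genes, ])))
  d <- as.dist(1 - cor(z))
  cl <- cutree(hclust(d, method = "average"), k = 2)
  expect_lt(mean_silhouette(d, cl), 0.25)
})
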