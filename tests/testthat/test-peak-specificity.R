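test_that("master peak merging unions overlapping and adjacent intervals", {
  a <- data.frame(chrom = "chr1", start = 100, end = 200)
  b <- data.frame(chrom = "chr1", start = 150, end = 250)
  merged <- merge_master_peaks(list(a, b))
  expect_equal(merged, data.frame(chrom = "chr1", start = 100, end = 250))

  # disjoint intervals unchanged, sorted
  d <- data.frame(chrom = c("chr1", "chr1"), start = c(500, 100),
                  end = c(600, 200))
  md <- merge_master_peaks(d)
  expect_equal(md$start, c(100, 500))

  # idempotent
  expect_equal(merge_master_peaks(md), md)

  expect_error(merge_master_peaks(data.frame(chrom = "chr1", start = 5,
                                             end = 5)), "malformed")
})

test_that("high-quality peak selection is strict at the 5% boundary", {
  # 3 peaks x 40 cells in 2 clusters of 20
  labels <- rep(c("A", "B"), each = 20)
  m <- matrix(0, 3, 40, dimnames = list(paste0("p", 1:3), NULL))
  m[1, 1:2] <- 1            # 10% of cluster A -> kept
  m[2, c(1, 21)] <- 1       # exactly 5% in both clusters -> dropped
  keep <- select_high_quality_peaks(m, labels, min_frac = 0.05)
  expect_equal(keep, "p1")
  expect_error(select_high_quality_peaks(m, rep(NA, 40)), "label")
})

test_that("variable-peak ranking favors structured rows and warns when short", {
  set.seed(1)
  prop <- matrix(runif(300, 0.2, 0.4), 100, 3,
                 dimnames = list(sprintf("p%03d", 1:100), NULL))
  prop[1, ] <- 0.3                    # constant row
  prop[2, ] <- c(0.9, 0, 0)           # one-hot row, mean 0.3
  obj <- list(prop = prop, scale_factors = rep(1, 3))
  ranked <- select_variable_peaks(obj, n = 100)
  expect_lt(which(ranked == "p002"), which(ranked == "p001"))
  expect_warning(select_variable_peaks(obj, n = 500), "fewer peaks")
  expect_error(select_variable_peaks(list(prop = prop[, 1, drop = FALSE],
                                          scale_factors = 1), n = 10),
               "2 cell types")
})

test_that("Jensen-Shannon specificity matches the entropy arithmetic oracle", {
  # q = (0.5, 0.5) vs one-hot: JSD = H((0.75, 0.25)) - H((0.5, 0.5)) / 2
  prop <- matrix(c(0.5, 1, 0.5, 0), 2, 2,
                 dimnames = list(c("even", "hot"), c("t1", "t2")))
  obj <- list(prop = prop, scale_factors = c(t1 = 1, t2 = 1))
  sp <- js_specificity(obj)
  h <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
  jsd_even <- h(c(0.75, 0.25)) - h(c(0.5, 0.5)) / 2
  expect_equal(jsd_even, 0.31127812, tolerance = 1e-7)
  expect_equal(sp$specificity["even", "t1"], 1 - sqrt(jsd_even),
               tolerance = 1e-12)
  expect_equal(sp$specificity["even", "t1"], 0.4421, tolerance = 1e-4)

  # one-hot row: JSD = 0, s = 1, final = 1^2 * scaled proportion
  expect_equal(sp$specificity["hot", "t1"], 1)
  expect_equal(sp$final["hot", "t1"], 1)

  # brute-force oracle on a 10 x 3 toy matrix
  set.seed(2)
  toy <- matrix(runif(30, 0.05, 0.9), 10, 3,
                dimnames = list(sprintf("p%02d", 1:10), c("a", "b", "c")))
  sf <- c(a = 0.8, b = 1.0, c = 1.2)
  sp_toy <- js_specificity(list(prop = toy, scale_factors = sf))
  scaled <- sweep(toy, 2, sf, "*")
  for (i in 1:10) {
    q <- scaled[i, ] / sum(scaled[i, ])
    for (t in 1:3) {
      e <- numeric(3); e[t] <- 1
      m <- (q + e) / 2
      jsd <- h(m) - (h(q) + h(e)) / 2
      expect_equal(sp_toy$specificity[i, t], 1 - sqrt(jsd),
                   tolerance = 1e-12)
      expect_equal(sp_toy$final[i, t], (1 - sqrt(jsd))^2 * scaled[i, t],
                   tolerance = 1e-12)
    }
  }

  # bounds and normalization conservation
  expect_true(all(sp_toy$specificity >= 0 & sp_toy$specificity <= 1))
  q_rows <- sweep(scaled, 1, rowSums(scaled), "/")
  expect_equal(unname(rowSums(q_rows)), rep(1, 10), tolerance = 1e-12)
})

test_that("specificity output is equivariant under cell-type permutation", {
  set.seed(3)
  prop <- matrix(runif(60, 0.05, 0.9), 20, 3,
                 dimnames = list(sprintf("p%02d", 1:20), c("a", "b", "c")))
  sf <- c(a = 0.7, b = 1.1, c = 1.2)
  sp1 <- js_specificity(list(prop = prop, scale_factors = sf))
  perm <- c("c", "a", "b")
  sp2 <- js_specificity(list(prop = prop[, perm], scale_factors = sf[perm]))
  expect_equal(sp2$final[, perm], sp1$final[, perm], tolerance = 1e-12)
  expect_equal(sp2$specificity, sp1$specificity[, perm], tolerance = 1e-12)
})

test_that("specific-peak selection dedupes by peak with lexicographic ties", {
  fin <- matrix(c(0.9, 0.2, 0.9, 0.1, 0.5, 0.8), 2, 3,
                dimnames = list(c("pk1", "pk2"), c("tB", "tA", "tC")))
  sel <- select_specific_peaks(list(final = fin), top_n = 10)
  # pk1 ties at 0.9 for tB and tA -> assigned to lexicographically first (tA)
  expect_equal(sel$type[sel$peak == "pk1"], "tA")
  expect_equal(anyDuplicated(sel$peak), 0L)

  sel1 <- select_specific_peaks(list(final = fin), top_n = 1)
  expect_equal(nrow(sel1), 1)
  expect_equal(sel1$peak, "pk1")
})
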