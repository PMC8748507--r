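test_that("TSS ratio counts half-open interval intersections exactly", {
  # one gene, '+' strand, TSS at 50000: window [49000, 51000)
  g <- manual_genome(genes = data.frame(
    gene_id = "g1", chrom = "chrT", tss = 50000, strand = "+",
    start = 50000, end = 60000, stringsAsFactors = FALSE))

  # 2 of 4 fragments intersect the window
  fr <- data.frame(chrom = "chrT",
                   start = c(49500, 50500, 10000, 20000),
                   end = c(49700, 50700, 10200, 20200),
                   barcode = "B1", stringsAsFactors = FALSE)
  expect_equal(unname(compute_tss_ratio(fr, g)), 0.5)

  # all fragments inside the window
  fr2 <- data.frame(chrom = "chrT", start = c(49100, 50100),
                    end = c(49300, 50300), barcode = "B2",
                    stringsAsFactors = FALSE)
  expect_equal(unname(compute_tss_ratio(fr2, g)), 1.0)

  # fragment ending exactly at TSS-1000 does not intersect (half-open);
  # one ending a single bp later does
  fr3 <- data.frame(chrom = "chrT", start = c(48800, 48801),
                    end = c(49000, 49001),
                    barcode = c("B3", "B4"), stringsAsFactors = FALSE)
  r <- compute_tss_ratio(fr3, g)
  expect_equal(unname(r["B3"]), 0)
  expect_equal(unname(r["B4"]), 1)

  expect_error(compute_tss_ratio(fr[0, ], g), "no fragments")
})

test_that("banding score concentrates spectral mass in the nucleosomal band for a periodic series", {
  sizes <- 1:1000
  series <- round(1000 + 500 * cos(2 * pi * sizes / 200))
  score <- compute_banding_score(series)
  pg <- spec.pgram(as.numeric(series), spans = 20, pad = 0.3, taper = 0.5,
                   detrend = TRUE, plot = FALSE)
  band <- pg$freq >= 1 / 300 & pg$freq <= 1 / 100
  expect_equal(score, sum(pg$spec[band]))
  # the 100-300 bp band holds the dominant share of smoothed spectral mass,
  # far above the band's width fraction of frequencies
  expect_gt(score / sum(pg$spec), 0.4)
  expect_gt((score / sum(pg$spec)) / mean(band), 20)
})

test_that("banding score is undefined for degenerate histograms and low counts", {
  expect_true(is.na(compute_banding_score(rep(0, 1000))))
  few <- c(rep(0, 199), 50, rep(0, 800))  # 50 fragments < default minimum
  expect_true(is.na(compute_banding_score(few)))
  expect_error(compute_banding_score(rep(1, 100)), "300")
})

test_that("banding ranks are invariant to uniform scaling of the histogram", {
  set.seed(3)
  make_series <- function(pf) {
    sz <- c(round(rnorm(round(2000 * pf), 200, 25)),
            round(30 + rexp(round(2000 * (1 - pf)), 1 / 55)))
    tabulate(pmin(pmax(sz, 1), 1000), nbins = 1000)
  }
  series <- lapply(c(0.1, 0.3, 0.5, 0.7), make_series)
  s1 <- vapply(series, compute_banding_score, numeric(1))
  s2 <- vapply(series, function(x) compute_banding_score(x * 7), numeric(1))
  expect_equal(order(s1), order(s2))
})

test_that("destroying periodicity by permuting the size histogram lowers banding scores", {
  set.seed(4)
  periodic <- lapply(1:10, function(i) {
    sz <- c(round(rnorm(1500, 200, 25)), round(rnorm(500, 400, 35)),
            round(30 + rexp(2000, 1 / 55)))
    tabulate(pmin(pmax(sz, 1), 1000), nbins = 1000)
  })
  orig <- vapply(periodic, compute_banding_score, numeric(1))
  shuf <- vapply(periodic, function(x) compute_banding_score(sample(x)),
                 numeric(1))
  expect_lt(median(shuf), median(orig))
})

test_that("aperiodic barcodes show no consistent band enrichment", {
  set.seed(6)
  # two aperiodic replicates (periodic fraction 0): band sums agree to 2x
  rep_series <- function() {
    sz <- round(30 + rexp(4000, 1 / 55))
    tabulate(pmin(pmax(sz, 1), 1000), nbins = 1000)
  }
  s1 <- compute_banding_score(rep_series())
  s2 <- compute_banding_score(rep_series())
  expect_gt(s1 / s2, 0.5)
  expect_lt(s1 / s2, 2)
})

test_that("bimodal cutoff lands between two clear modes and respects the stricter default", {
  set.seed(5)
  values <- c(rnorm(500, 2, 0.1), rnorm(500, 4, 0.1))
  fit <- fit_bimodal_cutoff(values, default_threshold = -Inf)
  expect_gt(fit$threshold, 2.5)
  expect_lt(fit$threshold, 3.5)
  expect_equal(fit$provenance, "fitted")

  # stricter default wins: candidate ~3.0, default 3.4 -> 3.4
  fit2 <- fit_bimodal_cutoff(values, default_threshold = 3.4)
  expect_equal(fit2$threshold, 3.4)
  expect_equal(fit2$provenance, "default")

  # unimodal data: degenerate fit falls back to the default
  uni <- rnorm(500, 3, 0.2)
  fit3 <- fit_bimodal_cutoff(uni, default_threshold = 1.23)
  expect_equal(fit3$threshold, 1.23)
  expect_equal(fit3$provenance, "default")

  expect_error(fit_bimodal_cutoff(rnorm(10), 0), ">= 20")
})

test_that("barcode filtering applies strict inequalities on all three criteria", {
  qc <- data.frame(
    barcode = c("pass", "boundary", "low_tss", "no_band"),
    n_fragments = c(10^3.5, 10^3.4, 10^3.5, 10^3.5),
    tss_ratio = c(0.20, 0.20, 0.10, 0.20),
    banding_score = c(10^-1, 10^-1, 10^-1, NA),
    stringsAsFactors = FALSE)
  th <- c(log10_n_fragments = 3.4, tss_ratio = 0.15,
          log10_banding_score = -1.75)
  res <- filter_barcodes(qc, th)
  expect_equal(res$retained, "pass")
  expect_equal(unname(res$n_failed["n_fragments"]), 1L)

  # identity: -Inf thresholds retain barcodes with defined banding
  all_in <- filter_barcodes(qc[1:3, ],
                            c(log10_n_fragments = -Inf, tss_ratio = -Inf,
                              log10_banding_score = -Inf))
  expect_equal(all_in$retained, qc$barcode[1:3])
})

test_that("QC on synthetic data separates genuine cells from background", {
  fx <- fx_qc()
  qc <- fx$qc
  truth <- fx$sim$barcodes$label[match(qc$barcode, fx$sim$barcodes$barcode)]

  # banding separates periodic (genuine) from aperiodic (background)
  ok <- !is.na(qc$banding_score)
  expect_gt(auroc(log10(qc$banding_score[ok]), truth[ok] == "cell"), 0.95)

  # fitted cutoffs: at least as strict as the defaults
  cuts <- fit_qc_cutoffs(qc)
  expect_gte(cuts$log10_n_fragments$threshold, 3.4)
  expect_gte(cuts$tss_ratio$threshold, 0.15)
  expect_gte(cuts$log10_banding_score$threshold, -1.75)
})
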