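test_that("genebody accessibility sums overlapping peaks with mirrored anchors", {
  genes <- data.frame(
    gene_id = c("gplus", "gminus"), chrom = "chrT",
    tss = c(20000, 10000), strand = c("+", "-"),
    start = c(20000, 5000), end = c(30000, 10000), stringsAsFactors = FALSE)
  g <- manual_genome(genes = genes)
  peaks <- data.frame(chrom = "chrT",
                      start = c(21000, 25000, 70000),
                      end = c(21500, 25500, 70500),
                      peak_id = c("pkA", "pkB", "pkC"),
                      role = "none", stringsAsFactors = FALSE)
  mat <- matrix(c(3, 2, 7), 3, 1, dimnames = list(peaks$peak_id, "cell1"))
  gb <- genebody_accessibility(mat, peaks, g)

  # gene overlapping peaks with counts 3 and 2 -> genebody value 5
  expect_equal(unname(gb$mat["gplus", "cell1"]), 5)
  # gene with no overlapping peak -> 0, row kept
  expect_equal(unname(gb$mat["gminus", "cell1"]), 0)

  # '-' strand gene with TSS 10000 -> anchor [9900, 10200)
  anchor <- gb$nodes[gb$nodes$id == "gminus", ]
  expect_equal(anchor$start, 9900)
  expect_equal(anchor$end, 10200)
  # '+' strand: [TSS - 200, TSS + 100)
  aplus <- gb$nodes[gb$nodes$id == "gplus", ]
  expect_equal(c(aplus$start, aplus$end), c(19800, 20100))
  expect_equal(aplus$end - aplus$start, 300)
})

test_that("cell aggregation conserves counts and is reproducible", {
  set.seed(5)
  mat <- matrix(rpois(30 * 40, 3), 30, 40,
                dimnames = list(sprintf("f%02d", 1:30),
                                sprintf("c%02d", 1:40)))
  emb <- matrix(rnorm(80), 40, 2)

  # k = n_cells: a single aggregate equal to the row sums
  agg_all <- aggregate_cells(mat, emb, k = 40, n_aggregates = 5, seed = 1)
  expect_equal(ncol(agg_all), 1)  # duplicates dropped (100% shared members)
  expect_equal(unname(agg_all[, 1]), unname(rowSums(mat)))

  agg <- aggregate_cells(mat, emb, k = 5, n_aggregates = 8, seed = 2)
  members <- attr(agg, "members")
  for (j in seq_len(ncol(agg))) {
    expect_equal(unname(agg[, j]),
                 unname(rowSums(mat[, members[[j]], drop = FALSE])))
  }
  agg2 <- aggregate_cells(mat, emb, k = 5, n_aggregates = 8, seed = 2)
  expect_identical(agg, agg2)
  expect_error(aggregate_cells(mat, emb, k = 41), "exceeds")
})

test_that("graphical lasso matches direct inversion at zero penalty and empties at infinite penalty", {
  set.seed(6)
  X <- matrix(rnorm(500 * 5), 500, 5)
  X[, 2] <- 0.7 * X[, 1] + 0.4 * rnorm(500)
  X[, 4] <- -0.5 * X[, 3] + 0.6 * rnorm(500)
  S <- cov(X)

  gl0 <- graphical_lasso(S, rho = 0, tol = 1e-10, max_iter = 500)
  expect_lt(max(abs(gl0$theta - solve(S))), 1e-6)

  gl_inf <- graphical_lasso(S, rho = 1e6)
  off <- gl_inf$theta; diag(off) <- 0
  expect_lt(max(abs(off)), 1e-12)
  expect_equal(diag(gl_inf$theta), 1 / diag(S), tolerance = 1e-8)

  # partial correlations: diagonal 1, symmetric, in [-1, 1]
  pc <- partial_correlations(gl0$theta)
  expect_equal(unname(diag(pc)), rep(1, 5))
  expect_equal(pc, t(pc), tolerance = 1e-10)
})

test_that("co-accessibility respects the distance constraint and links planted pairs", {
  # planted co-accessible pair (shared latent activation) vs a
  # distance-matched independent pair, plus a high-correlation pair beyond
  # the constraint that must never form an edge
  n_rep <- 20
  wins <- 0
  for (r in seq_len(n_rep)) {
    set.seed(100 + r)
    n_agg <- 40
    latent <- rpois(n_agg, 5)
    planted_a <- rpois(n_agg, 2) + latent
    planted_b <- rpois(n_agg, 2) + latent
    indep_a <- rpois(n_agg, 7)
    indep_b <- rpois(n_agg, 7)
    far_shared <- rpois(n_agg, 5)
    far_a <- far_shared + rpois(n_agg, 1)
    far_b <- far_shared + rpois(n_agg, 1)
    filler <- t(vapply(1:6, function(i) rpois(n_agg, 6), numeric(n_agg)))
    agg <- rbind(planted_a, planted_b, indep_a, indep_b, far_a, far_b,
                 filler)
    rownames(agg) <- c("plA", "plB", "inA", "inB", "farA", "farB",
                       sprintf("fill%d", 1:6))
    nodes <- data.frame(
      chrom = "chr1",
      start = c(10000, 60000, 110000, 160000, 200000, 460000,
                seq(240000, by = 30000, length.out = 6)),
      end = c(10000, 60000, 110000, 160000, 200000, 460000,
              seq(240000, by = 30000, length.out = 6)) + 500,
      id = rownames(agg), stringsAsFactors = FALSE)
    net <- coaccessibility(agg, nodes, window = 5e5, constraint = 2.5e5,
                           penalty_scale = 0.05, cutoff = 0.1)
    sc <- net$scores
    pl <- sc$score[sc$node_a == "plA" & sc$node_b == "plB"]
    ind <- sc$score[sc$node_a == "inA" & sc$node_b == "inB"]
    if (length(pl) == 1 && (length(ind) == 0 || pl > ind)) wins <- wins + 1

    # the 260 kb far pair is beyond the constraint: never scored or linked
    expect_false(any(sc$node_a == "farA" & sc$node_b == "farB"))
    expect_false(any(net$edges$node_a == "farA" &
                       net$edges$node_b == "farB"))
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("genebody anchors recover planted gene-enhancer links better than a single TSS window", {
  # the gene's transcription latent drives all its genebody peaks; the
  # genebody node (sum of three peaks) has higher signal-to-noise than the
  # single TSS-window peak, so its link to the planted enhancer scores higher
  gb_scores <- c(); tss_scores <- c()
  for (r in 1:10) {
    set.seed(600 + r)
    n_agg <- 40
    latent <- rpois(n_agg, 4)
    tss_peak <- rpois(n_agg, 2) + latent
    body1 <- rpois(n_agg, 2) + latent
    body2 <- rpois(n_agg, 2) + latent
    enhancer <- rpois(n_agg, 2) + latent
    genebody <- tss_peak + body1 + body2
    filler <- t(vapply(1:4, function(i) rpois(n_agg, 6), numeric(n_agg)))
    pos <- c(10000, 80000, seq(120000, by = 25000, length.out = 4))
    run_variant <- function(anchor_row) {
      agg <- rbind(anchor = anchor_row, enh = enhancer, filler)
      rownames(agg)[3:6] <- sprintf("fill%d", 1:4)
      nodes <- data.frame(chrom = "chr1", start = pos, end = pos + 500,
                          id = rownames(agg), stringsAsFactors = FALSE)
      sc <- coaccessibility(agg, nodes, penalty_scale = 0.05,
                            cutoff = 0.1)$scores
      v <- sc$score[(sc$node_a == "anchor" & sc$node_b == "enh") |
                      (sc$node_a == "enh" & sc$node_b == "anchor")]
      if (length(v)) v else NA_real_
    }
    gb_scores <- c(gb_scores, run_variant(genebody))
    tss_scores <- c(tss_scores, run_variant(tss_peak))
  }
  expect_gt(median(gb_scores, na.rm = TRUE), median(tss_scores, na.rm = TRUE))
})

test_that("gene activity adds linked peaks above the cutoff and normalizes per cell", {
  nodes <- data.frame(chrom = "chrT",
                      start = c(1000, 2000, 3000),
                      end = c(1500, 2500, 3300),
                      id = c("pk1", "pk2", "geneX"),
                      kind = c("peak", "peak", "gene"),
                      stringsAsFactors = FALSE)
  aug <- matrix(c(10, 4, 6,
                  20, 2, 8), 3, 2,
                dimnames = list(c("pk1", "pk2", "geneX"), c("c1", "c2")))
  net <- list(scores = data.frame(node_a = c("geneX", "geneX"),
                                  node_b = c("pk1", "pk2"),
                                  score = c(0.15, 0.05),
                                  stringsAsFactors = FALSE),
              cutoff = 0.1)
  act <- gene_activity(net, aug, nodes, total = 1e4)
  # only pk1 (score 0.15 >= 0.1) contributes: raw = genebody + pk1
  raw <- c(6 + 10, 8 + 20)
  expect_equal(unname(act["geneX", ]), raw / raw * 1e4)

  # with no links at all, activity = genebody value only (then normalized)
  net0 <- list(scores = net$scores[0, ], cutoff = 0.1)
  act0 <- gene_activity(net0, aug, nodes, total = 1e4)
  expect_equal(unname(act0["geneX", ]), c(1e4, 1e4))
})
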