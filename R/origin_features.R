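#' Cell-type feature genes from a gene-activity matrix
#'
#' Removes genes active (> 0) in fewer than `min_cells` cells, then for each
#' cell type versus the rest computes: `pct.1`, the fraction of the type's
#' cells with non-zero activity; `avg_logFC = ln((mean_in + 1) /
#' (mean_out + 1))`; and a Wilcoxon rank-sum p-value (BH-adjusted). Feature
#' genes satisfy `pct.1 > pct_min`, `avg_logFC > lfc_min` and, when
#' `use_pval`, adjusted p < 0.05. Types with fewer than 3 cells are skipped
#' with a warning.
#'
#' @param activity Gene-by-cell activity matrix.
#' @param labels Cell-type label per cell.
#' @param min_cells Activity pre-filter (strictly fewer are removed).
#' @param pct_min,lfc_min Thresholds (strict).
#' @param use_pval Apply the Wilcoxon filter.
#' @return Named list (one per type) of character vectors of feature genes.
#' @export
celltype_feature_genes <- function(activity, labels, min_cells = 10,
                                   pct_min = 0.5, lfc_min = 0.5,
                                   use_pval = TRUE) {
  labels <- as.character(labels)
  types <- sort(unique(labels))
  if (length(types) < 2) stop("need at least 2 cell types")
  active_cells <- rowSums(activity > 0)
  activity <- activity[active_cells >= min_cells, , drop = FALSE]
  out <- list()
  for (t in types) {
    inn <- labels == t
    if (sum(inn) < 3) {
      warning("type ", t, " has fewer than 3 cells; skipped")
      next
    }
    pct1 <- rowMeans(activity[, inn, drop = FALSE] > 0)
    m_in <- rowMeans(activity[, inn, drop = FALSE])
    m_out <- rowMeans(activity[, !inn, drop = FALSE])
    lfc <- log((m_in + 1) / (m_out + 1))
    cand <- which(pct1 > pct_min & lfc > lfc_min)
    if (use_pval && length(cand) > 0) {
      p <- vapply(cand, function(i) {
        wilcox.test(activity[i, inn], activity[i, !inn], exact = FALSE)$p.value
      }, numeric(1))
      cand <- cand[p.adjust(p, "BH") < 0.05]
    }
    out[[t]] <- rownames(activity)[cand]
  }
  out
}

#' Subgroup feature genes from bulk gene activity
#'
#' Delegates to the negative-binomial exact test with the bulk-subgroup
#' thresholds (|log2FC| > 1, FDR < 0.05, logCPM > 5 by default) and returns
#' the per-group up-regulated gene sets.
#'
#' @param bulk Gene-by-sample count/activity matrix.
#' @param groups Two-level subgroup label per sample.
#' @param lfc,fdr,min_logcpm Thresholds.
#' @param prefilter Apply the mean < 1 / SD > 10 pre-filter.
#' @return Named list of two character vectors (up genes per group).
#' @export
subgroup_feature_genes <- function(bulk, groups, lfc = 1, fdr = 0.05,
                                   min_logcpm = 5, prefilter = FALSE) {
  differential_peaks(bulk, groups, lfc = lfc, fdr = fdr,
                     min_logcpm = min_logcpm, prefilter = prefilter)$up
}

#' Intersect cell-type and subgroup feature genes into origin-derived features
#'
#' @param celltype_sets Named list of cell-type feature gene sets.
#' @param subgroup_sets Named list of subgroup feature gene sets.
#' @param pairing Named character vector mapping each subgroup name to its
#'   candidate cell-of-origin type.
#' @return Named list (by subgroup) of intersected gene sets; empty
#'   intersections produce a warning, not an error.
#' @export
derive_origin_features <- function(celltype_sets, subgroup_sets, pairing) {
  out <- list()
  for (sg in names(pairing)) {
    ct <- pairing[[sg]]
    if (is.null(subgroup_sets[[sg]]) || is.null(celltype_sets[[ct]]))
      stop("unknown pairing key: ", sg, " -> ", ct)
    feats <- intersect(celltype_sets[[ct]], subgroup_sets[[sg]])
    if (length(feats) == 0)
      warning("empty origin-derived feature set for ", sg)
    out[[sg]] <- feats
  }
  out
}

#' Subgroup bulk expression samples by origin-derived features
#'
#' Restricts the expression matrix to the feature genes, z-scores each gene
#' across samples, hierarchically clusters the samples (correlation
#' distance, average linkage), cuts at 2, and names the cluster with the
#' higher mean z-score over the second feature set after that set (the
#' "a2-like" analogue).
#'
#' @param expr Gene-by-sample expression matrix.
#' @param features Named list of two feature gene sets (e.g. a1, a2).
#' @return Named character vector of subgroup labels per sample
#'   (`"<name>_Like"`).
#' @export
subgroup_bulk_samples <- function(expr, features) {
  stopifnot(length(features) == 2)
  genes <- intersect(unlist(features), rownames(expr))
  if (length(genes) < 2) stop("fewer than 2 feature genes present")
  x <- expr[genes, , drop = FALSE]
  if (all(apply(x, 2, function(c) identical(c, x[, 1]))))
    stop("no 2-cluster structure: all samples identical")
  z <- t(scale(t(x)))
  z[!is.finite(z)] <- 0
  d <- as.dist(1 - cor(z))
  cl <- cutree(hclust(d, method = "average"), k = 2)
  nm2 <- names(features)[2]
  g2 <- intersect(features[[nm2]], rownames(z))
  mean_z2 <- if (length(g2) > 0) {
    tapply(colMeans(z[g2, , drop = FALSE]), cl, mean)
  } else tapply(-colMeans(z), cl, mean)  # fall back to set 1 polarity
  a2_cluster <- as.integer(names(which.max(mean_z2)))
  lab <- ifelse(cl == a2_cluster, paste0(nm2, "_Like"),
                paste0(names(features)[1], "_Like"))
  setNames(lab, colnames(expr))
}

#' Bootstrap test for label enrichment in a subgroup
#'
#' Emulates drawing a size-n subgroup at random from a cohort of N samples
#' containing m labeled samples: the number of labeled samples recovered is
#' counted over `reps` draws without replacement, a normal distribution is
#' fitted to the counts (sample mean and SD), and the p-value is the
#' normal upper-tail probability at the observed count. The exact
#' hypergeometric tail `P(X >= observed)` is reported alongside as the
#' reference value.
#'
#' @param N Cohort size.
#' @param n Subgroup size.
#' @param m Number of labeled samples in the cohort.
#' @param observed Observed labeled count inside the subgroup.
#' @param reps Bootstrap replicates (default 10,000).
#' @param seed Integer seed.
#' @return An `enrichment_result` list: observed, boot_mean, boot_sd,
#'   p_normal, p_exact, reps, degenerate flag, and the analytic
#'   hypergeometric moments (hyper_mean, hyper_sd).
#' @export
cimp_bootstrap_test <- function(N, n, m, observed, reps = 10000, seed = 1L) {
  stopifnot(m >= 0, m <= N, n >= 0, n <= N, observed <= m, observed >= 0,
            reps >= 1)
  set.seed(seed)
  ## each draw takes n of N without replacement and counts labeled samples
  counts <- rhyper(reps, m, N - m, n)
  mu <- mean(counts); sdev <- sd(counts)
  degenerate <- !is.finite(sdev) || sdev == 0
  p_normal <- if (degenerate) as.numeric(observed <= mu)
              else pnorm(observed, mean = mu, sd = sdev, lower.tail = FALSE)
  p_exact <- phyper(observed - 1, m, N - m, n, lower.tail = FALSE)
  hmean <- n * m / N
  hvar <- n * (m / N) * (1 - m / N) * (N - n) / (N - 1)
  res <- list(N = N, n = n, m = m, observed = observed, reps = reps,
              boot_mean = mu, boot_sd = sdev, p_normal = p_normal,
              p_exact = p_exact, degenerate = degenerate,
              hyper_mean = hmean, hyper_sd = sqrt(hvar))
  class(res) <- "enrichment_result"
  res
}

#' @export
#' @method print enrichment_result
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Label enrichment: %d of %d labeled samples in a subgroup of %d (cohort %d)\n",
              x$observed, x$m, x$n, x$N))
  cat(sprintf("  bootstrap (%d reps): mean %.4f, sd %.4f\n", x$reps,
              x$boot_mean, x$boot_sd))
  cat(sprintf("  normal-tail p = %.3g%s\n", x$p_normal,
              if (x$degenerate) " (degenerate: zero bootstrap SD)" else ""))
  cat(sprintf("  exact hypergeometric P(X >= %d) = %.3g\n", x$observed,
              x$p_exact))
  invisible(x)
}
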