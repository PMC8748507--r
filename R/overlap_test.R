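#' Fraction of cancer peaks overlapping a cell-type peak set
#'
#' Each cancer peak counts once, whether it hits one or several cell-type
#' peaks.
#'
#' @param cancer_peaks,celltype_peaks BED data.frames (chrom, start, end).
#' @return Overlap fraction in [0, 1].
#' @export
overlap_fraction <- function(cancer_peaks, celltype_peaks) {
  if (nrow(cancer_peaks) == 0) stop("empty cancer peak set")
  if (nrow(celltype_peaks) == 0) stop("empty cell-type peak set")
  hits <- GenomicRanges::countOverlaps(bed_to_granges(cancer_peaks),
                                       bed_to_granges(celltype_peaks))
  mean(hits > 0)
}

#' Permutation test for cancer / cell-type peak overlap enrichment
#'
#' For each (cancer set, cell type) pair: the observed overlap fraction is
#' compared with the expectation obtained by drawing, `n_perm` times, a
#' random cell-type peak set of the same size from the pooled specific
#' peaks. The p-value is a one-sided binomial tail
#' `P(X >= observed count | n = #cancer peaks, p = expected fraction)`,
#' testing over-representation; p-values are Benjamini-Hochberg adjusted
#' across all pairs.
#'
#' @param cancer_sets Named list of cancer peak BED data.frames.
#' @param celltype_sets Named list of cell-type-specific peak BED
#'   data.frames.
#' @param pooled_peaks BED data.frame of all pooled cell-type-specific peaks
#'   (superset of every cell-type set).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return data.frame: cancer, celltype, observed, expected, p, p_adj.
#' @export
permutation_overlap_test <- function(cancer_sets, celltype_sets, pooled_peaks,
                                     n_perm = 1000, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(seed)
  pooled_gr <- bed_to_granges(pooled_peaks)
  n_pool <- length(pooled_gr)
  rows <- list()
  for (ca in names(cancer_sets)) {
    ca_gr <- bed_to_granges(cancer_sets[[ca]])
    n_ca <- length(ca_gr)
    ## cancer-peak x pooled-peak overlap incidence, computed once per cancer
    ## set; a permutation is then a column subset, not a new interval query
    ov <- GenomicRanges::findOverlaps(ca_gr, pooled_gr)
    inc <- Matrix::sparseMatrix(i = S4Vectors::queryHits(ov),
                                j = S4Vectors::subjectHits(ov), x = 1,
                                dims = c(n_ca, n_pool))
    for (ct in names(celltype_sets)) {
      ct_pk <- celltype_sets[[ct]]
      obs <- overlap_fraction(cancer_sets[[ca]], ct_pk)
      draws <- unlist(lapply(seq_len(n_perm), function(b)
        sample(n_pool, nrow(ct_pk))))
      Z <- Matrix::sparseMatrix(i = draws,
                                j = rep(seq_len(n_perm), each = nrow(ct_pk)),
                                x = 1, dims = c(n_pool, n_perm))
      perm_frac <- Matrix::colSums((inc %*% Z) > 0) / n_ca
      expected <- mean(perm_frac)
      x <- round(obs * n_ca)
      p <- binom.test(x, n_ca, p = min(max(expected, 1e-12), 1 - 1e-12),
                      alternative = "greater")$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        cancer = ca, celltype = ct, observed = obs, expected = expected,
        p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
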