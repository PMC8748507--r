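#' Log counts-per-million with a prior count
#'
#' For column library size `L_j` and scaled prior `p_j = prior * L_j /
#' mean(L)`, each count `c` maps to `log2((c + p_j) / (L_j + 2 * p_j) * 1e6)`.
#' This matches the standard log-CPM transform with library-size-scaled
#' prior counts.
#'
#' @param counts Numeric matrix of non-negative counts (features x samples).
#' @param prior Prior count (default 5).
#' @return Matrix of log2-CPM values.
#' @export
logcpm_normalize <- function(counts, prior = 5) {
  counts <- as.matrix(counts)
  L <- colSums(counts)
  if (any(L <= 0)) stop("zero library size")
  pj <- prior * L / mean(L)
  t(log2(t(counts + rep(pj, each = nrow(counts))) / (L + 2 * pj) * 1e6))
}

#' Quantile normalization across columns
#'
#' Replaces each column's values by the cross-column mean of order
#' statistics at its ranks; ties receive the mean of their quantile values
#' (midrank interpolation), so after normalization every column's sorted
#' values are identical.
#'
#' @param x Numeric matrix.
#' @return Quantile-normalized matrix.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  sorted_mean <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    r <- rank(col, ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    (sorted_mean[lo] + sorted_mean[hi]) / 2
  })
  dimnames(out) <- dimnames(x)
  out
}
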