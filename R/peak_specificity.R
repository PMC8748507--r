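#' Merge per-cluster peak sets into a master peak list
#'
#' Takes the union of all intervals, merging overlapping and adjacent peaks,
#' and returns the sorted result. Idempotent.
#'
#' @param peak_list A data.frame of peaks (chrom, start, end) or a list of
#'   such data.frames (one per cluster).
#' @return Sorted merged data.frame (chrom, start, end).
#' @export
merge_master_peaks <- function(peak_list) {
  if (is.data.frame(peak_list)) peak_list <- list(peak_list)
  all_pk <- do.call(rbind, lapply(peak_list, function(p) {
    check_bed(p)
    p[, c("chrom", "start", "end")]
  }))
  gr <- GenomicRanges::reduce(bed_to_granges(all_pk))
  gr <- GenomicRanges::sort(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Select high-quality peaks: accessible in more than 5% of any cluster
#'
#' @param mat Peak-by-cell count matrix.
#' @param labels Cluster label per cell (same order as columns).
#' @param min_frac Strict lower bound on the within-cluster accessible
#'   fraction.
#' @return Character vector of retained peak ids (rownames of `mat`).
#' @export
select_high_quality_peaks <- function(mat, labels, min_frac = 0.05) {
  stopifnot(ncol(mat) == length(labels))
  labels <- as.character(labels)
  if (anyNA(labels)) stop("every cell must carry a cluster label")
  cl <- unique(labels)
  if (any(table(labels) == 0)) stop("empty cluster")
  frac <- vapply(cl, function(g) {
    sub <- mat[, labels == g, drop = FALSE]
    Matrix::rowSums(sub > 0) / ncol(sub)
  }, numeric(nrow(mat)))
  keep <- apply(frac, 1, max) > min_frac
  rownames(mat)[keep]
}

#' Peak-by-cell-type proportion matrix with per-type scaling factors
#'
#' Entry (p, t) is the fraction of type-t cells accessible (count > 0) at
#' peak p. The per-type scaling factor is the median total fragment count of
#' the type's cells, normalized to mean 1 across types so that scaled
#' proportions stay O(1).
#'
#' @param mat Peak-by-cell count matrix (already restricted to high-quality
#'   peaks).
#' @param labels Cell-type label per cell.
#' @return List: `prop` (peaks x types), `scale_factors` (named, mean 1).
#' @export
proportion_matrix <- function(mat, labels) {
  stopifnot(ncol(mat) == length(labels))
  labels <- as.character(labels)
  types <- sort(unique(labels))
  prop <- vapply(types, function(t) {
    sub <- mat[, labels == t, drop = FALSE]
    Matrix::rowSums(sub > 0) / ncol(sub)
  }, numeric(nrow(mat)))
  rownames(prop) <- rownames(mat)
  sf <- vapply(types, function(t) {
    median(Matrix::colSums(mat[, labels == t, drop = FALSE]))
  }, numeric(1))
  if (any(sf <= 0)) stop("non-positive scaling factor")
  sf <- sf / mean(sf)
  list(prop = prop, scale_factors = sf)
}

## vst-style standardized variance against a loess mean-variance trend
standardized_variance <- function(x, loess_span = 0.3) {
  mu <- rowMeans(x)
  v <- apply(x, 1, var)
  sv <- numeric(nrow(x))
  nz <- v > 0 & mu > 0
  if (sum(nz) >= 5) {
    fit <- loess(log10(v[nz]) ~ log10(mu[nz]), span = loess_span,
                 degree = 2)
    exp_sd <- sqrt(10^fitted(fit))
    clipmax <- sqrt(ncol(x))
    z <- sweep(x[nz, , drop = FALSE], 1, mu[nz], "-")
    z <- sweep(z, 1, exp_sd, "/")
    z <- pmin(pmax(z, -clipmax), clipmax)
    sv[nz] <- apply(z, 1, var)
  } else {
    sv[nz] <- v[nz]
  }
  sv
}

#' Select highly variable peaks from the proportion matrix
#'
#' Ranks peaks by variance standardized against a loess-smoothed
#' log10(variance) vs log10(mean) trend across peaks (vst-style), with
#' standardized values clipped at sqrt(n_types), and returns the top `n`.
#'
#' @param prop_obj Output of [proportion_matrix()].
#' @param n Number of variable peaks to keep.
#' @param loess_span Span of the mean-variance trend fit.
#' @return Character vector of peak ids, ranked by decreasing standardized
#'   variance.
#' @export
select_variable_peaks <- function(prop_obj, n = 50000, loess_span = 0.3) {
  prop <- prop_obj$prop
  if (ncol(prop) < 2) stop("need at least 2 cell types")
  sv <- standardized_variance(prop, loess_span)
  o <- order(-sv, seq_len(nrow(prop)))
  if (n > nrow(prop)) {
    warning("fewer peaks than requested; returning all")
    n <- nrow(prop)
  }
  rownames(prop)[o[seq_len(n)]]
}

## base-2 Shannon entropy of a probability vector (0 log 0 = 0)
entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

## Jensen-Shannon divergence (base 2) between probability vectors
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  entropy2(m) - (entropy2(p) + entropy2(q)) / 2
}

#' Jensen-Shannon specificity scores for peaks across cell types
#'
#' Scales the proportion matrix by the per-type scaling factors, normalizes
#' each peak's row to a distribution q over types, and scores specificity of
#' peak p for type t as `s = 1 - sqrt(JSD(q, e_t))` with base-2 logarithms
#' (JSD in [0, 1]; e_t is the one-hot distribution on t). The final score is
#' `s^2` times the scaled (normalized-proportion) matrix entry.
#'
#' @param prop_obj Output of [proportion_matrix()] (rows already restricted
#'   to variable peaks as desired).
#' @param peaks Optional character vector restricting rows.
#' @return List of matrices `specificity` (s), `final` (s^2 * scaled
#'   proportion), `scaled` (the normalized proportion matrix); rows with an
#'   all-zero scaled profile are excluded.
#' @export
js_specificity <- function(prop_obj, peaks = NULL) {
  scaled <- sweep(prop_obj$prop, 2, prop_obj$scale_factors, "*")
  if (!is.null(peaks)) scaled <- scaled[peaks, , drop = FALSE]
  rs <- rowSums(scaled)
  if (any(rs == 0)) scaled <- scaled[rs > 0, , drop = FALSE]
  q <- sweep(scaled, 1, rowSums(scaled), "/")
  K <- ncol(q)
  spec <- matrix(NA_real_, nrow(q), K, dimnames = dimnames(q))
  for (t in seq_len(K)) {
    e_t <- numeric(K); e_t[t] <- 1
    spec[, t] <- 1 - sqrt(apply(q, 1, js_divergence, q = e_t))
  }
  list(specificity = spec, final = spec^2 * scaled, scaled = scaled)
}

#' Select top cell-type-specific peaks from the final specificity scores
#'
#' Ranks all (peak, type) entries by final score, takes the top `top_n`
#' entries, and deduplicates by peak: each returned peak is assigned once, to
#' its best-scoring type (ties broken by lexicographically first type name).
#'
#' @param spec_obj Output of [js_specificity()].
#' @param top_n Number of (peak, type) entries to rank.
#' @return data.frame: peak, type, final score, ordered by decreasing score;
#'   at most `top_n` unique peaks.
#' @export
select_specific_peaks <- function(spec_obj, top_n = 20000) {
  fin <- spec_obj$final
  long <- data.frame(
    peak = rep(rownames(fin), ncol(fin)),
    type = rep(colnames(fin), each = nrow(fin)),
    final = as.vector(fin), stringsAsFactors = FALSE)
  long <- long[order(-long$final, long$peak, long$type), ]
  long <- head(long, top_n)
  long[!duplicated(long$peak), ]
}
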