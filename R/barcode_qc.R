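#' Fraction of a barcode's fragments overlapping TSS windows
#'
#' The TSS region is defined as +/-1000 bp around each TSS, half-open
#' `[tss - 1000, tss + 1000)`. A fragment counts if its interval intersects
#' any TSS window; each fragment counts once. Barcodes with zero fragments
#' are absent from the result (flagged missing upstream), never reported as 0.
#'
#' @param fragments data.frame with chrom, start, end, barcode (BED, 0-based
#'   half-open).
#' @param genome A [toy_genome()].
#' @param flank Half-width of the TSS window in bp.
#' @return Named numeric vector of TSS ratios, one entry per barcode present.
#' @export
compute_tss_ratio <- function(fragments, genome, flank = 1000) {
  stopifnot(inherits(genome, "toy_genome"))
  if (nrow(fragments) == 0) stop("no fragments")
  fr <- GenomicRanges::GRanges(fragments$chrom,
                               bed_to_iranges(fragments$start, fragments$end))
  tssw <- GenomicRanges::GRanges(
    genome$genes$chrom,
    bed_to_iranges(pmax(0, genome$genes$tss - flank), genome$genes$tss + flank))
  hit <- GenomicRanges::countOverlaps(fr, tssw) > 0
  tot <- tapply(rep(1L, nrow(fragments)), fragments$barcode, sum)
  in_tss <- tapply(as.integer(hit), fragments$barcode, sum)
  ratio <- as.vector(in_tss / tot)
  names(ratio) <- names(tot)
  ratio
}

#' Nucleosome banding score from an insert-size histogram
#'
#' Computes a smoothed periodogram of the insert-size histogram (counts per
#' bp, sizes 1..S) with linear detrending, a split-cosine-bell taper over
#' total proportion 0.5, 30% zero-padding and one modified Daniell smoother
#' of span 20, then sums the spectral densities at frequencies corresponding
#' to periods between 100 and 300 bp. High values indicate nucleosomal
#' banding, the signature of genuine nuclei.
#'
#' The periodogram operates on the size histogram, not the raw size sequence,
#' so the score is invariant to fragment order.
#'
#' @param size_counts Integer vector of insert-size counts indexed by size
#'   1..S (S >= 300), or raw insert sizes if `raw = TRUE`.
#' @param min_fragments Minimum total count below which the score is `NA`
#'   (undefined rather than zero).
#' @param max_size Maximum insert size entering the histogram.
#' @param raw If `TRUE`, `size_counts` are raw sizes to be tabulated.
#' @return A single numeric banding score, or `NA_real_` when undefined.
#' @export
compute_banding_score <- function(size_counts, min_fragments = 100,
                                  max_size = 1000, raw = FALSE) {
  if (raw) {
    sz <- pmin(pmax(round(size_counts), 1L), max_size)
    size_counts <- tabulate(sz, nbins = max_size)
  }
  S <- length(size_counts)
  if (S < 300) stop("insert-size histogram must cover sizes up to >= 300 bp")
  total <- sum(size_counts)
  if (total == 0 || total < min_fragments) return(NA_real_)
  pg <- stats::spec.pgram(as.numeric(size_counts), spans = 20, pad = 0.3,
                          taper = 0.5, detrend = TRUE, plot = FALSE)
  band <- pg$freq >= 1 / 300 & pg$freq <= 1 / 100
  sum(pg$spec[band])
}

#' Per-barcode QC table: fragment counts, TSS ratio, banding score
#'
#' @param fragments Fragment data.frame (chrom, start, end, barcode).
#' @param genome A [toy_genome()].
#' @param min_fragments_banding Minimum fragments for a defined banding score.
#' @param max_size Maximum insert size entering the banding histogram.
#' @return data.frame: barcode, n_fragments, tss_ratio, banding_score.
#' @export
barcode_qc_table <- function(fragments, genome, min_fragments_banding = 100,
                             max_size = 1000) {
  dt <- data.table::as.data.table(fragments)
  dt[, size := end - start]
  tssr <- compute_tss_ratio(fragments, genome)
  qc <- dt[, .(n_fragments = .N,
               banding_score = compute_banding_score(
                 size, min_fragments = min_fragments_banding,
                 max_size = max_size, raw = TRUE)),
           by = barcode]
  qc <- as.data.frame(qc)
  qc$tss_ratio <- unname(tssr[qc$barcode])
  qc[, c("barcode", "n_fragments", "tss_ratio", "banding_score")]
}

#' Fit a bimodal cutoff to a QC statistic
#'
#' Fits a two-component univariate Gaussian mixture by EM and places the
#' candidate cutoff at the point between the two means where the posterior
#' probabilities of the components are equal. The returned threshold is the
#' stricter (larger, for lower-bound criteria) of the candidate and the
#' supplied default. Degenerate fits (a component weight below `min_weight`,
#' or means closer than `min_sep` pooled standard deviations) fall back to
#' the default with provenance `"default"`.
#'
#' @param values Numeric vector of per-barcode statistics (>= 20 finite).
#' @param default_threshold Default (floor) threshold.
#' @param min_weight Minimum admissible mixture weight.
#' @param min_sep Minimum mean separation in pooled-SD units.
#' @param seed Seed for the EM restarts.
#' @return List: `threshold`, `candidate` (NA if degenerate), `provenance`
#'   ("fitted" or "default").
#' @export
fit_bimodal_cutoff <- function(values, default_threshold,
                               min_weight = 0.02, min_sep = 0.25, seed = 1L) {
  values <- values[is.finite(values)]
  if (length(values) < 20) stop("need >= 20 finite values to fit a cutoff")
  set.seed(seed)
  fit <- tryCatch(
    mclust::Mclust(values, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  degenerate <- TRUE
  candidate <- NA_real_
  if (!is.null(fit)) {
    mu <- fit$parameters$mean
    sg <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sg) == 1) sg <- rep(sg, 2)
    w <- fit$parameters$pro
    pooled <- sqrt(mean(sg^2))
    if (min(w) >= min_weight && abs(diff(mu)) >= min_sep * pooled) {
      o <- order(mu); mu <- mu[o]; sg <- sg[o]; w <- w[o]
      post_diff <- function(x) {
        w[1] * stats::dnorm(x, mu[1], sg[1]) - w[2] * stats::dnorm(x, mu[2], sg[2])
      }
      root <- tryCatch(uniroot(post_diff, lower = mu[1], upper = mu[2])$root,
                       error = function(e) NA_real_)
      if (is.finite(root)) {
        candidate <- root
        degenerate <- FALSE
      }
    }
  }
  if (degenerate) {
    list(threshold = default_threshold, candidate = NA_real_,
         provenance = "default")
  } else {
    list(threshold = max(candidate, default_threshold), candidate = candidate,
         provenance = if (candidate > default_threshold) "fitted" else "default")
  }
}

#' Fit QC cutoffs for all three barcode criteria
#'
#' Applies [fit_bimodal_cutoff()] to log10 fragment counts, TSS ratios and
#' log10 banding scores, each floored at its default threshold (the stricter
#' of mixture fit and default is kept).
#'
#' @param qc QC table from [barcode_qc_table()].
#' @param defaults Named numeric: log10_n_fragments, tss_ratio,
#'   log10_banding_score.
#' @param seed Seed for the mixture fits.
#' @return List of three cutoff objects (as from [fit_bimodal_cutoff()]).
#' @export
fit_qc_cutoffs <- function(qc,
                           defaults = c(log10_n_fragments = 3.4,
                                        tss_ratio = 0.15,
                                        log10_banding_score = -1.75),
                           seed = 1L) {
  list(
    log10_n_fragments = fit_bimodal_cutoff(
      log10(qc$n_fragments), defaults[["log10_n_fragments"]], seed = seed),
    tss_ratio = fit_bimodal_cutoff(
      qc$tss_ratio, defaults[["tss_ratio"]], seed = seed),
    log10_banding_score = fit_bimodal_cutoff(
      log10(qc$banding_score), defaults[["log10_banding_score"]], seed = seed)
  )
}

#' Filter barcodes by the three QC criteria
#'
#' A barcode is retained iff it is strictly greater than all three
#' thresholds: log10(fragment count), TSS ratio, and log10(banding score).
#' Barcodes with an undefined banding score fail that criterion.
#'
#' @param qc QC table from [barcode_qc_table()].
#' @param cutoffs List as returned by [fit_qc_cutoffs()], or a named numeric
#'   vector of the three thresholds.
#' @return List: `retained` (character vector of barcodes), `flags`
#'   (logical data.frame of per-criterion passes), `n_failed` (named counts
#'   of failures per criterion).
#' @export
filter_barcodes <- function(qc, cutoffs) {
  th <- if (is.list(cutoffs) && !is.null(cutoffs$log10_n_fragments$threshold)) {
    c(log10_n_fragments = cutoffs$log10_n_fragments$threshold,
      tss_ratio = cutoffs$tss_ratio$threshold,
      log10_banding_score = cutoffs$log10_banding_score$threshold)
  } else unlist(cutoffs)
  stopifnot(all(is.finite(th) | th == -Inf))
  pass_frag <- log10(qc$n_fragments) > th[["log10_n_fragments"]]
  pass_tss <- !is.na(qc$tss_ratio) & qc$tss_ratio > th[["tss_ratio"]]
  pass_band <- !is.na(qc$banding_score) &
    log10(qc$banding_score) > th[["log10_banding_score"]]
  flags <- data.frame(barcode = qc$barcode, pass_frag = pass_frag,
                      pass_tss = pass_tss, pass_band = pass_band,
                      stringsAsFactors = FALSE)
  keep <- pass_frag & pass_tss & pass_band
  list(retained = qc$barcode[keep], flags = flags,
       n_failed = c(n_fragments = sum(!pass_frag), tss_ratio = sum(!pass_tss),
                    banding_score = sum(!pass_band)))
}
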