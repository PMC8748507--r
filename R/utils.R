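#' @importFrom methods as is
#' @importFrom stats rnorm rbinom rpois rlnorm runif rhyper rmultinom rexp
#'   pnorm phyper pbinom dbinom dnorm binom.test p.adjust cor dist as.dist
#'   hclust cutree sd var median quantile loess predict fitted uniroot
#'   wilcox.test dnbinom spec.pgram plogis setNames
#' @importFrom utils head tail write.table read.table
#' @importFrom mclust Mclust mclustBIC
#' @importFrom Rcpp evalCpp
#' @useDynLib originatlas, .registration = TRUE
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific random seed from a global seed
#'
#' Deterministically maps a global integer seed and a stage name to a child
#' seed below 2^31, so that every stochastic stage of the pipeline receives
#' its own reproducible stream.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return A single integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(as.integer(charToRaw(stage)) * seq_along(charToRaw(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

## 0-based half-open BED interval -> IRanges (1-based closed)
bed_to_iranges <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

bed_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, bed_to_iranges(df$start, df$end))
}

## column SDs without the per-column closure overhead of apply()
matrixStats_colSds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt(pmax(0, (colSums(x^2) - n * mu^2) / (n - 1)))
}

check_bed <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$end <= df$start)) stop("malformed intervals: end <= start")
  invisible(df)
}
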