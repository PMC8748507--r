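#' Construct a toy genome with an annotated gene table
#'
#' Builds a small genome (default two 5 Mb chromosomes) with a table of genes
#' carrying TSS position, strand and genebody interval. Coordinates are
#' 0-based half-open throughout, following the BED convention. On the '+'
#' strand the TSS equals the genebody start; on the '-' strand it equals the
#' genebody end.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param n_genes Number of genes to place.
#' @param gene_length_range Range (bp) of genebody lengths, sampled uniformly.
#' @param seed Integer seed for gene placement.
#' @return An object of class `toy_genome`: a list with `chroms` (named
#'   lengths) and `genes` (data.frame: gene_id, chrom, tss, strand, start, end).
#' @export
toy_genome <- function(chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       n_genes = 200,
                       gene_length_range = c(5000, 30000),
                       seed = 1L) {
  if (length(chrom_lengths) == 0) stop("empty genome")
  stopifnot(all(chrom_lengths > 0), n_genes >= 1)
  set.seed(seed)
  chrom <- sample(names(chrom_lengths), n_genes, replace = TRUE,
                  prob = chrom_lengths / sum(chrom_lengths))
  len <- round(runif(n_genes, gene_length_range[1], gene_length_range[2]))
  start <- vapply(seq_len(n_genes), function(i) {
    floor(runif(1, 0, chrom_lengths[[chrom[i]]] - len[i]))
  }, numeric(1))
  end <- start + len
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(n_genes)),
    chrom = chrom,
    tss = ifelse(strand == "+", start, end),
    strand = strand,
    start = start,
    end = end,
    stringsAsFactors = FALSE
  )
  out <- list(chroms = chrom_lengths, genes = genes)
  class(out) <- "toy_genome"
  out
}

#' @export
#' @method print toy_genome
print.toy_genome <- function(x, ...) {
  cat("toy_genome:", length(x$chroms), "chromosomes,",
      sum(x$chroms) / 1e6, "Mb,", nrow(x$genes), "genes\n")
  invisible(x)
}

#' Lay out a peak catalogue over a toy genome
#'
#' Places non-overlapping peaks across the genome and partitions them into
#' disjoint cell-type-specific sets plus a shared (housekeeping) set. The
#' layout is a pure function of the genome and the seed, so fragment and
#' count-matrix simulators agree on peak identity.
#'
#' @param genome A [toy_genome()].
#' @param n_peaks Total number of peaks.
#' @param n_types Number of cell types.
#' @param specific_per_type Number of peaks specific to each type.
#' @param n_shared Number of housekeeping peaks accessible in all types.
#' @param peak_width Peak width in bp.
#' @param seed Integer seed.
#' @return data.frame: chrom, start, end, peak_id, role ("shared", "none" or
#'   a cell-type name).
#' @export
peak_layout <- function(genome, n_peaks = 2000, n_types = 3,
                        specific_per_type = 150, n_shared = 200,
                        peak_width = 500, seed = 1L) {
  stopifnot(inherits(genome, "toy_genome"))
  if (n_types * specific_per_type + n_shared > n_peaks)
    stop("specific + shared peaks exceed total peak count")
  set.seed(seed)
  per_chrom <- round(n_peaks * genome$chroms / sum(genome$chroms))
  per_chrom[length(per_chrom)] <- n_peaks - sum(per_chrom[-length(per_chrom)])
  rows <- lapply(seq_along(genome$chroms), function(ci) {
    L <- genome$chroms[[ci]]
    n <- per_chrom[ci]
    ## evenly spaced grid with jitter keeps peaks disjoint and in bounds
    slots <- floor(seq(peak_width, L - 2 * peak_width, length.out = n))
    jit <- floor(runif(n, 0, peak_width / 2))
    data.frame(chrom = names(genome$chroms)[ci], start = slots + jit,
               end = slots + jit + peak_width, stringsAsFactors = FALSE)
  })
  peaks <- do.call(rbind, rows)
  peaks <- peaks[order(peaks$chrom, peaks$start), ]
  peaks$peak_id <- sprintf("peak%05d", seq_len(nrow(peaks)))
  types <- sprintf("type%d", seq_len(n_types))
  role <- rep("none", nrow(peaks))
  idx <- sample(nrow(peaks), n_types * specific_per_type + n_shared)
  for (t in seq_len(n_types)) {
    role[idx[seq_len(specific_per_type) + (t - 1) * specific_per_type]] <- types[t]
  }
  role[idx[seq_len(n_shared) + n_types * specific_per_type]] <- "shared"
  peaks$role <- role
  rownames(peaks) <- NULL
  peaks
}
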