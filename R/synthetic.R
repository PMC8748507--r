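#' Simulation configuration for the synthetic kidney atlas
#'
#' Collects every tunable of the synthetic-data generators in one validated
#' object. Defaults emulate a desk-scale kidney atlas: three cell types with
#' nucleosome-banded fragment-size distributions, a background population of
#' low-depth aperiodic barcodes, bulk tumors that are noisy mixtures dominated
#' by one originating cell type, and a bulk expression cohort with the
#' 255/41/8 geometry (cohort size / minority subgroup / CIMP-labeled samples,
#' all CIMP inside the minority subgroup).
#'
#' @param seed Global integer seed; all generators are pure functions of
#'   (config, seed).
#' @param cells_per_type Named or unnamed integer vector, cells per type.
#' @param n_background Number of background (non-cell) barcodes.
#' @param specific_per_type Type-specific peaks per cell type.
#' @param n_shared Housekeeping peaks shared by all types.
#' @param n_peaks Total peaks in the catalogue.
#' @param depth_meanlog,depth_sdlog Log-normal parameters of genuine-cell
#'   fragment depth.
#' @param bg_depth_meanlog,bg_depth_sdlog Log-normal depth of background
#'   barcodes.
#' @param nucleosome_period Nucleosome repeat length in bp.
#' @param periodic_fraction Fraction of a genuine cell's fragments drawn from
#'   the nucleosomal (periodic) size components.
#' @param tss_fraction Fraction of genuine-cell fragments centered within
#'   +/-800 bp of a TSS.
#' @param type_fraction Fraction of genuine-cell fragments placed in
#'   type-specific or shared peaks (drives clusterability).
#' @param p_own,p_other,p_shared Accessibility probabilities of a
#'   type-specific peak in its own type / other types, and of shared peaks.
#' @param n_tumors_per_origin Integer vector, tumors per originating type
#'   (recycled over origin types).
#' @param origin_types Which cell types seed tumors (indices).
#' @param purity Mixing purity in (0.5, 1]: weight of the origin profile in
#'   the tumor mixture.
#' @param tumor_depth Total fragment count per bulk tumor sample.
#' @param n_private_peaks Tumor-private peaks absent from all normal types.
#' @param private_fraction Fraction of tumor reads falling in private peaks.
#' @param n_expr_genes Genes in the bulk expression matrix.
#' @param n_expr_samples Bulk expression cohort size.
#' @param subgroup_sizes Named vector c(a1 = ..., a2 = ...) of subgroup sizes.
#' @param n_markers Named vector c(a1 = ..., a2 = ...) of feature genes per
#'   subgroup.
#' @param expr_effect Log2 fold elevation of a subgroup's feature genes.
#' @param expr_sdlog Log-normal noise SD on expression.
#' @param n_cimp Number of CIMP-labeled samples.
#' @param cimp_host Subgroup hosting all CIMP labels ("a1" or "a2").
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       cells_per_type = c(type1 = 200, type2 = 200, type3 = 200),
                       n_background = 300,
                       specific_per_type = 150,
                       n_shared = 200,
                       n_peaks = 2000,
                       depth_meanlog = log(6000), depth_sdlog = 0.3,
                       bg_depth_meanlog = log(300), bg_depth_sdlog = 0.5,
                       nucleosome_period = 200,
                       periodic_fraction = 0.4,
                       tss_fraction = 0.25,
                       type_fraction = 0.35,
                       p_own = 0.6, p_other = 0.05, p_shared = 0.5,
                       n_tumors_per_origin = 12,
                       origin_types = c(1L, 2L),
                       purity = 0.8,
                       tumor_depth = 2e5,
                       n_private_peaks = 50,
                       private_fraction = 0.05,
                       n_expr_genes = 400,
                       n_expr_samples = 255,
                       subgroup_sizes = c(a1 = 214, a2 = 41),
                       n_markers = c(a1 = 25, a2 = 7),
                       expr_effect = 2,
                       expr_sdlog = 0.4,
                       n_cimp = 8,
                       cimp_host = "a2") {
  stopifnot(length(seed) == 1L, all(cells_per_type >= 1), n_background >= 0)
  if (purity <= 0.5 || purity > 1)
    stop("purity must lie in (0.5, 1] so the dominant origin is identifiable")
  if (sum(subgroup_sizes) != n_expr_samples)
    stop("subgroup sizes must sum to the cohort size")
  if (n_cimp > subgroup_sizes[[cimp_host]])
    stop("CIMP count exceeds host subgroup size")
  if (is.null(names(cells_per_type)))
    names(cells_per_type) <- sprintf("type%d", seq_along(cells_per_type))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

## nucleosome-banded insert-size sampler: sub-nucleosomal exponential plus
## Gaussians at 1x and 2x the repeat length for the periodic fraction
sample_insert_sizes <- function(n, periodic_fraction, period = 200) {
  if (n == 0) return(integer(0))
  comp <- runif(n)
  sizes <- numeric(n)
  free <- comp >= periodic_fraction
  sizes[free] <- 30 + stats::rexp(sum(free), rate = 1 / 55)
  per <- !free
  if (any(per)) {
    two <- runif(sum(per)) < 0.3
    mu <- ifelse(two, 2 * period, period)
    sdv <- ifelse(two, 35, 25)
    sizes[per] <- rnorm(sum(per), mu, sdv)
  }
  pmin(pmax(round(sizes), 20L), 1000L)
}

#' Simulate per-barcode ATAC fragment streams
#'
#' Generates deduplicated fragments for genuine cells of K types plus
#' aperiodic low-depth background barcodes. Genuine cells draw insert sizes
#' from a nucleosome-banded mixture (controlled by `periodic_fraction`),
#' concentrate a configurable fraction of fragments near TSSs and in their
#' type's specific peaks; background barcodes are aperiodic and near-uniform.
#'
#' @param genome A [toy_genome()].
#' @param config A [sim_config()].
#' @return List with `fragments` (data.frame: chrom, start, end, barcode),
#'   `barcodes` (data.frame: barcode, label ("cell"/"background"), cell_type),
#'   and `layout` (the [peak_layout()] used).
#' @export
simulate_fragments <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!inherits(genome, "toy_genome") || length(genome$chroms) == 0)
    stop("empty genome")
  set.seed(stage_seed(config$seed, "fragments"))
  layout <- peak_layout(genome, n_peaks = config$n_peaks,
                        n_types = length(config$cells_per_type),
                        specific_per_type = config$specific_per_type,
                        n_shared = config$n_shared, seed = config$seed)
  types <- names(config$cells_per_type)
  cells <- data.frame(
    barcode = sprintf("BC%05d", seq_len(sum(config$cells_per_type) + config$n_background)),
    label = rep(c("cell", "background"),
                c(sum(config$cells_per_type), config$n_background)),
    cell_type = c(rep(types, config$cells_per_type),
                  rep(NA_character_, config$n_background)),
    stringsAsFactors = FALSE
  )
  n_cells <- nrow(cells)
  depth <- ifelse(cells$label == "cell",
                  rlnorm(n_cells, config$depth_meanlog, config$depth_sdlog),
                  rlnorm(n_cells, config$bg_depth_meanlog, config$bg_depth_sdlog))
  depth <- pmax(1L, round(depth))

  chrom_names <- names(genome$chroms)
  chrom_len <- unname(genome$chroms)
  tss <- genome$genes

  one_barcode <- function(i) {
    n <- depth[i]
    genuine <- cells$label[i] == "cell"
    pf <- if (genuine) config$periodic_fraction else 0
    size <- sample_insert_sizes(n, pf, config$nucleosome_period)
    u <- runif(n)
    tfrac <- if (genuine) config$tss_fraction else 0.02
    pfrac <- if (genuine) config$type_fraction else 0
    src <- ifelse(u < tfrac, "tss", ifelse(u < tfrac + pfrac, "peak", "bg"))
    chrom <- character(n); start <- numeric(n)
    n_tss <- sum(src == "tss")
    if (n_tss > 0) {
      gi <- sample(nrow(tss), n_tss, replace = TRUE)
      chrom[src == "tss"] <- tss$chrom[gi]
      start[src == "tss"] <- tss$tss[gi] + round(runif(n_tss, -800, 800))
    }
    n_pk <- sum(src == "peak")
    if (n_pk > 0) {
      own <- layout[layout$role %in% c(cells$cell_type[i], "shared"), ]
      pi_ <- sample(nrow(own), n_pk, replace = TRUE)
      chrom[src == "peak"] <- own$chrom[pi_]
      start[src == "peak"] <- own$start[pi_] +
        floor(runif(n_pk, 0, own$end[pi_] - own$start[pi_]))
    }
    n_bg <- sum(src == "bg")
    if (n_bg > 0) {
      ci <- sample(length(chrom_names), n_bg, replace = TRUE,
                   prob = chrom_len / sum(chrom_len))
      chrom[src == "bg"] <- chrom_names[ci]
      start[src == "bg"] <- floor(runif(n_bg, 0, chrom_len[ci]))
    }
    start <- pmax(0, pmin(start, chrom_len[match(chrom, chrom_names)] - size - 1))
    data.table::data.table(chrom = chrom, start = as.integer(start),
                           end = as.integer(start + size),
                           barcode = cells$barcode[i])
  }
  frags <- data.table::rbindlist(lapply(seq_len(n_cells), one_barcode))
  ## PCR-style dedup: one record per (chrom, start, end, barcode)
  frags <- unique(frags, by = c("chrom", "start", "end", "barcode"))
  data.table::setorder(frags, chrom, start, end, barcode)
  list(fragments = as.data.frame(frags), barcodes = cells, layout = layout)
}

#' Simulate a peak-by-cell count matrix with planted cell types
#'
#' Each type-specific peak is accessible with probability `p_own` in its own
#' type and `p_other` elsewhere; housekeeping peaks are accessible in all
#' types. Accessible entries get counts 1 plus Poisson extra reads.
#'
#' @param genome A [toy_genome()].
#' @param config A [sim_config()].
#' @return List with `counts` (sparse dgCMatrix, peaks x cells), `peaks`
#'   (the layout data.frame), `cell_types` (named character vector by
#'   barcode).
#' @export
simulate_peak_matrix <- function(genome, config) {
  stopifnot(inherits(genome, "toy_genome"), inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "peak_matrix"))
  layout <- peak_layout(genome, n_peaks = config$n_peaks,
                        n_types = length(config$cells_per_type),
                        specific_per_type = config$specific_per_type,
                        n_shared = config$n_shared, seed = config$seed)
  if (any(layout$end > genome$chroms[layout$chrom]))
    stop("peak coordinates out of chromosome bounds")
  types <- names(config$cells_per_type)
  cell_types <- rep(types, config$cells_per_type)
  barcodes <- sprintf("CELL%05d", seq_along(cell_types))
  names(cell_types) <- barcodes
  P <- nrow(layout); N <- length(cell_types)
  prob <- matrix(0.01, P, length(types), dimnames = list(layout$peak_id, types))
  for (t in types) {
    prob[layout$role == t, ] <- config$p_other
    prob[layout$role == t, t] <- config$p_own
  }
  prob[layout$role == "shared", ] <- config$p_shared
  pm <- prob[, cell_types, drop = FALSE]
  acc <- matrix(rbinom(P * N, 1L, as.vector(pm)), P, N)
  extra <- matrix(rpois(P * N, 0.5), P, N)
  counts <- acc * (1L + extra)
  dimnames(counts) <- list(layout$peak_id, barcodes)
  list(counts = methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                        "generalMatrix"), "CsparseMatrix"),
       peaks = layout, cell_types = cell_types)
}

#' Simulate bulk tumor peak-count profiles as origin-dominated mixtures
#'
#' Each tumor draws `tumor_depth` reads from a multinomial whose peak
#' probabilities are `purity` times its originating type's mean profile plus
#' `1 - purity` times the average of the other types, with a small mass on
#' tumor-private peaks absent from every normal type.
#'
#' @param peak_sim Output of [simulate_peak_matrix()].
#' @param config A [sim_config()].
#' @param genome A [toy_genome()] (used to place private peaks).
#' @return List with `counts` (peaks x samples, includes private-peak rows),
#'   `peaks` (data.frame incl. private peaks), `origins` (named character
#'   vector of true origin per sample).
#' @export
simulate_bulk_tumors <- function(peak_sim, config, genome) {
  stopifnot(inherits(config, "sim_config"))
  if (config$purity <= 0.5) stop("purity <= 0.5: origin unidentifiable")
  set.seed(stage_seed(config$seed, "bulk_tumors"))
  types <- names(config$cells_per_type)
  profiles <- vapply(types, function(t) {
    Matrix::rowMeans(peak_sim$counts[, peak_sim$cell_types == t, drop = FALSE])
  }, numeric(nrow(peak_sim$counts)))
  profiles <- sweep(profiles, 2, colSums(profiles), "/")
  origin_types <- types[config$origin_types]
  n_per <- rep_len(config$n_tumors_per_origin, length(origin_types))
  origins <- rep(origin_types, n_per)
  n_samples <- length(origins)

  priv <- data.frame(
    chrom = rep(names(genome$chroms)[1], config$n_private_peaks),
    start = seq(100, by = 2000, length.out = config$n_private_peaks),
    end = seq(100, by = 2000, length.out = config$n_private_peaks) + 500,
    peak_id = sprintf("tumorpeak%04d", seq_len(config$n_private_peaks)),
    role = rep("tumor_private", config$n_private_peaks),
    stringsAsFactors = FALSE
  )
  P <- nrow(peak_sim$peaks); Q <- config$n_private_peaks
  counts <- matrix(0L, P + Q, n_samples)
  pf <- if (Q > 0) config$private_fraction else 0
  for (j in seq_len(n_samples)) {
    own <- profiles[, origins[j]]
    other <- rowMeans(profiles[, setdiff(types, origins[j]), drop = FALSE])
    p_norm <- config$purity * own + (1 - config$purity) * other
    p <- c((1 - pf) * p_norm, rep(pf / max(Q, 1), Q))
    counts[, j] <- rmultinom(1, config$tumor_depth, p)
  }
  samples <- sprintf("TUMOR%03d", seq_len(n_samples))
  dimnames(counts) <- list(c(peak_sim$peaks$peak_id, priv$peak_id), samples)
  names(origins) <- samples
  list(counts = counts, peaks = rbind(peak_sim$peaks, priv), origins = origins)
}

#' Simulate a bulk gene-expression cohort with a planted subgroup and CIMP labels
#'
#' Two subgroups (a1-like and a2-like analogues) each elevate their own
#' feature genes by `expr_effect` log2 units over log-normal noise; all CIMP
#' labels are placed inside the configured host subgroup.
#'
#' @param config A [sim_config()].
#' @return List with `expr` (gene x sample matrix, FPKM-like), `samples`
#'   (data.frame: sample, subgroup, cimp), `markers` (list of a1/a2 feature
#'   gene ids).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "expression"))
  G <- config$n_expr_genes; N <- config$n_expr_samples
  genes <- sprintf("exprgene%04d", seq_len(G))
  subgroup <- rep(names(config$subgroup_sizes), config$subgroup_sizes)
  subgroup <- sample(subgroup)  # shuffle sample order
  samples <- sprintf("S%03d", seq_len(N))
  markers <- list(
    a1 = genes[seq_len(config$n_markers[["a1"]])],
    a2 = genes[config$n_markers[["a1"]] + seq_len(config$n_markers[["a2"]])]
  )
  base <- rnorm(G, 3, 0.5)
  logexpr <- matrix(rnorm(G * N, 0, config$expr_sdlog), G, N) + base
  eff <- config$expr_effect * log(2)
  logexpr[match(markers$a1, genes), subgroup == "a1"] <-
    logexpr[match(markers$a1, genes), subgroup == "a1"] + eff
  logexpr[match(markers$a2, genes), subgroup == "a2"] <-
    logexpr[match(markers$a2, genes), subgroup == "a2"] + eff
  expr <- exp(logexpr)
  dimnames(expr) <- list(genes, samples)
  host <- which(subgroup == config$cimp_host)
  cimp_idx <- sample(host, config$n_cimp)
  cimp <- rep(FALSE, N); cimp[cimp_idx] <- TRUE
  list(expr = expr,
       samples = data.frame(sample = samples, subgroup = subgroup,
                            cimp = cimp, stringsAsFactors = FALSE),
       markers = markers)
}
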