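#' Append genebody accessibility rows to a peak-by-cell matrix
#'
#' For each gene, sums the counts of all peaks whose interval overlaps the
#' genebody and appends the result as a new row. The row is anchored at a
#' 300 bp interval around the TSS: `[TSS - 200, TSS + 100)` on the '+'
#' strand, mirrored (`[TSS - 100, TSS + 200)`) on the '-' strand. Genes with
#' no overlapping peak get a zero row (kept).
#'
#' @param mat Peak-by-cell count matrix; rownames are peak ids present in
#'   `peaks`.
#' @param peaks Peak coordinate data.frame (chrom, start, end, peak_id).
#' @param genome A [toy_genome()] supplying the gene table.
#' @return List: `mat` (augmented matrix; gene rows named by gene_id),
#'   `nodes` (data.frame chrom, start, end, id, kind = "peak"/"gene" for all
#'   rows; gene coordinates are the anchors).
#' @export
genebody_accessibility <- function(mat, peaks, genome) {
  stopifnot(inherits(genome, "toy_genome"))
  genes <- genome$genes
  if (any(genes$end > genome$chroms[genes$chrom]))
    stop("gene intervals outside genome")
  peaks <- peaks[match(rownames(mat), peaks$peak_id), ]
  pk_gr <- bed_to_granges(peaks)
  gene_gr <- bed_to_granges(genes)
  ov <- GenomicRanges::findOverlaps(gene_gr, pk_gr)
  gene_rows <- matrix(0, nrow(genes), ncol(mat),
                      dimnames = list(genes$gene_id, colnames(mat)))
  if (length(ov) > 0) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    for (g in unique(qh)) {
      gene_rows[g, ] <- Matrix::colSums(mat[sh[qh == g], , drop = FALSE])
    }
  }
  anchor_start <- ifelse(genes$strand == "+", genes$tss - 200, genes$tss - 100)
  nodes <- rbind(
    data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
               id = peaks$peak_id, kind = "peak", stringsAsFactors = FALSE),
    data.frame(chrom = genes$chrom, start = anchor_start,
               end = anchor_start + 300, id = genes$gene_id, kind = "gene",
               stringsAsFactors = FALSE))
  aug <- rbind(as.matrix(mat), gene_rows)
  list(mat = aug, nodes = nodes)
}

#' Aggregate cells into pseudo-cells by k-nearest neighbors
#'
#' Samples seed cells without replacement and sums each seed with its k-1
#' nearest neighbors in the embedding. Aggregates sharing more than 90% of
#' members with an earlier aggregate are dropped.
#'
#' @param mat Feature-by-cell matrix.
#' @param embedding Cell embedding (cells x components), rows aligned with
#'   columns of `mat`.
#' @param k Cells per aggregate.
#' @param n_aggregates Number of seed cells to draw (default `n_cells / 10`,
#'   at least 10).
#' @param max_overlap Drop threshold on shared-member fraction.
#' @param seed Integer seed.
#' @return Feature-by-aggregate matrix with attribute `members` (list of
#'   member indices).
#' @export
aggregate_cells <- function(mat, embedding, k = 30, n_aggregates = NULL,
                            max_overlap = 0.9, seed = 1L) {
  n <- ncol(mat)
  if (k > n) stop("k exceeds the number of cells")
  stopifnot(nrow(embedding) == n)
  set.seed(seed)
  n_aggregates <- n_aggregates %||% max(10L, floor(n / 10))
  n_aggregates <- min(n_aggregates, n)
  seeds <- sample(n, n_aggregates)
  nn <- if (k > 1) knn_indices(embedding, k - 1) else NULL
  members <- lapply(seeds, function(s) {
    if (k > 1) sort(c(s, nn[s, ])) else s
  })
  keep <- rep(TRUE, length(members))
  for (i in seq_along(members)[-1]) {
    for (j in seq_len(i - 1)) {
      if (!keep[j]) next
      shared <- length(intersect(members[[i]], members[[j]])) / k
      if (shared > max_overlap) { keep[i] <- FALSE; break }
    }
  }
  members <- members[keep]
  agg <- vapply(members, function(m) {
    if (length(m) > 1) Matrix::rowSums(mat[, m, drop = FALSE])
    else as.numeric(mat[, m])
  }, numeric(nrow(mat)))
  rownames(agg) <- rownames(mat)
  colnames(agg) <- sprintf("agg%03d", seq_along(members))
  attr(agg, "members") <- members
  agg
}

#' Distance-penalized co-accessibility network
#'
#' Slides 500 kb windows (step = the distance constraint) along each
#' chromosome. Within a window, node vectors (log1p counts across
#' aggregates) are standardized and their correlation matrix is fed to a
#' graphical lasso whose off-diagonal penalty grows linearly with genomic
#' distance, `rho_ij = penalty_scale * d_ij / constraint`, and is effectively
#' infinite beyond the constraint. Precision estimates are converted to
#' partial correlations; pairs scored in several windows are averaged.
#' Edges at or above `cutoff` form the network.
#'
#' @param agg Feature-by-aggregate matrix from [aggregate_cells()] (>= 10
#'   aggregates).
#' @param nodes Node coordinates (chrom, start, end, id) matching the rows.
#' @param window Window size in bp.
#' @param constraint Distance constraint in bp (also the window step).
#' @param penalty_scale Penalty at distance = constraint.
#' @param cutoff Score threshold for retained edges.
#' @return List: `edges` (data.frame node_a, node_b, score with score >=
#'   cutoff), `scores` (all averaged pair scores), `cutoff`.
#' @export
coaccessibility <- function(agg, nodes, window = 5e5, constraint = 2.5e5,
                            penalty_scale = 0.2, cutoff = 0.1) {
  if (ncol(agg) < 10) stop("need at least 10 aggregates")
  stopifnot(nrow(agg) == nrow(nodes))
  center <- (nodes$start + nodes$end) / 2
  chunks <- list()
  for (ch in unique(nodes$chrom)) {
    on_ch <- which(nodes$chrom == ch)
    if (length(on_ch) < 2) next
    lo <- min(center[on_ch]); hi <- max(center[on_ch])
    starts <- seq(floor(lo / constraint) * constraint - constraint, hi,
                  by = constraint)
    for (ws in starts) {
      in_win <- on_ch[center[on_ch] >= ws & center[on_ch] < ws + window]
      if (length(in_win) < 2) next
      X <- log1p(t(agg[in_win, , drop = FALSE]))
      keep <- matrixStats_colSds(X) > 0
      if (sum(keep) < 2) next
      in_win <- in_win[keep]
      X <- scale(X[, keep, drop = FALSE])
      S <- stats::cor(X)
      d <- abs(outer(center[in_win], center[in_win], "-"))
      rho <- penalty_scale * d / constraint
      rho[d > constraint] <- 1e6
      fit <- tryCatch(graphical_lasso(S, rho, tol = 1e-5, max_iter = 50),
                      error = function(e) NULL)
      if (is.null(fit)) { warning("window skipped: graphical lasso failed"); next }
      pc <- partial_correlations(fit$theta)
      ids <- nodes$id[in_win]
      lt <- which(lower.tri(pc) & d <= constraint, arr.ind = TRUE)
      if (nrow(lt) == 0) next
      a <- ids[lt[, 1]]; b <- ids[lt[, 2]]
      swap <- a > b
      chunks[[length(chunks) + 1L]] <- data.table::data.table(
        node_a = ifelse(swap, b, a), node_b = ifelse(swap, a, b),
        score = pc[lt])
    }
  }
  if (length(chunks) == 0) {
    scores <- data.frame(node_a = character(0), node_b = character(0),
                         score = numeric(0), stringsAsFactors = FALSE)
  } else {
    all_pairs <- data.table::rbindlist(chunks)
    scores <- all_pairs[, list(score = mean(score)), by = c("node_a", "node_b")]
    scores <- as.data.frame(scores[order(-score)])
  }
  list(edges = scores[scores$score >= cutoff, , drop = FALSE],
       scores = scores, cutoff = cutoff)
}

#' Gene activity from a co-accessibility network
#'
#' The raw activity of gene g in cell c is the genebody accessibility plus
#' the counts of every peak linked to g's anchor with a co-accessibility
#' score at or above the cutoff. Columns are then normalized to a fixed
#' total (counts per 10,000 per cell).
#'
#' @param network Output of [coaccessibility()].
#' @param aug Augmented matrix from [genebody_accessibility()] (`$mat`).
#' @param nodes Node table from [genebody_accessibility()].
#' @param cutoff Score cutoff for links (default the network's).
#' @param total Per-cell normalization total.
#' @return Gene-by-cell activity matrix, column-normalized.
#' @export
gene_activity <- function(network, aug, nodes, cutoff = NULL, total = 1e4) {
  cutoff <- cutoff %||% network$cutoff
  gene_ids <- nodes$id[nodes$kind == "gene"]
  ed <- network$scores
  ed <- ed[ed$score >= cutoff, , drop = FALSE]
  act <- matrix(0, length(gene_ids), ncol(aug),
                dimnames = list(gene_ids, colnames(aug)))
  peak_ids <- nodes$id[nodes$kind == "peak"]
  for (g in gene_ids) {
    linked <- union(ed$node_b[ed$node_a == g], ed$node_a[ed$node_b == g])
    linked <- intersect(linked, peak_ids)
    act[g, ] <- aug[g, ]
    if (length(linked) > 0)
      act[g, ] <- act[g, ] + colSums(aug[linked, , drop = FALSE])
  }
  cs <- colSums(act)
  cs[cs == 0] <- 1
  sweep(act, 2, cs, "/") * total
}
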