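#' Build a binary 5 kb window-by-cell matrix from fragments
#'
#' The genome is tiled with fixed-width windows (the last partial window is
#' kept). A window is 1 for a cell iff at least one Tn5 insertion site (a
#' fragment start or end coordinate) falls inside it.
#'
#' @param fragments Fragment data.frame (chrom, start, end, barcode), already
#'   restricted to retained barcodes.
#' @param genome A [toy_genome()].
#' @param window Window width in bp.
#' @return List: `mat` (sparse binary dgCMatrix, windows x cells), `windows`
#'   (data.frame chrom, start, end).
#' @export
build_window_matrix <- function(fragments, genome, window = 5000) {
  if (window <= 0) stop("window size must be positive")
  stopifnot(inherits(genome, "toy_genome"))
  wins <- do.call(rbind, lapply(seq_along(genome$chroms), function(ci) {
    L <- genome$chroms[[ci]]
    starts <- seq(0, L - 1, by = window)
    data.frame(chrom = names(genome$chroms)[ci], start = starts,
               end = pmin(starts + window, L), stringsAsFactors = FALSE)
  }))
  win_offset <- c(0, cumsum(ceiling(genome$chroms / window)))
  names(win_offset) <- c(names(genome$chroms), "..end")
  barcodes <- sort(unique(fragments$barcode))
  cell_idx <- match(fragments$barcode, barcodes)
  ## Tn5 cut sites: both fragment endpoints (0-based positions start and end)
  site <- c(fragments$start, fragments$end)
  chrom <- rep(fragments$chrom, 2)
  cell <- rep(cell_idx, 2)
  L <- unname(genome$chroms[chrom])
  site <- pmin(site, L - 1)
  widx <- win_offset[chrom] + floor(site / window) + 1
  ij <- unique(cbind(widx, cell))
  mat <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1,
                              dims = c(nrow(wins), length(barcodes)))
  rownames(mat) <- sprintf("%s:%d-%d", wins$chrom, wins$start, wins$end)
  colnames(mat) <- barcodes
  list(mat = mat, windows = wins)
}

#' Remove zero-coverage and abnormally high-coverage windows
#'
#' Drops windows covered in no cell, then removes the top `top_frac` of the
#' remaining windows by cell coverage. The removal quota is
#' `ceiling(top_frac * n_remaining)`; windows are ordered by (coverage
#' descending, window index ascending) and exactly the quota is removed, so
#' the result is deterministic under ties.
#'
#' @param mat Binary window-by-cell matrix (windows in rows).
#' @param top_frac Fraction of high-coverage windows to remove.
#' @return The filtered matrix, with attributes `n_zero` and `n_top` giving
#'   the removal counts.
#' @export
filter_windows <- function(mat, top_frac = 0.05) {
  if (nrow(mat) == 0 || ncol(mat) == 0) stop("empty matrix")
  cov <- Matrix::rowSums(mat > 0)
  nz <- cov > 0
  mat2 <- mat[nz, , drop = FALSE]
  cov2 <- cov[nz]
  quota <- ceiling(top_frac * nrow(mat2))
  drop_idx <- order(-cov2, seq_along(cov2))[seq_len(quota)]
  out <- mat2[-drop_idx, , drop = FALSE]
  attr(out, "n_zero") <- sum(!nz)
  attr(out, "n_top") <- quota
  out
}

#' Log TF-IDF weighting of a binary accessibility matrix
#'
#' Entry (i, j) becomes `ln(1 + 1e4 * tf * idf)` with
#' `tf = x_ij / colsum_j` and `idf = n_cells / rowsum_i`. All-zero cells and
#' all-zero windows are dropped with a warning (their tf or idf is
#' undefined).
#'
#' @param mat Binary window-by-cell sparse matrix.
#' @param scale_factor Scale constant inside the log (default 1e4).
#' @return Weighted sparse matrix.
#' @export
log_tfidf <- function(mat, scale_factor = 1e4) {
  cs <- Matrix::colSums(mat)
  if (any(cs == 0)) {
    warning(sum(cs == 0), " all-zero cells dropped")
    mat <- mat[, cs > 0, drop = FALSE]
    cs <- cs[cs > 0]
  }
  rs <- Matrix::rowSums(mat)
  if (any(rs == 0)) {
    warning(sum(rs == 0), " all-zero windows dropped")
    mat <- mat[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  n <- ncol(mat)
  x <- methods::as(methods::as(mat, "generalMatrix"), "CsparseMatrix")
  ## column-major traversal of non-zeros
  jj <- rep(seq_len(ncol(x)), diff(x@p))
  ii <- x@i + 1L
  x@x <- log1p(scale_factor * (x@x / cs[jj]) * (n / rs[ii]))
  x
}

#' Latent semantic analysis embedding of the weighted window matrix
#'
#' Truncated SVD to `d` components; cell embeddings are the right singular
#' vectors scaled by the singular values. The first component tracks
#' sequencing depth and is excluded downstream (components 2..d feed the KNN
#' graph).
#'
#' @param mat Weighted window-by-cell matrix.
#' @param d Number of components (default 40).
#' @return List: `embedding` (cells x d), `d_vals` (singular values), `keep`
#'   (integer vector of components used for the graph, 2..d).
#' @export
lsa_reduce <- function(mat, d = 40) {
  if (d >= min(dim(mat))) stop("d must be below both matrix dimensions")
  sv <- svd(as.matrix(mat), nu = 0, nv = d)
  emb <- sweep(sv$v, 2, sv$d[seq_len(d)], "*")
  rownames(emb) <- colnames(mat)
  colnames(emb) <- sprintf("LSI%d", seq_len(d))
  list(embedding = emb, d_vals = sv$d[seq_len(d)], keep = 2:d)
}

## k-nearest-neighbor indices (excluding self) by Euclidean distance
knn_indices <- function(emb, k) {
  dmat <- as.matrix(dist(emb))
  diag(dmat) <- Inf
  t(apply(dmat, 1, function(r) order(r)[seq_len(k)]))
}

#' KNN graph with shared-neighbor Jaccard edge weights
#'
#' @param emb Cell embedding matrix (cells x components).
#' @param k Neighbors per cell.
#' @return An igraph undirected weighted graph.
#' @export
knn_graph <- function(emb, k = 15) {
  n <- nrow(emb)
  if (k >= n) stop("k must be smaller than the number of cells")
  nn <- knn_indices(emb, k)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  w <- vapply(seq_len(nrow(edges)), function(e) {
    a <- sets[[edges[e, 1]]]; b <- sets[[edges[e, 2]]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  igraph::V(g)$name <- rownames(emb)
  g
}

#' Louvain modularity clustering with a small-cluster floor
#'
#' Runs Louvain community detection at the given resolution on the weighted
#' KNN graph and marks clusters of `min_cells` cells or fewer as unassigned
#' (`NA`); only clusters with more than `min_cells` cells are retained.
#'
#' @param graph igraph from [knn_graph()].
#' @param resolution Louvain resolution.
#' @param min_cells Retention floor: clusters must exceed this size.
#' @param seed Seed for the Louvain heuristic.
#' @return Named integer vector of cluster labels (NA = unassigned),
#'   renumbered 1..K by decreasing size.
#' @export
louvain_cluster <- function(graph, resolution = 1, min_cells = 50, seed = 1L) {
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, resolution = resolution)
  memb <- igraph::membership(cl)
  tab <- sort(table(memb), decreasing = TRUE)
  keep <- names(tab)[tab > min_cells]
  out <- rep(NA_integer_, length(memb))
  for (i in seq_along(keep)) out[memb == as.integer(keep[i])] <- i
  names(out) <- names(memb)
  out
}

#' End-to-end LSA clustering of retained barcodes
#'
#' Convenience wrapper: window matrix, window filtering, log TF-IDF, SVD,
#' KNN graph on components 2..d, Louvain clustering, small-cluster removal.
#'
#' @param fragments Fragments of retained barcodes.
#' @param genome A [toy_genome()].
#' @param window Window size (bp).
#' @param d SVD components.
#' @param k KNN neighbors.
#' @param resolution Louvain resolution.
#' @param min_cells Cluster retention floor.
#' @param seed Seed.
#' @return List: `clusters` (named vector), `embedding`, `graph`.
#' @export
lsa_cluster_cells <- function(fragments, genome, window = 5000, d = 40,
                              k = 15, resolution = 1, min_cells = 50,
                              seed = 1L) {
  wm <- build_window_matrix(fragments, genome, window)
  fm <- filter_windows(wm$mat)
  tf <- log_tfidf(fm)
  red <- lsa_reduce(tf, d = min(d, min(dim(tf)) - 1))
  g <- knn_graph(red$embedding[, red$keep, drop = FALSE], k = k)
  cl <- louvain_cluster(g, resolution = resolution, min_cells = min_cells,
                        seed = seed)
  list(clusters = cl, embedding = red$embedding, graph = g)
}
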