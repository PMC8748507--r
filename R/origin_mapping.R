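#' Correlate bulk tumor samples with cell-type pseudo-profiles
#'
#' Computes the Pearson correlation of each (sample, cell subtype) pair over
#' a shared variable-peak set, averages subtype correlations within each
#' cell-type group, and splits samples into two candidate-origin groups by
#' hierarchical clustering of the correlation rows (correlation distance,
#' average linkage, cut at 2).
#'
#' Both matrices must already be normalized (log-CPM + quantile) and carry
#' the same peak rownames.
#'
#' @param tumor_mat Normalized peaks x samples matrix.
#' @param celltype_mat Normalized peaks x subtypes matrix.
#' @param peaks Character vector of shared variable peaks (>= 3).
#' @param subtype_groups Named character vector mapping each column of
#'   `celltype_mat` to a cell-type group; defaults to identity.
#' @return List: `cor` (samples x subtypes), `group_cor` (samples x groups),
#'   `sample_groups` (integer 1/2 per sample), `argmax` (best group per
#'   sample).
#' @export
correlate_samples_celltypes <- function(tumor_mat, celltype_mat, peaks,
                                        subtype_groups = NULL) {
  peaks <- intersect(peaks, intersect(rownames(tumor_mat), rownames(celltype_mat)))
  if (length(peaks) < 3) stop("fewer than 3 shared peaks")
  tm <- tumor_mat[peaks, , drop = FALSE]
  cm <- celltype_mat[peaks, , drop = FALSE]
  cc <- cor(tm, cm)  # samples x subtypes
  if (is.null(subtype_groups))
    subtype_groups <- setNames(colnames(cm), colnames(cm))
  groups <- unique(unname(subtype_groups))
  gc <- vapply(groups, function(g) {
    rowMeans(cc[, names(subtype_groups)[subtype_groups == g], drop = FALSE])
  }, numeric(nrow(cc)))
  if (is.null(dim(gc))) gc <- matrix(gc, nrow = nrow(cc),
                                     dimnames = list(rownames(cc), groups))
  sample_groups <- if (nrow(gc) >= 2) {
    d <- as.dist(1 - cor(t(gc)))
    cutree(hclust(d, method = "average"), k = 2)
  } else setNames(1L, rownames(gc))
  list(cor = cc, group_cor = gc, sample_groups = sample_groups,
       argmax = colnames(gc)[max.col(gc, ties.method = "first")])
}

#' Build a pseudo-bulk reference panel from a peak-by-cell matrix
#'
#' For each cell type, samples `cells_per_rep` cells `reps` times and sums
#' their counts into replicate columns, then applies log-CPM and quantile
#' normalization. Types with fewer than `cells_per_rep` cells are sampled
#' with replacement, with a warning.
#'
#' @param mat Peak-by-cell count matrix.
#' @param labels Cell-type label per cell.
#' @param cells_per_rep Cells summed per replicate (default 50).
#' @param reps Replicates per type (default 20).
#' @param seed Integer seed.
#' @param prior Prior count for log-CPM.
#' @return List: `panel` (normalized peaks x replicates), `raw` (raw sums),
#'   `labels` (type per replicate column).
#' @export
build_pseudobulk_panel <- function(mat, labels, cells_per_rep = 50, reps = 20,
                                   seed = 1L, prior = 5) {
  stopifnot(ncol(mat) == length(labels))
  set.seed(seed)
  types <- sort(unique(as.character(labels)))
  cols <- list(); col_lab <- character(0)
  for (t in types) {
    idx <- which(labels == t)
    if (length(idx) == 0) stop("empty cell type: ", t)
    replace <- length(idx) < cells_per_rep
    if (replace) warning("type ", t, " has fewer than ", cells_per_rep,
                         " cells; sampling with replacement")
    for (r in seq_len(reps)) {
      pick <- sample(idx, cells_per_rep, replace = replace)
      cols[[length(cols) + 1L]] <- Matrix::rowSums(mat[, pick, drop = FALSE])
      col_lab <- c(col_lab, t)
    }
  }
  raw <- do.call(cbind, cols)
  dimnames(raw) <- list(rownames(mat),
                        sprintf("%s_rep%02d", col_lab,
                                unlist(lapply(types, function(t) seq_len(reps)))))
  panel <- quantile_normalize(logcpm_normalize(raw, prior = prior))
  list(panel = panel, raw = raw, labels = col_lab)
}

#' Train one-vs-rest offset logistic similarity models
#'
#' For each cell type, fits an L1-regularized binomial logistic regression of
#' replicate identity on the reduced peak features, with a fixed
#' per-observation training offset `log(f / (1 - f))` where `f` is the
#' type's fraction of cells in the reference. The regularization strength is
#' the largest lambda whose 10-fold cross-validated deviance is within one
#' standard error of the minimum. Prediction later uses offset 0.
#'
#' @param panel Normalized pseudo-bulk panel (peaks x replicates).
#' @param labels Type per replicate column.
#' @param features Character vector of feature peaks (rows of `panel`).
#' @param cell_fractions Optional named numeric of true per-type cell
#'   fractions f; defaults to replicate fractions.
#' @param nfolds Cross-validation folds.
#' @param seed Integer seed (controls fold assignment).
#' @return Named list of `similarity_model` objects (one per type) with
#'   elements `type`, `f`, `offset`, `lambda`, `fit`, `features`.
#' @export
train_similarity_models <- function(panel, labels, features,
                                    cell_fractions = NULL, nfolds = 10,
                                    seed = 1L) {
  features <- intersect(features, rownames(panel))
  if (length(features) < 2) stop("need at least 2 feature peaks")
  x <- t(panel[features, , drop = FALSE])
  types <- sort(unique(labels))
  if (any(table(labels) < 2)) stop("a type with a single replicate")
  models <- list()
  for (t in types) {
    y <- as.integer(labels == t)
    f <- if (!is.null(cell_fractions)) cell_fractions[[t]] else mean(y)
    off <- rep(log(f / (1 - f)), nrow(x))
    set.seed(stage_seed(seed, paste0("cv_", t)))
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                            offset = off, nfolds = nfolds,
                            standardize = TRUE)
    m <- list(type = t, f = f, offset = log(f / (1 - f)),
              lambda = cv$lambda.1se, fit = cv, features = features)
    class(m) <- "similarity_model"
    models[[t]] <- m
  }
  models
}

#' Predict similarity scores for bulk samples
#'
#' Applies each trained model with offset 0: score = logistic(x'beta +
#' intercept). Samples must be normalized the same way as the training
#' panel and contain all model features.
#'
#' @param models List from [train_similarity_models()].
#' @param tumor_mat Normalized peaks x samples matrix.
#' @return List: `scores` (samples x types in [0,1]), `argmax` (best type
#'   per sample).
#' @export
predict_similarity <- function(models, tumor_mat) {
  feats <- models[[1]]$features
  if (!all(feats %in% rownames(tumor_mat))) stop("feature mismatch")
  newx <- t(tumor_mat[feats, , drop = FALSE])
  scores <- vapply(models, function(m) {
    as.vector(predict(m$fit, newx = newx, s = m$lambda,
                      newoffset = rep(0, nrow(newx)), type = "response"))
  }, numeric(nrow(newx)))
  if (is.null(dim(scores)))
    scores <- matrix(scores, nrow = nrow(newx),
                     dimnames = list(rownames(newx), names(models)))
  rownames(scores) <- rownames(newx)
  list(scores = scores,
       argmax = colnames(scores)[max.col(scores, ties.method = "first")])
}
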