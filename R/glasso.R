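#' Graphical lasso with an element-wise penalty matrix
#'
#' Estimates a sparse inverse covariance matrix by the block coordinate
#' descent algorithm of Friedman, Hastie and Tibshirani: each column of the
#' working covariance W is updated by solving an L1-penalized regression via
#' cycling coordinate descent (compiled code). The penalty may differ per
#' element (`rho` a matrix), which is how distance-dependent
#' co-accessibility penalties enter. With all penalties 0 the estimate
#' converges to the ordinary inverse of `S`.
#'
#' @param S Sample covariance (or correlation) matrix, symmetric PD-ish.
#' @param rho Scalar penalty or symmetric penalty matrix (diagonal ignored).
#' @param tol Convergence tolerance on the mean absolute change of W
#'   (relative to the mean absolute off-diagonal of `S`).
#' @param max_iter Maximum outer sweeps.
#' @return List: `w` (estimated covariance), `theta` (sparse precision
#'   matrix), `iterations`, `converged`.
#' @export
graphical_lasso <- function(S, rho = 0, tol = 1e-8, max_iter = 200) {
  S <- as.matrix(S)
  p <- nrow(S)
  stopifnot(p == ncol(S))
  if (length(rho) == 1) rho <- matrix(rho, p, p)
  stopifnot(all(dim(rho) == p))
  if (p == 1) {
    theta <- matrix(1 / S[1, 1], 1, 1, dimnames = dimnames(S))
    return(list(w = S, theta = theta, iterations = 0L, converged = TRUE))
  }
  fit <- .glasso_cpp(S, rho, tol, as.integer(max_iter), 1e-10, 1000L)
  W <- fit$w
  B <- fit$B
  ## recover the precision matrix from the final regressions
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    beta <- B[idx, j]
    t22 <- 1 / (W[j, j] - sum(W[idx, j] * beta))
    Theta[j, j] <- t22
    Theta[idx, j] <- -beta * t22
  }
  Theta <- (Theta + t(Theta)) / 2
  dimnames(W) <- dimnames(Theta) <- dimnames(S)
  list(w = W, theta = Theta, iterations = fit$iterations,
       converged = fit$converged)
}

#' Partial correlations from a precision matrix
#'
#' @param theta Precision (inverse covariance) matrix.
#' @return Matrix of partial correlations: `-theta_ij / sqrt(theta_ii *
#'   theta_jj)` off-diagonal, 1 on the diagonal.
#' @export
partial_correlations <- function(theta) {
  d <- sqrt(diag(theta))
  pc <- -theta / outer(d, d)
  diag(pc) <- 1
  pc
}
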