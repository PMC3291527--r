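# Robust PCA: decomposition of a patch matrix into a low-rank "typical"
# part L and an entrywise-sparse "atypical" part S by an inexact
# augmented-Lagrangian iteration, plus the plain-PCA baseline and the
# rank/weight diagnostics used in lambda-prime sweeps.

#' Soft-thresholding (shrinkage) operator
#'
#' `sign(x) * max(|x| - tau, 0)` applied entrywise; the proximal operator
#' of the l1 norm.
#'
#' @param x numeric scalar, vector or matrix.
#' @param tau nonnegative threshold.
#' @return Same shape as `x`.
#' @export
shrink <- function(x, tau) {
  if (tau < 0) stopf("tau must be nonnegative")
  sign(x) * pmax(abs(x) - tau, 0)
}

#' Singular value thresholding operator
#'
#' Applies [shrink()] to the singular values: `U shrink(Sigma, tau) V'`
#' for any SVD `X = U Sigma V'`; the proximal operator of the nuclear norm.
#'
#' @param X numeric matrix with finite entries.
#' @param tau nonnegative threshold.
#' @return Matrix of the same shape as `X`.
#' @export
svt <- function(X, tau) {
  if (tau < 0) stopf("tau must be nonnegative")
  check_finite(X, "X")
  sv <- svd(X)
  d <- shrink(sv$d, tau)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(X), ncol(X)))
  sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Reference value of the sparsity trade-off
#'
#' The reference `lambda_ref = 1/sqrt(max(n1, n2))` against which the
#' trade-off is normalized: `lambda_abs = lambda_norm * lambda_ref`
#' everywhere in this package, so `lambda_norm = 1` is the theoretical
#' default of the exact-recovery guarantee.
#'
#' @param n1,n2 matrix dimensions (>= 1).
#' @return Positive scalar.
#' @export
reference_lambda <- function(n1, n2) {
  if (n1 < 1L || n2 < 1L) stopf("dimensions must be >= 1")
  1 / sqrt(max(n1, n2))
}

#' Robust principal component decomposition M ~ L + S
#'
#' Minimizes `||L||_* + lambda ||S||_1` subject to `M = L + S` by the
#' inexact augmented-Lagrangian method: each outer iteration performs one
#' singular-value-thresholding update of L, one shrinkage update of S and a
#' dual ascent step on the multiplier Y, with the penalty mu grown
#' geometrically. Iteration stops when the relative constraint violation
#' `||M - L - S||_F / ||M||_F` drops below `tol`.
#'
#' @param M numeric matrix or [patch_matrix].
#' @param lambda_norm normalized trade-off `lambda' = lambda / lambda_ref`
#'   (see [reference_lambda()]); 1 is the theoretical default, larger values
#'   suppress S.
#' @param tol relative constraint-violation tolerance. Default `1e-7`.
#' @param max_iter outer-iteration cap. Default 500; hitting it returns the
#'   current iterate with `converged = FALSE` and a warning.
#' @param mu_growth geometric growth factor of the penalty. Default 1.5.
#' @return An object of class `rpca_result`: `L`, `S`, `lambda_abs`,
#'   `lambda_norm`, `iterations`, `constraint_violation`, `converged`, and
#'   `trace` (per-iteration constraint violations).
#' @export
rpca_decompose <- function(M, lambda_norm = 1, tol = 1e-7, max_iter = 500L,
                           mu_growth = 1.5) {
  M <- as_data_matrix(M)
  check_finite(M, "M")
  if (lambda_norm <= 0) stopf("lambda_norm must be positive")
  n1 <- nrow(M); n2 <- ncol(M)
  lambda <- lambda_norm * reference_lambda(n1, n2)
  normM <- fnorm(M)
  if (normM == 0) {
    return(structure(list(L = M, S = M, lambda_abs = lambda,
                          lambda_norm = lambda_norm, iterations = 0L,
                          constraint_violation = 0, converged = TRUE,
                          trace = numeric(0)),
                     class = "rpca_result"))
  }
  # Scale-free warm start for the dual variable; penalty starts at
  # 1.25 / sigma_max(M), the usual inexact-ALM choice (a fixed-penalty
  # start of order n1*n2/||M||_1 pairs badly with geometric growth: the
  # iteration then reaches feasibility before the thresholds have had a
  # chance to separate L from S).
  sigma_max <- svd(M, nu = 0, nv = 0)$d[1]
  Y <- M / max(sigma_max, max(abs(M)) / lambda)
  mu0 <- 1.25 / sigma_max
  mu <- mu0
  S <- matrix(0, n1, n2)
  L <- matrix(0, n1, n2)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    L <- svt(M - S + Y / mu, 1 / mu)
    S <- shrink(M - L + Y / mu, lambda / mu)
    R <- M - L - S
    Y <- Y + mu * R
    mu <- min(mu * mu_growth, 1e7 * mu0)
    viol <- fnorm(R) / normM
    trace <- c(trace, viol)
    if (viol <= tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("RPCA did not reach tol = %g in %d iterations (violation %g)",
                    tol, max_iter, trace[length(trace)]))
  }
  structure(list(L = L, S = S, lambda_abs = lambda, lambda_norm = lambda_norm,
                 iterations = it, constraint_violation = trace[length(trace)],
                 converged = converged, trace = trace),
            class = "rpca_result")
}

#' @export
print.rpca_result <- function(x, ...) {
  cat(sprintf("<rpca_result> %d x %d, lambda' = %g, %d iterations, ||M-L-S||_F/||M||_F = %.3g%s\n",
              nrow(x$L), ncol(x$L), x$lambda_norm, x$iterations,
              x$constraint_violation,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' PCA baseline: project data out of the leading principal subspace
#'
#' Classical (non-robust) counterpart of [rpca_decompose()]: the top `d`
#' left singular vectors of the column-centered data span the "typical"
#' subspace, and the residuals are the data with that subspace projected
#' out. Useful as the prefiltering baseline that robust decomposition is
#' compared against.
#'
#' @param M numeric matrix or [patch_matrix] (`n x T`, samples in columns).
#' @param d retained dimension, `0 <= d <= min(n, T)`.
#' @return An object of class `pca_baseline`: `basis` (`n x d`,
#'   orthonormal), `residuals` (`n x T`), `d`, and `center` (the mean
#'   column that was removed).
#' @export
pca_prefilter <- function(M, d) {
  M <- as_data_matrix(M)
  n <- nrow(M); T_ <- ncol(M)
  if (d < 0L || d > min(n, T_)) stopf("d must lie in [0, min(n, T)] = [0, %d]",
                                      min(n, T_))
  center <- rowMeans(M)
  Mc <- M - center
  if (d == 0L) {
    basis <- matrix(0, n, 0L)
    resid <- Mc
  } else {
    sv <- svd(Mc, nu = d, nv = 0)
    basis <- sv$u
    resid <- Mc - basis %*% (t(basis) %*% Mc)
  }
  structure(list(basis = basis, residuals = resid, d = as.integer(d),
                 center = center),
            class = "pca_baseline")
}

#' Numerical rank by singular-value thresholding
#'
#' Counts singular values at or above `threshold_fraction` times the
#' largest one; the "intrinsic dimension" diagnostic reported over
#' lambda-prime sweeps.
#'
#' @param L numeric matrix.
#' @param threshold_fraction fraction of the maximal singular value, in
#'   `(0, 1)`. Default 0.01.
#' @return Integer rank estimate (0 for a zero matrix).
#' @export
estimate_rank <- function(L, threshold_fraction = 0.01) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1) {
    stopf("threshold_fraction must lie in (0, 1)")
  }
  d <- svd(L, nu = 0, nv = 0)$d
  if (length(d) == 0L || d[1] == 0) return(0L)
  sum(d >= threshold_fraction * d[1])
}

#' Relative weight of the low-rank part in a decomposition
#'
#' Frobenius-energy share `||L||_F / (||L||_F + ||M - L||_F)`: 1 when L
#' carries the whole signal, 0 when it carries none. Reported alongside
#' [estimate_rank()] in lambda-prime sweeps.
#'
#' @param L low-rank part.
#' @param M original matrix (same shape, not all-zero).
#' @return Fraction in `[0, 1]`.
#' @export
lowrank_weight <- function(L, M) {
  L <- as_data_matrix(L); M <- as_data_matrix(M)
  if (!all(dim(L) == dim(M))) stopf("L and M must have the same shape")
  if (all(M == 0)) stopf("M is all-zero; relative weight undefined")
  nl <- fnorm(L)
  nl / (nl + fnorm(M - L))
}
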