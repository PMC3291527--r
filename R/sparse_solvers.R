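# Sparse-encoding algorithms: Subspace Pursuit (greedy support refinement),
# the Cross-Entropy method over Bernoulli support distributions, and their
# combination SCE, in which each Cross-Entropy round is steered by a
# Subspace-Pursuit-style backprojection of the current residual.

#' Sparse code container
#'
#' @param support integer indices of active dictionary columns.
#' @param coefficients coefficients aligned with `support`.
#' @param residual_norm l2 norm of `y - A[, support] %*% coefficients`.
#' @param iterations solver iterations spent.
#' @param degenerate `TRUE` when the selected columns were rank deficient
#'   and a minimum-norm solution was returned.
#' @return Object of class `sparse_code`.
#' @export
sparse_code <- function(support, coefficients, residual_norm,
                        iterations = 0L, degenerate = FALSE) {
  structure(list(support = as.integer(support),
                 coefficients = as.numeric(coefficients),
                 residual_norm = as.numeric(residual_norm),
                 iterations = as.integer(iterations),
                 degenerate = isTRUE(degenerate)),
            class = "sparse_code")
}

#' @export
print.sparse_code <- function(x, ...) {
  cat(sprintf("<sparse_code> |support| = %d, residual = %.4g (%d iterations)%s\n",
              length(x$support), x$residual_norm, x$iterations,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Moore-Penrose pseudoinverse via SVD.
pinv <- function(A, tol = NULL) {
  sv <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, keep, drop = FALSE] %*% ((1 / sv$d[keep]) * t(sv$u[, keep, drop = FALSE]))
}

#' Minimum-norm least squares restricted to a support
#'
#' Solves `min ||y - A[, support] b||_2` over `b`, returning the
#' minimum-norm solution when the selected columns are rank deficient
#' (flagged via `degenerate`).
#'
#' @param A dictionary object or `n x m` matrix.
#' @param y length-`n` signal.
#' @param support nonempty set of valid column indices.
#' @return list with `coefficients`, `residual` (length-`n` vector),
#'   `residual_norm`, `degenerate`.
#' @export
least_squares_on_support <- function(A, y, support) {
  Amat <- dict_matrix(A)
  support <- as.integer(support)
  if (length(support) == 0L) stopf("support must be nonempty")
  if (any(support < 1L) || any(support > ncol(Amat))) {
    stopf("support indices out of range [1, %d]", ncol(Amat))
  }
  sub <- Amat[, support, drop = FALSE]
  sv <- svd(sub)
  tol <- max(dim(sub)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > tol
  degenerate <- sum(keep) < length(support)
  if (!any(keep)) {
    coef <- numeric(length(support))
  } else {
    coef <- sv$v[, keep, drop = FALSE] %*%
      ((1 / sv$d[keep]) * (t(sv$u[, keep, drop = FALSE]) %*% y))
    coef <- as.numeric(coef)
  }
  resid <- as.numeric(y - sub %*% coef)
  list(coefficients = coef, residual = resid,
       residual_norm = fnorm(resid), degenerate = degenerate)
}

#' Subspace Pursuit sparse recovery
#'
#' Greedy solver that maintains a `K`-element candidate support. The
#' initial support holds the `K` largest-amplitude coordinates of the
#' backprojected signal; each iteration (i) backprojects the residual,
#' (ii) expands the support with the `expansion_size` largest-amplitude
#' coordinates, (iii) solves least squares on the enlarged set,
#' (iv) shrinks back to the `K` largest coefficients and recomputes the
#' residual. Iteration stops when the residual norm fails to decrease (the
#' previous support is restored), reaches zero, or `max_iter` is hit.
#'
#' Backprojection is the minimum-norm pseudoinverse map by default;
#' `backprojection = "correlation"` uses the classical `A' r` correlations,
#' which is much cheaper for large dictionaries.
#'
#' @param A dictionary object or matrix with unit-norm columns.
#' @param y length-`n` signal.
#' @param K target sparsity, `1 <= K <= n`.
#' @param max_iter iteration cap. Default 100.
#' @param backprojection `"pinv"` (default) or `"correlation"`.
#' @param expansion_size candidates added per iteration. Default `K`.
#' @return A [sparse_code()]; attribute `residual_trace` holds the accepted
#'   residual norms (initialization first).
#' @export
subspace_pursuit <- function(A, y, K, max_iter = 100L,
                             backprojection = c("pinv", "correlation"),
                             expansion_size = K) {
  Amat <- dict_matrix(A)
  backprojection <- match.arg(backprojection)
  n <- nrow(Amat); m <- ncol(Amat)
  if (K < 1L || K > n) stopf("K must lie in [1, n] = [1, %d]", n)
  y <- as.numeric(y)
  B <- if (backprojection == "pinv") pinv(Amat) else t(Amat)
  ztol <- 1e-12 * max(1, fnorm(y))

  supp <- sort(top_k_abs(as.numeric(B %*% y), K))
  fit <- least_squares_on_support(Amat, y, supp)
  rn <- fit$residual_norm
  trace <- rn
  it <- 0L
  while (rn > ztol && it < max_iter) {
    it <- it + 1L
    bp <- as.numeric(B %*% fit$residual)
    expanded <- sort(union(supp, top_k_abs(bp, expansion_size)))
    wide <- least_squares_on_support(Amat, y, expanded)
    new_supp <- sort(expanded[top_k_abs(wide$coefficients, K)])
    new_fit <- least_squares_on_support(Amat, y, new_supp)
    if (new_fit$residual_norm >= rn) break  # no improvement: keep previous set
    supp <- new_supp; fit <- new_fit; rn <- new_fit$residual_norm
    trace <- c(trace, rn)
  }
  out <- sparse_code(supp, fit$coefficients, rn, iterations = it,
                     degenerate = fit$degenerate)
  attr(out, "residual_trace") <- trace
  out
}

#' Bernoulli support distribution
#'
#' Inclusion probabilities over dictionary columns, as maintained by the
#' Cross-Entropy method. Probabilities are clipped to `[eps, 1 - eps]`
#' (default `eps = 1e-3`) so no coordinate is ever frozen.
#'
#' @param p length-`m` vector of inclusion probabilities.
#' @param eps clipping bound.
#' @return Object of class `bernoulli_support` with fields `p`,
#'   `expected_actives` (= `sum(p)`), `eps`.
#' @export
bernoulli_support <- function(p, eps = 1e-3) {
  p <- pmin(pmax(as.numeric(p), eps), 1 - eps)
  structure(list(p = p, expected_actives = sum(p), eps = eps),
            class = "bernoulli_support")
}

# Clip to [eps, 1-eps] and rescale so that sum(p) = K; alternates the two
# until both hold (multiplicative rescaling of the unclipped mass).
renormalize_bernoulli <- function(p, K, eps = 1e-3) {
  m <- length(p)
  if (K <= m * eps || K >= m * (1 - eps)) {
    stopf("target expected actives K = %g infeasible for m = %d with eps = %g",
          K, m, eps)
  }
  for (i in 1:200) {
    p <- pmin(pmax(p, eps), 1 - eps)
    s <- sum(p)
    if (abs(s - K) < 1e-9) break
    p <- p * (K / s)
  }
  pmin(pmax(p, eps), 1 - eps)
}

#' Cross-Entropy method configuration
#'
#' Hyperparameters of the Cross-Entropy optimizer: samples drawn per
#' iteration, the elite fraction retained, the smoothing weight `alpha` of
#' the distribution update, the iteration cap, and the patience (iterations
#' without best-score improvement) before early stopping. `target`, when
#' finite, stops the search as soon as the best score reaches it.
#'
#' @param n_samples samples per iteration. Default 1000.
#' @param elite_fraction fraction of top-scoring samples used for the
#'   update, in `(0, 1)`. Default 0.05.
#' @param alpha smoothing weight in `(0, 1]`. Default 0.7.
#' @param max_iterations iteration cap. Default 50.
#' @param stagnation_patience early-stop patience. Default 5.
#' @param target optional score level at which to stop. Default `Inf`
#'   (never).
#' @return list of class `cem_config`.
#' @export
cem_config <- function(n_samples = 1000L, elite_fraction = 0.05, alpha = 0.7,
                       max_iterations = 50L, stagnation_patience = 5L,
                       target = Inf) {
  if (elite_fraction <= 0 || elite_fraction >= 1) {
    stopf("elite_fraction must lie in (0, 1)")
  }
  if (alpha <= 0 || alpha > 1) stopf("alpha must lie in (0, 1]")
  structure(list(n_samples = as.integer(n_samples),
                 elite_fraction = elite_fraction, alpha = alpha,
                 max_iterations = as.integer(max_iterations),
                 stagnation_patience = as.integer(stagnation_patience),
                 target = target),
            class = "cem_config")
}

#' Cross-Entropy optimization over binary vectors
#'
#' Maximizes a black-box score over `{0,1}^m` by iteratively (i) drawing
#' `n_samples` supports from an independent-Bernoulli distribution,
#' (ii) scoring them, (iii) selecting the elite (top `elite_fraction`) and
#' (iv) moving each inclusion probability toward the elite mean:
#' `p_i <- alpha * mean(elite bit i) + (1 - alpha) * p_i`. Sampled supports
#' with more than `3 * target_actives` ones are truncated to the most
#' probable bits before scoring, which bounds the cost of each evaluation.
#' The best sample ever drawn is returned, so the best-so-far score is
#' non-decreasing across iterations.
#'
#' @param score function taking a 0/1 vector of length `m` and returning a
#'   finite scalar, larger is better. A score that throws discards that
#'   sample with a warning.
#' @param m number of bits.
#' @param target_actives desired number of ones; initializes
#'   `p = target_actives / m` when `p_init` is not given.
#' @param config a [cem_config()].
#' @param seed integer seed, or `NULL` to use the ambient RNG stream.
#' @param p_init optional initial probability vector.
#' @return list with `best` (0/1 vector), `best_score`, `distribution`
#'   (a [bernoulli_support()]), `trace` (data.frame of per-iteration best
#'   and elite-mean scores), `iterations`.
#' @export
cem_optimize <- function(score, m, target_actives, config = cem_config(),
                         seed = 1L, p_init = NULL) {
  if (m < 1L) stopf("m must be >= 1")
  eps <- 1e-3
  p <- if (is.null(p_init)) rep(min(max(target_actives / m, eps), 1 - eps), m)
       else pmin(pmax(as.numeric(p_init), eps), 1 - eps)
  cap <- 3L * max(1L, as.integer(target_actives))
  with_seed(seed, {
    best <- NULL; best_score <- -Inf
    trace_best <- numeric(0); trace_elite <- numeric(0)
    stagnant <- 0L
    it <- 0L
    while (it < config$max_iterations) {
      it <- it + 1L
      draws <- matrix(stats::runif(config$n_samples * m), config$n_samples, m) <
        rep(p, each = config$n_samples)
      storage.mode(draws) <- "integer"
      # truncate oversized supports to the most probable active bits
      sizes <- rowSums(draws)
      for (r in which(sizes > cap)) {
        act <- which(draws[r, ] == 1L)
        keep <- act[order(-p[act], act)[seq_len(cap)]]
        draws[r, ] <- 0L; draws[r, keep] <- 1L
      }
      # score unique supports once
      key <- apply(draws, 1L, function(b) paste(which(b == 1L), collapse = ","))
      uniq <- !duplicated(key)
      uscore <- vapply(which(uniq), function(r) {
        tryCatch(score(draws[r, ]), error = function(e) {
          warning(sprintf("score failed on a sample (%s); discarded",
                          conditionMessage(e)))
          NA_real_
        })
      }, numeric(1))
      names(uscore) <- key[uniq]
      sc <- unname(uscore[key])
      valid <- which(is.finite(sc))
      if (length(valid) == 0L) next
      n_elite <- max(1L, ceiling(config$elite_fraction * length(valid)))
      elite <- valid[order(-sc[valid])][seq_len(n_elite)]
      p <- config$alpha * colMeans(draws[elite, , drop = FALSE]) +
        (1 - config$alpha) * p
      p <- pmin(pmax(p, eps), 1 - eps)
      top <- valid[which.max(sc[valid])]
      improved <- sc[top] > best_score
      if (improved) {
        best_score <- sc[top]; best <- draws[top, ]
        stagnant <- 0L
      } else stagnant <- stagnant + 1L
      trace_best <- c(trace_best, best_score)
      trace_elite <- c(trace_elite, mean(sc[elite]))
      if (best_score >= config$target) break
      if (stagnant >= config$stagnation_patience) break
    }
    list(best = best, best_score = best_score,
         distribution = bernoulli_support(p, eps),
         trace = data.frame(iteration = seq_along(trace_best),
                            best_score = trace_best,
                            elite_mean = trace_elite),
         iterations = it)
  })
}

#' Subspace Cross-Entropy sparse encoding
#'
#' Combines Cross-Entropy search over Bernoulli support distributions with
#' Subspace-Pursuit-style residual guidance. Each outer iteration (i) runs
#' a Cross-Entropy round whose score for a sampled support `T` is the
#' negative least-squares residual `-||y - A_T b||_2`, (ii) takes the
#' optimized support -- shrunk to its `K` largest coefficients when the
#' sampled set is larger, so the returned code honors the sparsity budget
#' -- and its residual `r`, (iii) builds an auxiliary
#' Bernoulli distribution `q` proportional to the amplitudes of the
#' backprojected residual, scaled to `K` expected ones, (iv) blends it into
#' the sampling distribution with weight `w = min(1, ||r|| / ||y||)`:
#' `p <- (1 - w) p + w q`, and (v) renormalizes `p` to `K` expected ones.
#' The best support seen over all rounds is returned.
#'
#' @param A dictionary object or matrix; columns must be nonzero.
#' @param y length-`n` signal.
#' @param K target sparsity.
#' @param config a [cem_config()].
#' @param outer_iters outer (Subspace-Pursuit-style) iterations. Default 5.
#' @param seed integer seed.
#' @param backprojection as in [subspace_pursuit()].
#' @return A [sparse_code()]; attribute `trace` is a data.frame with the
#'   per-round best residual norm, the running best, and the expected
#'   number of active units of the updated distribution.
#' @export
sce_encode <- function(A, y, K, config = cem_config(), outer_iters = 5L,
                       seed = 1L, backprojection = c("pinv", "correlation")) {
  Amat <- dict_matrix(A)
  backprojection <- match.arg(backprojection)
  if (any(colSums(Amat^2) == 0)) stopf("dictionary has an all-zero column")
  n <- nrow(Amat); m <- ncol(Amat)
  if (K < 1L || K > n) stopf("K must lie in [1, n] = [1, %d]", n)
  y <- as.numeric(y)
  normy <- fnorm(y)
  B <- if (backprojection == "pinv") pinv(Amat) else t(Amat)
  ztol <- 1e-12 * max(1, normy)
  score_fun <- function(bits) {
    supp <- which(bits == 1L)
    if (length(supp) == 0L) return(-normy)
    -least_squares_on_support(Amat, y, supp)$residual_norm
  }
  # stop a CE round as soon as it finds an (effectively) exact code
  if (!is.finite(config$target)) config$target <- -ztol

  with_seed(seed, {
    p <- renormalize_bernoulli(rep(K / m, m), K)
    best_supp <- integer(0); best_fit <- NULL; best_rn <- Inf
    tr_round <- numeric(0); tr_best <- numeric(0); tr_active <- numeric(0)
    for (outer in seq_len(outer_iters)) {
      cem <- cem_optimize(score_fun, m, K, config, seed = NULL, p_init = p)
      supp <- which(cem$best == 1L)
      if (length(supp) > K) {
        # SP-style shrinkage: keep the K largest coefficients of the
        # CE-optimized set, so the returned code honors the sparsity budget
        wide <- least_squares_on_support(Amat, y, supp)
        supp <- sort(supp[top_k_abs(wide$coefficients, K)])
      }
      if (length(supp) == 0L) {
        rn <- normy
        fit <- list(coefficients = numeric(0), residual = y,
                    residual_norm = rn, degenerate = FALSE)
      } else {
        fit <- least_squares_on_support(Amat, y, supp)
        rn <- fit$residual_norm
      }
      if (rn < best_rn) { best_rn <- rn; best_supp <- supp; best_fit <- fit }
      # auxiliary distribution from the amplitude-ordered backprojected residual
      b <- abs(as.numeric(B %*% fit$residual))
      q <- if (sum(b) > 0) b * (K / sum(b)) else rep(K / m, m)
      q <- renormalize_bernoulli(q, K)
      w <- min(1, rn / max(normy, .Machine$double.eps))
      p <- renormalize_bernoulli((1 - w) * cem$distribution$p + w * q, K)
      tr_round <- c(tr_round, rn); tr_best <- c(tr_best, best_rn)
      tr_active <- c(tr_active, sum(p))
      if (best_rn <= ztol) break
    }
    out <- sparse_code(best_supp, best_fit$coefficients, best_rn,
                       iterations = length(tr_round),
                       degenerate = isTRUE(best_fit$degenerate))
    attr(out, "trace") <- data.frame(round = seq_along(tr_round),
                                     round_residual = tr_round,
                                     best_residual = tr_best,
                                     expected_actives = tr_active)
    attr(out, "distribution") <- bernoulli_support(p)
    out
  })
}
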