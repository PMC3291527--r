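# Overcomplete dictionary learning: alternating sparse encoding (fixed
# dictionary) and stochastic-gradient feature updates, plus the two-stage
# pipeline in which robust low-rank/sparse decomposition precedes sparse
# coding of the atypical part.

#' Dictionary of unit-norm features
#'
#' @param A `n x m` matrix of features in columns; every column must be
#'   nonzero. Columns are renormalized to unit Euclidean norm.
#' @param seed creation seed tag (bookkeeping only).
#' @return Object of class `sc_dictionary` with fields `A`, `n`, `m`,
#'   `overcompleteness` (= `m/n`), `seed`.
#' @export
dictionary <- function(A, seed = NA_integer_) {
  A <- as.matrix(A)
  check_finite(A, "A")
  nrm <- sqrt(colSums(A^2))
  if (any(nrm == 0)) stopf("dictionary columns must be nonzero")
  A <- sweep(A, 2L, nrm, "/")
  structure(list(A = A, n = nrow(A), m = ncol(A),
                 overcompleteness = ncol(A) / nrow(A), seed = seed),
            class = "sc_dictionary")
}

#' @export
print.sc_dictionary <- function(x, ...) {
  cat(sprintf("<sc_dictionary> %d x %d (%.3gx overcomplete)\n",
              x$n, x$m, x$overcompleteness))
  invisible(x)
}

# Extract the feature matrix from a dictionary object or bare matrix.
dict_matrix <- function(A) {
  if (inherits(A, "sc_dictionary")) A$A else as.matrix(A)
}

#' Random initial dictionary
#'
#' i.i.d. Gaussian columns normalized to unit norm. Overcomplete use
#' expects `m >= n`; `m < n` is allowed with a warning (undercomplete).
#'
#' @param n input dimension.
#' @param m number of features.
#' @param seed integer seed.
#' @return An [dictionary()] object.
#' @export
init_dictionary <- function(n, m, seed = 1L) {
  if (n < 1L || m < 1L) stopf("n and m must be >= 1")
  if (m < n) warning("m < n: dictionary is undercomplete")
  with_seed(seed, dictionary(matrix(rnorm(n * m), n, m), seed = seed))
}

#' Stochastic-gradient dictionary update for one sample
#'
#' Gradient step on the reconstruction error `||x - A s||^2` with the code
#' held fixed: only active columns move,
#' `A_j <- A_j + eta * (x - A s) * s_j` for `j` in the support, and the
#' updated columns are renormalized to unit norm (without a norm constraint
#' the sparse-coding objective is degenerate under column rescaling).
#'
#' @param A an [dictionary()] object.
#' @param x the sample that was encoded.
#' @param code the [sparse_code()] of `x` under `A`.
#' @param eta positive learning rate.
#' @return The updated dictionary.
#' @export
sgd_update <- function(A, x, code, eta) {
  stopifnot(inherits(A, "sc_dictionary"), inherits(code, "sparse_code"))
  if (eta <= 0) stopf("eta must be positive")
  if (length(code$support) == 0L) return(A)
  Amat <- A$A
  resid <- as.numeric(x) - as.numeric(Amat[, code$support, drop = FALSE] %*%
                                        code$coefficients)
  upd <- Amat[, code$support, drop = FALSE] +
    eta * outer(resid, code$coefficients)
  nrm <- sqrt(colSums(upd^2))
  nrm[nrm == 0] <- 1
  Amat[, code$support] <- sweep(upd, 2L, nrm, "/")
  A$A <- Amat
  A
}

#' Train a sparse coder by alternating encoding and dictionary updates
#'
#' One pass (`epoch`) visits all training columns in a seeded shuffled
#' order; each sample is encoded with the chosen solver at the current
#' dictionary and the active columns take a stochastic-gradient step
#' ([sgd_update()]). The learning rate decays as
#' `eta0 / (1 + epoch / tau)`. If the running mean residual grows 10-fold
#' within an epoch, the rate is halved for the remainder (divergence
#' guard; the event is recorded in the trace).
#'
#' @param X training data: [patch_matrix] (normally normalized patches) or
#'   matrix, samples in columns.
#' @param m number of dictionary features.
#' @param K nonzeros per code, `K <= n`.
#' @param epochs training passes. `0` returns the initial dictionary.
#' @param eta0,tau learning-rate schedule `eta0 / (1 + epoch/tau)` (epoch
#'   counted from 0). Defaults 0.1 and 5.
#' @param solver `"sp"` (Subspace Pursuit, default) or `"sce"`.
#' @param seed integer seed (initialization and shuffling).
#' @param backprojection passed to the solver; `"correlation"` is the fast
#'   choice for large dictionaries.
#' @param sce_config,sce_outer_iters solver options when `solver = "sce"`.
#' @return list with `dictionary` and `trace` (data.frame: epoch,
#'   mean_residual, mean_support, eta, eta_halvings).
#' @export
train_sparse_coder <- function(X, m, K, epochs, eta0 = 0.1, tau = 5,
                               solver = c("sp", "sce"), seed = 1L,
                               backprojection = c("pinv", "correlation"),
                               sce_config = cem_config(n_samples = 200L,
                                                       max_iterations = 10L),
                               sce_outer_iters = 3L) {
  X <- as_data_matrix(X)
  solver <- match.arg(solver)
  backprojection <- match.arg(backprojection)
  n <- nrow(X); T_ <- ncol(X)
  if (K > n) stopf("K must be <= n = %d", n)
  A <- init_dictionary(n, m, seed = seed)
  trace <- data.frame(epoch = integer(0), mean_residual = numeric(0),
                      mean_support = numeric(0), eta = numeric(0),
                      eta_halvings = integer(0))
  if (epochs < 1L) return(list(dictionary = A, trace = trace))
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      eta <- eta0 / (1 + (ep - 1) / tau)
      halvings <- 0L
      ord <- sample.int(T_)
      resids <- numeric(T_); supports <- numeric(T_)
      run_mean0 <- NA_real_
      for (i in seq_along(ord)) {
        x <- X[, ord[i]]
        code <- if (solver == "sp") {
          subspace_pursuit(A, x, K, backprojection = backprojection)
        } else {
          sce_encode(A, x, K, config = sce_config,
                     outer_iters = sce_outer_iters, seed = NULL,
                     backprojection = backprojection)
        }
        A <- sgd_update(A, x, code, eta)
        resids[i] <- code$residual_norm
        supports[i] <- sum(abs(code$coefficients) > 0)
        if (i == 50L) run_mean0 <- mean(resids[1:50])
        if (!is.na(run_mean0) && i %% 50L == 0L) {
          if (mean(resids[(i - 49L):i]) > 10 * run_mean0) {
            eta <- eta / 2; halvings <- halvings + 1L
          }
        }
      }
      trace <- rbind(trace, data.frame(epoch = ep, mean_residual = mean(resids),
                                       mean_support = mean(supports),
                                       eta = eta, eta_halvings = halvings))
    }
  })
  list(dictionary = A, trace = trace)
}

#' Two-stage encoding: robust decomposition, then overcomplete sparse coding
#'
#' Runs [rpca_decompose()] on the (normalized) patch matrix, trains an
#' overcomplete dictionary on the columns of the sparse "atypical" part S,
#' and encodes every S column. The reconstruction of a sample is its
#' low-rank column plus the dictionary reconstruction of its code, so the
#' stored decomposition satisfies `P = L + S` to the RPCA tolerance
#' regardless of sparse-coding quality. With `lambda_norm` at the small
#' limit the low-rank part vanishes and the pipeline reduces to plain
#' sparse coding of `P`.
#'
#' @param P normalized [patch_matrix] or matrix.
#' @param lambda_norm normalized RPCA trade-off.
#' @param m,K,epochs sparse-coding parameters (see [train_sparse_coder()]).
#' @param seed integer seed.
#' @param solver,backprojection solver options.
#' @param rpca_args list of extra arguments to [rpca_decompose()].
#' @param ... further arguments to [train_sparse_coder()].
#' @return list of class `two_stage_result`: `rpca` ([rpca_decompose()]
#'   result), `dictionary`, `codes` (list of [sparse_code()] per column),
#'   `trace`.
#' @export
two_stage_pipeline <- function(P, lambda_norm, m, K, epochs = 1L, seed = 1L,
                               solver = "sp", backprojection = "correlation",
                               rpca_args = list(), ...) {
  X <- as_data_matrix(P)
  dec <- do.call(rpca_decompose, c(list(M = X, lambda_norm = lambda_norm),
                                   rpca_args))
  S <- dec$S
  if (max(abs(S)) < 1e-12 * max(1, max(abs(X)))) {
    stopf("degenerate decomposition: S is (numerically) all-zero at lambda' = %g",
          lambda_norm)
  }
  fit <- train_sparse_coder(S, m = m, K = K, epochs = epochs, seed = seed,
                            solver = solver, backprojection = backprojection,
                            ...)
  codes <- lapply(seq_len(ncol(S)), function(j) {
    subspace_pursuit(fit$dictionary, S[, j], K, backprojection = backprojection)
  })
  structure(list(rpca = dec, dictionary = fit$dictionary, codes = codes,
                 trace = fit$trace),
            class = "two_stage_result")
}

#' Reconstruct one sample from a two-stage encoding
#'
#' @param result a `two_stage_result`.
#' @param j column index.
#' @return list with `reconstruction` (L column + dictionary part) and
#'   `code_residual_norm` (equals `||S_j - A s_j||`).
#' @export
reconstruct_sample <- function(result, j) {
  code <- result$codes[[j]]
  Amat <- result$dictionary$A
  sc_part <- if (length(code$support)) {
    as.numeric(Amat[, code$support, drop = FALSE] %*% code$coefficients)
  } else numeric(nrow(Amat))
  list(reconstruction = result$rpca$L[, j] + sc_part,
       code_residual_norm = code$residual_norm)
}
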