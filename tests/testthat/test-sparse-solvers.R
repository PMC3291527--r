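test_that("support-restricted least squares is minimal and flags degeneracy", {
  I5 <- diag(5)
  f <- least_squares_on_support(I5, c(0, 1, 0, 0, 0), 2)
  expect_equal(f$coefficients, 1)
  expect_equal(f$residual_norm, 0)
  expect_false(f$degenerate)

  # duplicated column: rank deficient, residual still minimal
  A <- cbind(c(1, 0), c(1, 0), c(0, 1))
  fd <- least_squares_on_support(A, c(2, 3), c(1, 2))
  expect_true(fd$degenerate)
  expect_lt(abs(fd$residual_norm - 3), 1e-10)

  # residual orthogonal to the selected columns
  set.seed(31)
  A <- matrix(rnorm(10 * 6), 10, 6)
  y <- rnorm(10)
  fo <- least_squares_on_support(A, y, c(1, 3, 5))
  expect_lt(max(abs(t(A[, c(1, 3, 5)]) %*% fo$residual)), 1e-8)

  expect_error(least_squares_on_support(I5, rnorm(5), integer(0)), "nonempty")
  expect_error(least_squares_on_support(I5, rnorm(5), 9), "out of range")
})

test_that("subspace pursuit solves identity and degenerate inputs exactly", {
  n <- 12
  y <- numeric(n); y[c(2, 5, 9)] <- c(3, -1, 0.5)
  code <- subspace_pursuit(diag(n), y, 3)
  expect_equal(code$support, c(2L, 5L, 9L))
  expect_equal(code$residual_norm, 0)
  expect_equal(code$iterations, 0L)

  z <- subspace_pursuit(diag(n), numeric(n), 3)
  expect_equal(z$residual_norm, 0)
  expect_true(all(abs(z$coefficients) < 1e-12))

  expect_error(subspace_pursuit(diag(4), rnorm(4), 5), "K must lie")
})

test_that("subspace pursuit recovers planted noiseless codes with a zero-residual certificate", {
  hits <- 0
  for (sd in 1:100) {
    A <- init_dictionary(20, 40, seed = sd)
    g <- generate_planted_codes(A, 3, 1, 0, seed = sd + 500)
    y <- g$X$data[, 1]
    code <- subspace_pursuit(A, y, 3)
    if (code$residual_norm < 1e-8 * max(1, sqrt(sum(y^2)))) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("subspace pursuit residual trace decreases and the best iterate is returned", {
  set.seed(77)
  for (i in 1:10) {
    A <- init_dictionary(15, 30, seed = i)
    y <- rnorm(15)
    code <- subspace_pursuit(A, y, 4)
    tr <- attr(code, "residual_trace")
    expect_true(all(diff(tr) < 0) || length(tr) == 1)
    expect_equal(code$residual_norm, min(tr))
    # residual_norm consistency with the stored code
    rec <- A$A[, code$support, drop = FALSE] %*% code$coefficients
    expect_lt(abs(sqrt(sum((y - rec)^2)) - code$residual_norm), 1e-8)
  }
})

test_that("solver output is invariant to dictionary column permutation", {
  A <- init_dictionary(16, 32, seed = 3)
  g <- generate_planted_codes(A, 3, 1, 0, seed = 4)
  y <- g$X$data[, 1]
  set.seed(123); perm <- sample(32)
  Ap <- dictionary(A$A[, perm])
  c1 <- subspace_pursuit(A, y, 3)
  c2 <- subspace_pursuit(Ap, y, 3)
  expect_equal(sort(perm[c2$support]), sort(c1$support))
  expect_equal(c2$coefficients[order(perm[c2$support])],
               c1$coefficients[order(c1$support)], tolerance = 1e-8)
})

test_that("cross-entropy optimization solves separable and hidden-mask objectives", {
  # separable optimum: all ones
  r <- cem_optimize(function(b) sum(b), 8, 8, cem_config(n_samples = 400),
                    seed = 1)
  expect_equal(r$best, rep(1L, 8))
  expect_true(all(r$distribution$p > 0.95))

  # hidden mask via brute force: the enumerated optimum is the mask itself
  set.seed(5)
  mask <- as.integer(runif(12) < 0.5)
  scorefun <- function(b) -sum(b != mask)
  r2 <- cem_optimize(scorefun, 12, max(1, sum(mask)),
                     cem_config(target = 0), seed = 2)
  expect_equal(r2$best, mask)
  expect_equal(r2$best_score, 0)

  # best-so-far score is non-decreasing
  expect_true(all(diff(r2$trace$best_score) >= 0))

  # determinism under a fixed seed
  a <- cem_optimize(scorefun, 12, 4, cem_config(), seed = 9)
  b <- cem_optimize(scorefun, 12, 4, cem_config(), seed = 9)
  expect_identical(a$trace, b$trace)
  expect_identical(a$best, b$best)
})

test_that("a throwing score discards the sample and continues", {
  bad <- function(b) { if (b[1] == 1L) stop("boom"); sum(b) }
  w <- testthat::capture_warnings(
    r <- cem_optimize(bad, 6, 3, cem_config(n_samples = 100,
                                            max_iterations = 5), seed = 3))
  expect_true(any(grepl("discarded", w)))
  expect_true(is.finite(r$best_score))
  expect_equal(r$best[1], 0L)
})

test_that("SCE attains exact codes on identity and keeps its distribution contract", {
  n <- 10
  y <- numeric(n); y[c(1, 4, 7)] <- c(2, -1, 3)
  code <- sce_encode(diag(n), y, 3, seed = 1)
  expect_equal(sort(code$support), c(1L, 4L, 7L))
  expect_lt(code$residual_norm, 1e-10)

  # expected number of active units stays at K after every outer round
  A <- init_dictionary(8, 12, seed = 2)
  g <- generate_planted_codes(A, 3, 1, 0.3, seed = 3)  # noisy: several rounds
  code2 <- sce_encode(A, g$X$data[, 1], 3, outer_iters = 4, seed = 4)
  tr <- attr(code2, "trace")
  expect_true(all(abs(tr$expected_actives - 3) < 1e-6))
  # returned residual is the running best over rounds
  expect_equal(code2$residual_norm, min(tr$round_residual))
  expect_true(all(tr$best_residual == cummin(tr$round_residual)))
})

test_that("SCE matches the exhaustive-search optimum on enumerable instances", {
  hits <- 0
  for (sd in 1:25) {
    A <- init_dictionary(8, 12, seed = sd)
    g <- generate_planted_codes(A, 3, 1, 0, seed = sd + 300)
    y <- g$X$data[, 1]
    code <- sce_encode(A, y, 3, seed = sd)
    # noiseless planted codes certify the brute-force optimum at residual 0
    if (code$residual_norm < 1e-8 * max(1, sqrt(sum(y^2)))) hits <- hits + 1
  }
  expect_gte(hits, 24)

  # direct brute-force cross-check on a noisy instance (optimum > 0)
  A <- init_dictionary(8, 12, seed = 101)
  g <- generate_planted_codes(A, 3, 1, 0.5, seed = 102)
  y <- g$X$data[, 1]
  best <- brute_force_residual(A, y, 3)
  code <- sce_encode(A, y, 3, outer_iters = 8, seed = 103)
  expect_lt(code$residual_norm, best + 1e-8)
})
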