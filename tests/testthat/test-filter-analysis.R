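test_that("reverse correlation recovers planted linear filters", {
  set.seed(20)
  n <- 36; T_ <- 50 * n
  X <- matrix(rnorm(n * T_), n, T_)  # white stimuli
  truth <- cbind(rnorm(n), rnorm(n))
  R <- t(X) %*% truth
  est <- reverse_correlation(X, R)
  for (u in 1:2) {
    expect_gt(abs(cor(est[, u], truth[, u])), 0.99)
  }

  # all-zero responses give the zero filter
  expect_true(all(reverse_correlation(X, matrix(0, T_, 1)) == 0))

  # orthonormal spanning stimuli, noiseless: exact recovery
  Q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  Rq <- t(Q) %*% truth
  expect_lt(max(abs(reverse_correlation(Q, Rq) - truth)), 1e-8)

  # rank-deficient stimuli fall back to ridge with a message
  Xdef <- X[, 1:10] %*% matrix(1, 10, 30)
  expect_message(reverse_correlation(Xdef, matrix(rnorm(30), 30, 1)), "ridge")
})

test_that("gabor fitting recovers planted parameters and is seed-deterministic", {
  p <- gabor_params(x0 = 7.3, y0 = 8.4, theta = 1.1, f = 0.2, phi = 0.5,
                    sigma_x = 2.4, sigma_y = 1.7)
  patch <- generate_gabor_patch(p, 16)
  fit <- fit_gabor(patch, n_restarts = 20, seed = 2)
  expect_lt(fit$rmse, 1e-6)
  expect_lt(abs(fit$params$x0 - p$x0), 0.5)
  expect_lt(abs(fit$params$y0 - p$y0), 0.5)
  dth <- abs(fit$params$theta - p$theta) %% pi
  expect_lt(min(dth, pi - dth), 5 * pi / 180)
  expect_lt(abs(fit$params$f - p$f) / p$f, 0.05)
  expect_equal(fit$nx, fit$params$sigma_x * fit$params$f)

  # same patch + seed: identical fit
  fit2 <- fit_gabor(patch, n_restarts = 20, seed = 2)
  expect_identical(fit, fit2)

  # fitting the fitted model to itself is (near) exact
  self <- generate_gabor_patch(fit$params, 16)
  expect_lt(sqrt(mean((self - patch)^2)), 1e-6)

  # shape parameters are invariant under amplitude rescaling
  fit3 <- fit_gabor(3.7 * patch, n_restarts = 20, seed = 2)
  expect_lt(abs(fit3$nx - fit$nx), 1e-3)
  expect_lt(abs(fit3$ny - fit$ny), 1e-3)
})

test_that("gabor fitting survives pure noise", {
  set.seed(4)
  noise <- matrix(rnorm(256), 16, 16)
  fit <- fit_gabor(noise, n_restarts = 5, seed = 5)
  expect_true(is.finite(fit$rmse))
  expect_lt(fit$rmse, sqrt(mean(noise^2)) * 1.5)
})

test_that("population discard rules flag edge and too-small fits", {
  # interior planted Gabor with sigma_x = 2, f = 0.25: retained, nx = 0.5
  interior <- generate_gabor_patch(gabor_params(8, 8, 0.6, 0.25, 0.2, 2, 3), 16)
  # an off-center filter near the border
  edgy <- generate_gabor_patch(gabor_params(0.2, 8, 0, 0.2, 0, 2, 2), 16)
  filters <- cbind(as.numeric(t(interior)), as.numeric(t(edgy)))
  tab <- population_shapes(filters, 16, n_restarts = 15, seed = 6)
  expect_equal(tab$discarded[1], "none")
  expect_lt(abs(tab$nx[1] - 0.5), 0.05)
  expect_equal(tab$discarded[2], "edge")

  # tiny envelope triggers the 0.3-pixel rule
  tiny <- generate_gabor_patch(gabor_params(8, 8, 0, 0.3, 0, 0.2, 0.2), 16)
  tab2 <- population_shapes(matrix(as.numeric(t(tiny))), 16, n_restarts = 15,
                            seed = 7)
  expect_equal(tab2$discarded[1], "too_small")
})

test_that("mean SNR matches its closed forms", {
  set.seed(8)
  X <- matrix(rnorm(40), 8, 5)
  expect_equal(mean_snr(X, X), 100)            # capped exact reconstruction
  expect_equal(mean_snr(X, 0 * X), 0)          # zero reconstruction: 0 dB
  expect_equal(mean_snr(X, X / 2), 10 * log10(4), tolerance = 1e-12)
  Xz <- X; Xz[, 2] <- 0
  expect_warning(v <- mean_snr(Xz, Xz / 2), "skipped")
  expect_equal(v, 10 * log10(4), tolerance = 1e-12)
})

test_that("radial amplitude spectra localize sinusoids and flatten white noise", {
  # single-pixel impulse: flat spectrum
  imp <- matrix(0, 16, 16); imp[1, 1] <- 1
  sp <- radial_amplitude_spectrum(image_stack(array(imp, c(16, 16, 1))), 8)
  expect_lt(diff(range(sp$amplitude)), 1e-10)

  # horizontal sinusoid at f0: peak in the bin containing f0
  f0 <- 0.25
  xg <- matrix(rep(0:31, each = 32), 32, 32)
  sine <- sin(2 * pi * f0 * xg)
  sps <- radial_amplitude_spectrum(image_stack(array(sine, c(32, 32, 1))), 16)
  expect_lt(abs(sps$frequency[which.max(sps$amplitude)] - f0), 0.5 / 16)

  # white noise: flat within 10% across mid bins
  wn <- generate_pink_noise_images(500, 32, 0, seed = 30)
  spw <- radial_amplitude_spectrum(wn, 12)
  mid <- spw$frequency > 0.08 & spw$frequency < 0.45
  expect_lt(diff(range(spw$amplitude[mid])) / mean(spw$amplitude[mid]), 0.1)
})

test_that("the whitening filter ramps from zero and peaks at the quartic-cutoff optimum", {
  W <- whitening_filter(32, f0 = 0.4)
  expect_equal(W[1, 1], 0)  # DC
  prof <- function(f) f * exp(-(f / 0.4)^4)
  fs <- seq(0, 0.5, by = 1e-4)
  expect_equal(fs[which.max(prof(fs))], 0.4 * (1 / 4)^(1 / 4), tolerance = 1e-3)
  # low-frequency ramp is increasing
  expect_true(all(diff(prof(seq(0, 0.1, by = 0.01))) > 0))
  expect_error(whitening_filter(32, 0.9), "f0")
})

test_that("effective filter size separates localized from global filters", {
  local_f <- c(rep(0, 60), 5, 5, rep(0, 2))  # 2 of 64 coefficients
  global_f <- rep(1, 64)
  es <- effective_filter_size(cbind(local_f, global_f))
  expect_lt(es[1], 0.05)
  expect_gte(es[2], 0.9)
})
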