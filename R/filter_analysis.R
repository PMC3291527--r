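# Receptive-field characterization of learned filters: reverse correlation,
# Gabor fitting with the best-of-restarts protocol, population shape
# statistics with discard rules, reconstruction SNR, and amplitude-spectrum
# / whitening-filter comparisons.

#' Gabor parameter set
#'
#' @param x0,y0 center in pixels (0-based grid, (0,0) top-left).
#' @param theta orientation in radians (normal to the stripes).
#' @param f carrier frequency in cycles/pixel, `>= 0`.
#' @param phi phase of the cosine carrier, radians.
#' @param sigma_x,sigma_y envelope widths in pixels, `> 0`.
#' @param amplitude carrier amplitude.
#' @return list of class `gabor_params`.
#' @export
gabor_params <- function(x0, y0, theta, f, phi, sigma_x, sigma_y,
                         amplitude = 1) {
  if (sigma_x <= 0 || sigma_y <= 0) stopf("envelope widths must be positive")
  if (f < 0) stopf("frequency must be nonnegative")
  structure(list(x0 = x0, y0 = y0, theta = theta, f = f, phi = phi,
                 sigma_x = sigma_x, sigma_y = sigma_y, amplitude = amplitude),
            class = "gabor_params")
}

# Canonicalize the (theta + pi, phi) ~ (theta, -phi) Gabor symmetry to
# theta in [0, pi); also folds phi into (-pi, pi].
canonicalize_gabor <- function(p) {
  th <- p$theta %% (2 * pi)
  if (th >= pi) {
    th <- th - pi
    p$phi <- -p$phi
  }
  p$theta <- th
  p$phi <- atan2(sin(p$phi), cos(p$phi))
  p
}

#' Linear receptive-field estimate by reverse correlation
#'
#' Whitened cross-correlation: the least-squares linear filter of each unit
#' is `(X X')^{-1} X R`, the inverse stimulus covariance times the
#' stimulus-response cross-covariance. For white stimuli this reduces to
#' the spike-triggered average. A singular stimulus covariance triggers a
#' ridge fallback (regularizer logged via `message()` and returned as
#' attribute `ridge`).
#'
#' @param stimuli [patch_matrix] or `n x T` matrix.
#' @param responses `T x units` matrix of unit responses.
#' @return `n x units` matrix of filter estimates.
#' @export
reverse_correlation <- function(stimuli, responses) {
  X <- as_data_matrix(stimuli)
  R <- as.matrix(responses)
  if (ncol(X) != nrow(R)) stopf("ncol(stimuli) = %d must equal nrow(responses) = %d",
                                ncol(X), nrow(R))
  G <- X %*% t(X)
  C <- X %*% R
  ridge <- 0
  est <- tryCatch(solve(G, C), error = function(e) NULL)
  if (is.null(est)) {
    ridge <- 1e-8 * sum(diag(G)) / nrow(G)
    message(sprintf("singular stimulus covariance; ridge fallback with regularizer %g",
                    ridge))
    est <- solve(G + diag(ridge, nrow(G)), C)
  }
  attr(est, "ridge") <- ridge
  est
}

# Gabor model on a flattened grid; par = (x0, y0, theta, f, phi, sx, sy, a).
gabor_model_vec <- function(par, size) {
  as.numeric(t(generate_gabor_patch(
    list(x0 = par[1], y0 = par[2], theta = par[3], f = par[4], phi = par[5],
         sigma_x = par[6], sigma_y = par[7], amplitude = par[8]), size)))
}

#' Fit a Gabor function to a patch
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) over center,
#' orientation, frequency, phase, envelope widths and an amplitude scale.
#' The optimizer is restarted `n_restarts` times from random points drawn
#' uniformly inside the parameter box (seeded) and the best solution by
#' RMSE is kept. Shape parameters `nx = sigma_x * f` and `ny = sigma_y * f`
#' (dimensionless) are computed from the canonicalized fit.
#'
#' @param patch square numeric matrix, side >= 4.
#' @param n_restarts random restarts. Default 20.
#' @param seed integer seed for the restart draws.
#' @param edge_margin border margin (pixels) for the edge-discard flag.
#'   Default 1.
#' @param min_sigma envelope width below which a fit is flagged
#'   `too_small`. Default 0.3 px.
#' @return Object of class `gabor_fit`: `params` ([gabor_params()]),
#'   `rmse`, `nx`, `ny`, `discarded` (`"none"`, `"edge"` or
#'   `"too_small"`).
#' @export
fit_gabor <- function(patch, n_restarts = 20L, seed = 1L, edge_margin = 1,
                      min_sigma = 0.3) {
  patch <- as.matrix(patch)
  size <- nrow(patch)
  if (size != ncol(patch) || size < 4L) stopf("patch must be square, side >= 4")
  target <- as.numeric(t(patch))
  amp0 <- max(abs(patch))
  if (amp0 == 0) amp0 <- 1
  lower <- c(-2, -2, 0, 0, -pi, 0.05, 0.05, -10 * amp0)
  upper <- c(size + 1, size + 1, pi, 0.5, pi, size, size, 10 * amp0)
  resid_fun <- function(par) gabor_model_vec(par, size) - target

  # Data-driven starting points: energy centroid for the center, dominant
  # Fourier component for orientation and frequency, second moments of the
  # energy for the envelope, four candidate phases. Remaining restarts are
  # uniform in the parameter box (seeded).
  guided <- local({
    E <- patch^2
    tot <- sum(E)
    if (tot == 0) return(list())
    xy <- seq_len(size) - 1L
    Xc <- matrix(rep(xy, each = size), size, size)   # column (x) coordinate
    Yc <- matrix(rep(xy, times = size), size, size)  # row (y) coordinate
    x0 <- sum(Xc * E) / tot; y0 <- sum(Yc * E) / tot
    sig <- sqrt(max(sum(((Xc - x0)^2 + (Yc - y0)^2) * E) / (2 * tot), 0.25))
    Fm <- Mod(stats::fft(patch))
    f1 <- fft_freqs(size)
    Fm[1, 1] <- 0  # ignore DC
    pk <- arrayInd(which.max(Fm), dim(Fm))
    fy <- f1[pk[1]]; fx <- f1[pk[2]]
    f0 <- min(sqrt(fx^2 + fy^2), 0.5)
    th0 <- atan2(fy, fx) %% pi
    lapply(c(0, pi / 2, pi, -pi / 2), function(ph) {
      pmin(pmax(c(x0, y0, th0, f0, ph, sig, sig, amp0), lower), upper)
    })
  })
  starts <- c(guided, with_seed(seed, {
    lapply(seq_len(max(1L, n_restarts)), function(i) {
      s <- stats::runif(8, lower, upper)
      s[8] <- amp0 * stats::runif(1, 0.3, 1.5) * sample(c(-1, 1), 1)
      s
    })
  }))
  best <- NULL; best_rmse <- Inf
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rmse <- sqrt(mean(fit$fvec^2))
    if (rmse < best_rmse) { best_rmse <- rmse; best <- fit$par }
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, rmse = Inf, nx = NA_real_,
                          ny = NA_real_, discarded = "too_small"),
                     class = "gabor_fit"))
  }
  p <- canonicalize_gabor(gabor_params(best[1], best[2], best[3], best[4],
                                       best[5], max(best[6], 1e-8),
                                       max(best[7], 1e-8), best[8]))
  nx <- p$sigma_x * p$f
  ny <- p$sigma_y * p$f
  discarded <- "none"
  if (p$x0 < edge_margin || p$x0 > size - 1 - edge_margin ||
      p$y0 < edge_margin || p$y0 > size - 1 - edge_margin) {
    discarded <- "edge"
  } else if (min(p$sigma_x, p$sigma_y) < min_sigma) {
    discarded <- "too_small"
  }
  structure(list(params = p, rmse = best_rmse, nx = nx, ny = ny,
                 discarded = discarded),
            class = "gabor_fit")
}

#' @export
print.gabor_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("<gabor_fit> failed (all restarts)\n")
  } else {
    cat(sprintf("<gabor_fit> center (%.2f, %.2f), theta %.1f deg, f %.3f c/px, rmse %.3g, (nx, ny) = (%.3f, %.3f)%s\n",
                x$params$x0, x$params$y0, x$params$theta * 180 / pi,
                x$params$f, x$rmse, x$nx, x$ny,
                if (x$discarded == "none") "" else paste0(" [", x$discarded, "]")))
  }
  invisible(x)
}

#' Gabor population statistics over a filter set
#'
#' Fits every filter with [fit_gabor()] and applies the population discard
#' rules: filters whose fitted center falls within `edge_margin` pixels of
#' the border (or outside the patch) are flagged `edge`, and fits with an
#' envelope width below `min_sigma` (default 0.3 px, where fitting is
#' unreliable) are flagged `too_small`. Retained rows carry the shape
#' parameters `(nx, ny)`.
#'
#' @param filters [dictionary()] object or `n x units` matrix; columns are
#'   reshaped (row-major) to `side x side` patches.
#' @param side patch side; `side^2` must equal the filter length.
#' @param n_restarts,seed,edge_margin,min_sigma passed to [fit_gabor()].
#' @return data.frame, one row per filter: `filter_id`, `x0`, `y0`,
#'   `theta`, `f`, `phi`, `sigma_x`, `sigma_y`, `rmse`, `nx`, `ny`,
#'   `discarded`.
#' @export
population_shapes <- function(filters, side, n_restarts = 20L, seed = 1L,
                              edge_margin = 1, min_sigma = 0.3) {
  Fm <- dict_matrix(filters)
  if (nrow(Fm) != side^2) stopf("filters of length %d cannot form %d x %d patches",
                                nrow(Fm), side, side)
  rows <- lapply(seq_len(ncol(Fm)), function(j) {
    patch <- matrix(Fm[, j], side, side, byrow = TRUE)
    g <- fit_gabor(patch, n_restarts = n_restarts, seed = seed + j,
                   edge_margin = edge_margin, min_sigma = min_sigma)
    p <- g$params
    data.frame(filter_id = j,
               x0 = if (is.null(p)) NA_real_ else p$x0,
               y0 = if (is.null(p)) NA_real_ else p$y0,
               theta = if (is.null(p)) NA_real_ else p$theta,
               f = if (is.null(p)) NA_real_ else p$f,
               phi = if (is.null(p)) NA_real_ else p$phi,
               sigma_x = if (is.null(p)) NA_real_ else p$sigma_x,
               sigma_y = if (is.null(p)) NA_real_ else p$sigma_y,
               rmse = g$rmse, nx = g$nx, ny = g$ny,
               discarded = g$discarded)
  })
  do.call(rbind, rows)
}

#' Mean reconstruction signal-to-noise ratio in dB
#'
#' `mean over columns of 10 log10(||x||^2 / ||x - xhat||^2)`, with exact
#' (or near-exact) reconstructions capped at `cap_db`. Zero-norm columns
#' carry no signal and are skipped with a warning.
#'
#' @param X original data ([patch_matrix] or matrix).
#' @param Xhat reconstruction of the same shape.
#' @param cap_db per-column ceiling in dB. Default 100.
#' @return Mean SNR in dB.
#' @export
mean_snr <- function(X, Xhat, cap_db = 100) {
  X <- as_data_matrix(X); Xhat <- as_data_matrix(Xhat)
  if (!all(dim(X) == dim(Xhat))) stopf("X and Xhat must have the same shape")
  sig <- colSums(X^2)
  err <- colSums((X - Xhat)^2)
  keep <- sig > 0
  if (!all(keep)) warning(sprintf("%d zero-norm column(s) skipped", sum(!keep)))
  if (!any(keep)) stopf("no nonzero columns to evaluate")
  snr <- 10 * log10(sig[keep] / pmax(err[keep], sig[keep] * 10^(-cap_db / 10)))
  mean(pmin(snr, cap_db))
}

#' Radially averaged Fourier amplitude spectrum
#'
#' 2-D DFT amplitude of each input, averaged over inputs, binned by radial
#' frequency up to the Nyquist limit (0.5 cycles/pixel) and rescaled so the
#' maximum is 1.
#'
#' @param x an [image_stack], [patch_matrix] (square patches) or matrix of
#'   vectorized square patches in columns.
#' @param n_bins number of radial bins. Default 16.
#' @return data.frame with `frequency` (bin centers, cycles/pixel) and
#'   `amplitude` (max-normalized mean amplitude); empty bins are dropped.
#' @export
radial_amplitude_spectrum <- function(x, n_bins = 16L) {
  imgs <- if (inherits(x, "image_stack")) {
    lapply(seq_len(dim(x$pixels)[3]), function(i) x$pixels[, , i])
  } else {
    X <- as_data_matrix(x)
    side <- round(sqrt(nrow(X)))
    if (side^2 != nrow(X)) stopf("inputs must be square")
    lapply(seq_len(ncol(X)), function(j) matrix(X[, j], side, side, byrow = TRUE))
  }
  side <- nrow(imgs[[1]])
  if (side != ncol(imgs[[1]])) stopf("inputs must be square")
  f1 <- fft_freqs(side)
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  amp <- Reduce("+", lapply(imgs, function(im) Mod(stats::fft(im)))) / length(imgs)
  keep <- fr <= 0.5 + 1e-12
  breaks <- seq(0, 0.5, length.out = n_bins + 1L)
  bin <- cut(fr[keep], breaks, include.lowest = TRUE, labels = FALSE)
  means <- tapply(amp[keep], bin, mean)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- data.frame(frequency = centers[as.integer(names(means))],
                    amplitude = as.numeric(means))
  out$amplitude <- out$amplitude / max(out$amplitude)
  out
}

#' Radially symmetric whitening filter in the frequency domain
#'
#' Gain `W(f) = f * exp(-(f / f0)^4)` on the 2-D DFT frequency grid: zero
#' at DC, a linear ramp at low frequencies (flattening a 1/f amplitude
#' spectrum) and a smooth quartic cutoff around `f0`. The radial gain peaks
#' at `f0 * (1/4)^(1/4)`.
#'
#' @param size grid side (>= 8).
#' @param f0 cutoff frequency in cycles/pixel, `0 < f0 <= 0.5`. Default
#'   `0.4` (0.8 x Nyquist).
#' @return `size x size` matrix of gains (DFT layout, DC at `[1, 1]`).
#' @export
whitening_filter <- function(size, f0 = 0.4) {
  if (size < 8L) stopf("size must be >= 8")
  if (f0 <= 0 || f0 > 0.5) stopf("f0 must lie in (0, 0.5]")
  f1 <- fft_freqs(size)
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  fr * exp(-(fr / f0)^4)
}

#' Effective size of a filter
#'
#' The fraction of a filter's coefficients needed to hold `mass` (default
#' 90%) of its squared l2 mass: small for localized filters, near 1 for
#' global ones. The population median of this quantity over a filter set
#' is the structural-sparsity summary used in lambda-prime sweeps.
#'
#' @param filters [dictionary()] object or matrix, filters in columns.
#' @param mass fraction of squared mass to cover. Default 0.9.
#' @return numeric vector, one value per filter.
#' @export
effective_filter_size <- function(filters, mass = 0.9) {
  Fm <- dict_matrix(filters)
  apply(Fm, 2L, function(v) {
    e <- sort(v^2, decreasing = TRUE)
    tot <- sum(e)
    if (tot == 0) return(0)
    which(cumsum(e) >= mass * tot)[1] / length(v)
  })
}
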