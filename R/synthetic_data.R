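# Synthetic input generators: every input class the two-stage pipeline
# assumes (planted low-rank + sparse matrices, 1/f images, dictionary-sparse
# signals, parametric Gabor patches) plus patch extraction and normalization.

#' Patch matrix container
#'
#' A `patch_matrix` holds column-wise stacked stimulus patches: an `n x T`
#' numeric matrix whose columns are vectorized patches (row-major, pixel
#' (0,0) top-left), together with the patch geometry and a normalization
#' flag.
#'
#' @param data numeric matrix, one vectorized patch per column.
#' @param patch_shape integer vector `(height, width)` or
#'   `(height, width, frames)`; its product must equal `nrow(data)`.
#' @param normalized logical; `TRUE` when every column has zero mean and
#'   unit (population) standard deviation.
#' @return An object of class `patch_matrix` with fields `data`,
#'   `patch_shape`, `normalized`.
#' @export
patch_matrix <- function(data, patch_shape, normalized = FALSE) {
  data <- as.matrix(data)
  check_finite(data, "data")
  patch_shape <- as.integer(patch_shape)
  if (prod(patch_shape) != nrow(data)) {
    stopf("prod(patch_shape) = %d must equal nrow(data) = %d",
          prod(patch_shape), nrow(data))
  }
  structure(list(data = data, patch_shape = patch_shape,
                 normalized = isTRUE(normalized)),
            class = "patch_matrix")
}

#' @export
print.patch_matrix <- function(x, ...) {
  cat(sprintf("<patch_matrix> %d x %d (patch %s%s)\n",
              nrow(x$data), ncol(x$data),
              paste(x$patch_shape, collapse = "x"),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

# Accept either a patch_matrix or a bare matrix.
as_data_matrix <- function(x) {
  if (inherits(x, "patch_matrix")) x$data else as.matrix(x)
}

#' Grayscale image stack
#'
#' @param pixels 3-D numeric array, `height x width x n_images`.
#' @param provenance free-text tag describing how the stack was produced.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, provenance = "unspecified") {
  pixels <- as.array(pixels)
  if (length(dim(pixels)) == 2L) dim(pixels) <- c(dim(pixels), 1L)
  if (length(dim(pixels)) != 3L) stopf("`pixels` must be a 3-D array")
  if (dim(pixels)[1] < 2L || dim(pixels)[2] < 2L) {
    stopf("images must be at least 2 x 2")
  }
  check_finite(pixels, "pixels")
  structure(list(pixels = pixels, provenance = as.character(provenance)[1]),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d images of %d x %d (%s)\n",
              d[3], d[1], d[2], x$provenance))
  invisible(x)
}

#' Planted low-rank plus entrywise-sparse matrix
#'
#' Draws `M = L0 + S0` where `L0 = U V'` with independent standard-normal
#' factor entries scaled by `1/sqrt(min(n1, n2))` (so `rank(L0) <= rank_r`)
#' and `S0` has `floor(sparse_fraction * n1 * n2)` entries of value
#' `+/- magnitude` (random signs) on a uniformly random support. The
#' decomposition is exact by construction, which gives downstream recovery
#' tests a ground truth.
#'
#' @param n1,n2 matrix dimensions.
#' @param rank_r target rank of the low-rank part; must not exceed
#'   `min(n1, n2)`. `rank_r = 0` gives an all-zero `L0`.
#' @param sparse_fraction fraction of corrupted entries, in `[0, 1]`.
#' @param magnitude absolute value of the sparse spikes.
#' @param seed integer seed; identical seeds give identical draws.
#' @return A list of class `planted_decomposition` with fields `M`, `L0`,
#'   `S0`, `rank_r`, `sparse_fraction`, `seed`.
#' @export
generate_lowrank_sparse <- function(n1, n2, rank_r, sparse_fraction,
                                    magnitude = 1, seed = 1L) {
  if (rank_r > min(n1, n2)) stopf("rank_r must be <= min(n1, n2)")
  if (rank_r < 0L) stopf("rank_r must be nonnegative")
  if (sparse_fraction < 0 || sparse_fraction > 1) {
    stopf("sparse_fraction must lie in [0, 1]")
  }
  if (magnitude <= 0) stopf("magnitude must be positive")
  with_seed(seed, {
    if (rank_r > 0L) {
      U <- matrix(rnorm(n1 * rank_r), n1, rank_r)
      V <- matrix(rnorm(n2 * rank_r), n2, rank_r)
      L0 <- (U %*% t(V)) / sqrt(min(n1, n2))
    } else {
      L0 <- matrix(0, n1, n2)
    }
    nnz <- floor(sparse_fraction * n1 * n2)
    S0 <- matrix(0, n1, n2)
    if (nnz > 0L) {
      idx <- sample.int(n1 * n2, nnz)
      S0[idx] <- magnitude * sample(c(-1, 1), nnz, replace = TRUE)
    }
    structure(list(M = L0 + S0, L0 = L0, S0 = S0, rank_r = as.integer(rank_r),
                   sparse_fraction = sparse_fraction, seed = seed),
              class = "planted_decomposition")
  })
}

#' Images with power-law amplitude spectra
#'
#' Generates `count` real `size x size` images by shaping the Fourier
#' amplitude of white Gaussian noise as `frequency^(-spectral_exponent)`
#' (zero frequency set to 0). `spectral_exponent = 1` emulates the ~1/f
#' amplitude-spectrum fall-off of natural images; `0` gives white noise.
#'
#' @param count number of images (>= 1).
#' @param size image side in pixels (>= 8).
#' @param spectral_exponent exponent of the radial amplitude fall-off.
#' @param seed integer seed.
#' @return An [image_stack] of `count` images.
#' @export
generate_pink_noise_images <- function(count, size, spectral_exponent = 1,
                                       seed = 1L) {
  if (size < 8L) stopf("size must be >= 8")
  if (count < 1L) stopf("count must be >= 1")
  f1 <- fft_freqs(size)
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  gain <- ifelse(fr > 0, fr^(-spectral_exponent), 0)
  with_seed(seed, {
    imgs <- array(0, dim = c(size, size, count))
    for (i in seq_len(count)) {
      w <- matrix(rnorm(size * size), size, size)
      spec <- stats::fft(w) * gain
      img <- Re(stats::fft(spec, inverse = TRUE)) / (size * size)
      imgs[, , i] <- img
    }
    image_stack(imgs, provenance = sprintf("synthetic 1/f^%g noise",
                                           spectral_exponent))
  })
}

# DFT frequencies (cycles/pixel) for an n-point axis.
fft_freqs <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k <= n %/% 2, k, k - n) / n
}

#' Extract random patches from an image stack
#'
#' Samples `count` patches at uniformly random images and positions and
#' stacks their row-major vectorizations as columns. Output columns are
#' unnormalized; see [normalize_patches()].
#'
#' @param images an [image_stack].
#' @param patch_size `(height, width)` of each patch; must fit in the images.
#' @param count number of patches.
#' @param seed integer seed.
#' @return An unnormalized [patch_matrix].
#' @export
extract_patches <- function(images, patch_size, count, seed = 1L) {
  stopifnot(inherits(images, "image_stack"))
  d <- dim(images$pixels)
  h <- as.integer(patch_size[1]); w <- as.integer(patch_size[2])
  if (h > d[1] || w > d[2]) stopf("patch (%d x %d) larger than image (%d x %d)",
                                  h, w, d[1], d[2])
  with_seed(seed, {
    out <- matrix(0, h * w, count)
    for (j in seq_len(count)) {
      im <- sample.int(d[3], 1L)
      r0 <- sample.int(d[1] - h + 1L, 1L)
      c0 <- sample.int(d[2] - w + 1L, 1L)
      out[, j] <- vectorize_rowmajor(
        images$pixels[r0:(r0 + h - 1L), c0:(c0 + w - 1L), im])
    }
    patch_matrix(out, c(h, w), normalized = FALSE)
  })
}

# Population (divide-by-n) standard deviation per column.
col_sd_pop <- function(X) {
  mu <- colMeans(X)
  sqrt(colMeans(X^2) - mu^2)
}

#' Normalize patches to zero mean and unit standard deviation
#'
#' Centers and scales every column to mean 0 and population (divide-by-n)
#' standard deviation 1. Near-constant columns (std below
#' `reject_std_below`) cannot be scaled meaningfully and are dropped; the
#' number dropped is recorded in attribute `n_rejected`.
#'
#' @param P a [patch_matrix] or bare matrix.
#' @param reject_std_below columns with population std below this are
#'   dropped. Default `1e-6`.
#' @return A normalized [patch_matrix]; attribute `n_rejected` counts
#'   dropped columns. Errors if every column is rejected.
#' @export
normalize_patches <- function(P, reject_std_below = 1e-6) {
  shape <- if (inherits(P, "patch_matrix")) P$patch_shape else NULL
  X <- as_data_matrix(P)
  sds <- col_sd_pop(X)
  keep <- sds >= reject_std_below
  if (!any(keep)) stopf("all %d columns rejected (std < %g)", ncol(X),
                        reject_std_below)
  X <- X[, keep, drop = FALSE]
  sds <- sds[keep]
  X <- sweep(X, 2L, colMeans(X), "-")
  X <- sweep(X, 2L, sds, "/")
  if (is.null(shape)) shape <- c(nrow(X), 1L)
  out <- patch_matrix(X, shape, normalized = TRUE)
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Stack normalized frames into spatio-temporal patches
#'
#' Builds spatio-temporal inputs by stacking `frames` single-frame patch
#' matrices column-wise in temporal order. Each frame is normalized (zero
#' mean, unit population std) before stacking; the stacked column is not
#' re-normalized. Columns whose std is degenerate in any frame are dropped
#' from all frames to keep the temporal alignment.
#'
#' @param patch_sequences list of `frames` matrices or [patch_matrix]
#'   objects with identical shapes, each holding the same patches at one
#'   time step.
#' @param frames number of time steps; must equal
#'   `length(patch_sequences)`.
#' @param reject_std_below per-frame degeneracy threshold.
#' @return A [patch_matrix] with `patch_shape = (h, w, frames)`.
#' @export
concatenate_temporal <- function(patch_sequences, frames = length(patch_sequences),
                                 reject_std_below = 1e-6) {
  if (frames < 1L || length(patch_sequences) != frames) {
    stopf("`patch_sequences` must hold exactly `frames` = %d elements", frames)
  }
  shapes <- lapply(patch_sequences, function(p) {
    if (inherits(p, "patch_matrix")) p$patch_shape else c(nrow(as.matrix(p)), 1L)
  })
  mats <- lapply(patch_sequences, as_data_matrix)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stopf("all frames must share the same dimensions")
  }
  shape0 <- shapes[[1]]
  if (length(shape0) != 2L) stopf("frames must be single (2-D) patches")
  keep <- Reduce("&", lapply(mats, function(X) col_sd_pop(X) >= reject_std_below))
  if (!any(keep)) stopf("all columns rejected during temporal concatenation")
  norm_frames <- lapply(mats, function(X) {
    X <- X[, keep, drop = FALSE]
    X <- sweep(X, 2L, colMeans(X), "-")
    sweep(X, 2L, col_sd_pop(X), "/")
  })
  patch_matrix(do.call(rbind, norm_frames), c(shape0, frames),
               normalized = FALSE)
}

#' Signals with planted k-sparse codes under a known dictionary
#'
#' Each column is `x = A s + e` where `s` has exactly `k` nonzeros (uniform
#' support, standard-normal amplitudes) and `e` is i.i.d. Gaussian noise of
#' standard deviation `noise_sigma`. The true codes make solver recovery
#' testable.
#'
#' @param A a dictionary (see [init_dictionary()]) or `n x m` matrix with
#'   unit-norm columns.
#' @param k nonzeros per code, `0 <= k <= m`.
#' @param T_samples number of columns to generate.
#' @param noise_sigma additive noise standard deviation (0 for noiseless).
#' @param seed integer seed.
#' @return list with `X` (a [patch_matrix] tagged unnormalized) and
#'   `codes` (`m x T` matrix of true coefficients).
#' @export
generate_planted_codes <- function(A, k, T_samples, noise_sigma = 0,
                                   seed = 1L) {
  Amat <- dict_matrix(A)
  m <- ncol(Amat); n <- nrow(Amat)
  if (k > m) stopf("k = %d exceeds dictionary size m = %d", k, m)
  if (k < 0L) stopf("k must be nonnegative")
  with_seed(seed, {
    S <- matrix(0, m, T_samples)
    for (j in seq_len(T_samples)) {
      if (k > 0L) S[sample.int(m, k), j] <- rnorm(k)
    }
    X <- Amat %*% S
    if (noise_sigma > 0) X <- X + matrix(rnorm(n * T_samples, sd = noise_sigma),
                                         n, T_samples)
    list(X = patch_matrix(X, c(n, 1L), normalized = FALSE), codes = S)
  })
}

#' Evaluate a Gabor function on a pixel grid
#'
#' A Gabor patch is a Gaussian envelope times a cosine carrier:
#' `a * exp(-xr^2/(2 sigma_x^2) - yr^2/(2 sigma_y^2)) * cos(2 pi f xr + phi)`
#' where `(xr, yr)` are the pixel coordinates rotated by the orientation
#' `theta` (normal to the stripes) about the center `(x0, y0)`. Pixel
#' coordinates are 0-based with (0,0) at top-left; `x` runs along columns
#' and `y` along rows.
#'
#' @param params named list or [gabor_params()] with `x0`, `y0`, `theta`,
#'   `f` (cycles/pixel), `phi`, `sigma_x`, `sigma_y`, and optionally
#'   `amplitude` (default 1).
#' @param size patch side in pixels (>= 4).
#' @return `size x size` numeric matrix.
#' @export
generate_gabor_patch <- function(params, size) {
  if (size < 4L) stopf("size must be >= 4")
  p <- as.list(params)
  if (is.null(p$amplitude)) p$amplitude <- 1
  if (p$sigma_x <= 0 || p$sigma_y <= 0) stopf("envelope widths must be positive")
  xy <- seq_len(size) - 1L
  X <- matrix(rep(xy, each = size), size, size)   # column index per pixel
  Y <- matrix(rep(xy, times = size), size, size)  # row index per pixel
  dx <- X - p$x0; dy <- Y - p$y0
  xr <- dx * cos(p$theta) + dy * sin(p$theta)
  yr <- -dx * sin(p$theta) + dy * cos(p$theta)
  env <- exp(-xr^2 / (2 * p$sigma_x^2) - yr^2 / (2 * p$sigma_y^2))
  p$amplitude * env * cos(2 * pi * p$f * xr + p$phi)
}
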