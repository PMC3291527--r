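test_that("planted low-rank plus sparse decompositions are exact and honor their parameters", {
  pl <- generate_lowrank_sparse(50, 50, 3, 0.1, magnitude = 2, seed = 11)
  expect_identical(pl$M, pl$L0 + pl$S0)
  expect_equal(sum(pl$S0 != 0), floor(0.1 * 50 * 50))
  expect_true(all(abs(pl$S0[pl$S0 != 0]) == 2))
  d <- svd(pl$L0, nu = 0, nv = 0)$d
  expect_equal(sum(d > 1e-10 * d[1]), 3)

  # degenerate corners
  z <- generate_lowrank_sparse(10, 12, 0, 0.1, seed = 1)
  expect_true(all(z$L0 == 0))
  nosparse <- generate_lowrank_sparse(10, 12, 2, 0, seed = 1)
  expect_true(all(nosparse$S0 == 0))
  expect_identical(nosparse$M, nosparse$L0)

  expect_error(generate_lowrank_sparse(10, 10, 11, 0.1), "rank_r")
})

test_that("generators are pure functions of their seed", {
  a <- generate_lowrank_sparse(20, 20, 2, 0.05, seed = 5)
  b <- generate_lowrank_sparse(20, 20, 2, 0.05, seed = 5)
  expect_identical(a, b)
  i1 <- generate_pink_noise_images(3, 16, 1, seed = 9)
  i2 <- generate_pink_noise_images(3, 16, 1, seed = 9)
  expect_identical(i1$pixels, i2$pixels)
  p1 <- extract_patches(i1, c(8, 8), 20, seed = 4)
  p2 <- extract_patches(i2, c(8, 8), 20, seed = 4)
  expect_identical(p1$data, p2$data)
  g1 <- generate_planted_codes(init_dictionary(6, 10, seed = 2), 2, 5, 0.1, seed = 3)
  g2 <- generate_planted_codes(init_dictionary(6, 10, seed = 2), 2, 5, 0.1, seed = 3)
  expect_identical(g1$X$data, g2$X$data)
})

test_that("pink-noise images follow the requested amplitude power law", {
  # exponent 1: mid-band log-log slope of the radial amplitude spectrum ~ -1
  st <- generate_pink_noise_images(200, 64, 1, seed = 21)
  sp <- radial_amplitude_spectrum(st, n_bins = 24)
  mid <- sp$frequency > 0.06 & sp$frequency < 0.4
  fitc <- stats::coef(stats::lm(log(amplitude) ~ log(frequency), data = sp[mid, ]))
  expect_lt(abs(fitc[2] - (-1)), 0.1)

  # exponent 0 is white noise: flat mid-band spectrum
  w <- generate_pink_noise_images(200, 32, 0, seed = 22)
  spw <- radial_amplitude_spectrum(w, n_bins = 12)
  midw <- spw$frequency > 0.06
  expect_lt(diff(range(spw$amplitude[midw])) / mean(spw$amplitude[midw]), 0.2)

  one <- generate_pink_noise_images(1, 16, 1, seed = 1)
  expect_equal(dim(one$pixels)[3], 1)
  expect_true(all(abs(Im(one$pixels)) == 0))
})

test_that("patch extraction vectorizes row-major and respects bounds", {
  img <- matrix(seq_len(12), 3, 4, byrow = TRUE)
  st <- image_stack(array(img, c(3, 4, 1)))
  p <- extract_patches(st, c(3, 4), 1, seed = 1)
  expect_equal(p$data[, 1], as.numeric(t(img)))  # row-major flattening
  expect_equal(p$patch_shape, c(3L, 4L))

  const <- image_stack(array(7, c(4, 4, 2)))
  pc <- extract_patches(const, c(2, 2), 5, seed = 1)
  expect_true(all(apply(pc$data, 2, function(v) all(v == 7))))

  expect_error(extract_patches(st, c(5, 2), 1), "larger")
})

test_that("patch normalization gives zero mean, unit population std, and is idempotent", {
  P <- tiny_patches(seed = 3, n_patches = 50)
  expect_true(all(abs(colMeans(P$data)) < 1e-8))
  sds <- sqrt(colMeans(P$data^2) - colMeans(P$data)^2)
  expect_true(all(abs(sds - 1) < 1e-6))

  P2 <- normalize_patches(P)
  expect_lt(max(abs(P2$data - P$data)), 1e-12)

  # population-std convention: (0, 2) -> (-1, 1)
  one <- normalize_patches(matrix(c(0, 2), 2, 1))
  expect_equal(one$data[, 1], c(-1, 1))

  # constant columns are dropped and counted
  X <- cbind(c(1, 2, 3), c(5, 5, 5))
  out <- normalize_patches(patch_matrix(X, c(3, 1)))
  expect_equal(ncol(out$data), 1)
  expect_equal(attr(out, "n_rejected"), 1)
  expect_error(normalize_patches(matrix(1, 3, 2)), "rejected")
})

test_that("temporal concatenation stacks normalized frames in order", {
  frames <- lapply(1:16, function(i) {
    patch_matrix(matrix(rnorm(64 * 5, mean = i), 64, 5), c(8, 8))
  })
  out <- concatenate_temporal(frames, 16)
  expect_equal(nrow(out$data), 1024)  # 16 frames of 8x8
  expect_equal(out$patch_shape, c(8L, 8L, 16L))
  # each 64-row block is the normalized frame
  blk2 <- out$data[65:128, ]
  expect_true(all(abs(colMeans(blk2)) < 1e-8))

  # frames = 1 reduces to static vectorization (after normalization)
  single <- concatenate_temporal(frames[1], 1)
  expect_equal(single$data, normalize_patches(frames[[1]])$data)

  # reordering frames permutes the row blocks
  swapped <- concatenate_temporal(frames[c(2, 1, 3:16)], 16)
  expect_equal(swapped$data[1:64, ], out$data[65:128, ])
  expect_equal(swapped$data[65:128, ], out$data[1:64, ])

  bad <- c(frames[1:15], list(patch_matrix(matrix(0.5 + rnorm(36 * 5), 36, 5), c(6, 6))))
  expect_error(concatenate_temporal(bad, 16), "same dimensions")
})

test_that("planted codes have exactly k nonzeros and zero noiseless residual", {
  A <- init_dictionary(10, 40, seed = 6)
  g <- generate_planted_codes(A, 3, 25, 0, seed = 7)
  expect_true(all(colSums(g$codes != 0) == 3))
  expect_lt(max(abs(g$X$data - A$A %*% g$codes)), 1e-12)

  g0 <- generate_planted_codes(A, 0, 5, 0.5, seed = 8)
  expect_true(all(g0$codes == 0))
  expect_error(generate_planted_codes(A, 41, 5, 0), "exceeds")
})

test_that("Gabor patches obey their closed-form symmetries", {
  base <- list(x0 = 7.2, y0 = 8.1, theta = 0.7, f = 0.2, phi = 0.4,
               sigma_x = 2.5, sigma_y = 1.8)
  # f = 0, phi = 0: pure Gaussian envelope
  g0 <- generate_gabor_patch(modifyList(base, list(f = 0, phi = 0)), 16)
  expect_true(all(g0 > 0))
  expect_equal(max(g0), g0[which.max(g0)])

  # (theta + pi, -phi) equivalence
  g1 <- generate_gabor_patch(base, 16)
  g2 <- generate_gabor_patch(modifyList(base, list(theta = base$theta + pi,
                                                   phi = -base$phi)), 16)
  expect_lt(max(abs(g1 - g2)), 1e-12)

  # isotropic envelope is rotation invariant (compare envelope at rotated thetas)
  iso <- modifyList(base, list(sigma_x = 2, sigma_y = 2, f = 0, phi = 0))
  e1 <- generate_gabor_patch(iso, 16)
  e2 <- generate_gabor_patch(modifyList(iso, list(theta = iso$theta + 1.1)), 16)
  expect_lt(max(abs(e1 - e2)), 1e-10)

  expect_error(generate_gabor_patch(modifyList(base, list(sigma_x = 0)), 16),
               "widths")
})
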