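# Small fixtures shared across test files; everything is generated in code.

relerr <- function(est, truth) {
  sqrt(sum((est - truth)^2)) / sqrt(sum(truth^2))
}

# A tiny normalized patch matrix from synthetic 1/f images.
tiny_patches <- function(seed = 1L, n_patches = 200L, patch_side = 8L,
                         image_size = 32L) {
  imgs <- generate_pink_noise_images(8L, image_size, 1, seed = seed)
  normalize_patches(extract_patches(imgs, c(patch_side, patch_side),
                                    n_patches, seed = seed + 1L))
}

# Exhaustive search over all K-supports: minimal residual norm.
brute_force_residual <- function(A, y, K) {
  Amat <- if (inherits(A, "sc_dictionary")) A$A else A
  combs <- utils::combn(ncol(Amat), K)
  best <- Inf
  for (j in seq_len(ncol(combs))) {
    rn <- least_squares_on_support(Amat, y, combs[, j])$residual_norm
    if (rn < best) best <- rn
  }
  best
}
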