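# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched, so every generator is a pure function of its
# arguments plus the seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

fnorm <- function(x) sqrt(sum(x^2))

# Indices of the k largest values of |x|, ties broken by lowest index.
top_k_abs <- function(x, k) {
  if (k <= 0L) return(integer(0))
  k <- min(k, length(x))
  order(-abs(x), seq_along(x))[seq_len(k)]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_finite <- function(x, name) {
  if (!all(is.finite(x))) stopf("`%s` must contain only finite values", name)
}

# Row-major vectorization of a 2-D (or 3-D, frame-by-frame) patch: pixel
# (0,0) is top-left and columns vary fastest within a row.
vectorize_rowmajor <- function(patch) {
  if (length(dim(patch)) == 3L) {
    as.vector(apply(patch, 3L, function(fr) as.vector(t(fr))))
  } else {
    as.vector(t(patch))
  }
}
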