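# File interchange: matrices as TSV with a small attribute header, images
# from PNG/PGM, and filter mosaics to PNG.

#' Write a matrix as TSV with attribute header lines
#'
#' Plain-text matrix container: `#key=value` header lines followed by
#' tab-separated numeric rows. Round-trips through [read_matrix_tsv()].
#'
#' @param mat numeric matrix, [patch_matrix] or [dictionary()] (their
#'   geometry is stored in the header).
#' @param path output file.
#' @param attrs named list of scalar attributes to store.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, attrs = list()) {
  if (inherits(mat, "patch_matrix")) {
    attrs$patch_shape <- paste(mat$patch_shape, collapse = ",")
    attrs$normalized <- mat$normalized
  } else if (inherits(mat, "sc_dictionary")) {
    attrs$n <- mat$n; attrs$m <- mat$m
    mat <- mat$A
  }
  X <- as_data_matrix(mat)
  con <- file(path, "w")
  for (k in names(attrs)) {
    writeLines(sprintf("#%s=%s", k, as.character(attrs[[k]])), con)
  }
  close(con)
  data.table::fwrite(data.table::as.data.table(X), path, sep = "\t",
                     append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path input file.
#' @return numeric matrix; header keys are returned in attribute `attrs`.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path, n = 100L)
  hdr <- grep("^#", lines, value = TRUE)
  attrs <- list()
  for (h in hdr) {
    kv <- sub("^#", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) attrs[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  X <- as.matrix(data.table::fread(path, sep = "\t", skip = length(hdr),
                                   header = FALSE))
  dimnames(X) <- NULL
  attr(X, "attrs") <- attrs
  X
}

#' Read a grayscale image into an image stack
#'
#' Supports PNG (via the png package; color images are averaged to
#' grayscale) and ASCII/binary PGM (P2/P5).
#'
#' @param path image file; format chosen by extension.
#' @return An [image_stack] with one image.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    img <- if (length(dim(a)) == 3L) apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                           c(1, 2), mean) else a
  } else if (ext == "pgm") {
    img <- read_pgm(path)
  } else stopf("unsupported image format: '%s'", ext)
  image_stack(array(img, dim = c(dim(img), 1L)), provenance = basename(path))
}

# Minimal PGM (P2 ASCII / P5 binary) reader.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stopf("not a PGM file (magic '%s')", magic)
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L)
    if (length(ch) == 0L || ch == "") stopf("truncated PGM header")
    if (ch == "#") { # comment to end of line
      repeat {
        ch <- readChar(con, 1L)
        if (length(ch) == 0L || ch %in% c("\n", "")) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
        buf <- character(0)
      }
    } else buf <- c(buf, ch)
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "integer", n = w * h,
                       size = if (maxval < 256) 1L else 2L,
                       signed = FALSE, endian = "big"))
  } else {
    as.integer(scan(con, what = integer(), n = w * h, quiet = TRUE))
  }
  matrix(vals / maxval, h, w, byrow = TRUE)
}

#' Write a filter mosaic as PNG
#'
#' Tiles filters (columns reshaped row-major to `side x side`) into a grid;
#' each tile is min-max scaled to `[0, 1]` independently, with a 1-pixel
#' separator between tiles.
#'
#' @param filters [dictionary()] or matrix, filters in columns.
#' @param side patch side.
#' @param path output PNG path.
#' @param ncol tiles per row. Default `ceiling(sqrt(#filters))`.
#' @return `path`, invisibly.
#' @export
write_filter_mosaic_png <- function(filters, side, path, ncol = NULL) {
  Fm <- dict_matrix(filters)
  if (nrow(Fm) != side^2) stopf("filter length %d is not %d^2", nrow(Fm), side)
  nf <- ncol(Fm)
  if (is.null(ncol)) ncol <- ceiling(sqrt(nf))
  nrow_t <- ceiling(nf / ncol)
  canvas <- matrix(1, nrow_t * (side + 1) + 1, ncol * (side + 1) + 1)
  for (j in seq_len(nf)) {
    tile <- matrix(Fm[, j], side, side, byrow = TRUE)
    rng <- range(tile)
    tile <- if (diff(rng) > 0) (tile - rng[1]) / diff(rng) else tile * 0 + 0.5
    r0 <- ((j - 1) %/% ncol) * (side + 1) + 2
    c0 <- ((j - 1) %% ncol) * (side + 1) + 2
    canvas[r0:(r0 + side - 1), c0:(c0 + side - 1)] <- tile
  }
  png::writePNG(canvas, path)
  invisible(path)
}
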