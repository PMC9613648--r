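#' RGB image arrays
#'
#' The package represents every image as a plain numeric `H x W x 3` array of
#' intensities on the canonical `[0, 255]` scale (8-bit files map 1:1). All
#' augmentations transform these arrays; there is no heavier image class.
#'
#' @param x A 2-D matrix (grayscale) or an `H x W x 3` array.
#' @return An `H x W x 3` numeric array.
#' @details `to_rgb()` promotes a grayscale image by replicating it into three
#'   identical channels, so `I_R = I_G = I_B`; a 3-channel input passes through
#'   unchanged (idempotent). Any other channel count is an error.
#' @examples
#' gray <- matrix(5, 2, 2)
#' img <- to_rgb(gray)
#' dim(img)
#' @export
to_rgb <- function(x) {
  if (!is.numeric(x)) abort("image must be numeric")
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(2L, 3L))) {
    abort("image must be a 2-D matrix or an H x W x C array")
  }
  if (length(d) == 2L) {
    out <- array(x, dim = c(d, 3L))
  } else if (d[3] == 1L) {
    out <- array(x[, , 1L], dim = c(d[1:2], 3L))
  } else if (d[3] == 3L) {
    out <- x
  } else {
    abort(sprintf("channel count must be 1 or 3, got %d", d[3]))
  }
  if (!all(is.finite(out))) abort("image intensities must be finite")
  out
}

assert_rgb_image <- function(x, arg = "image") {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L || d[3] != 3L || !is.numeric(x)) {
    abort(sprintf("%s must be an H x W x 3 numeric array", arg))
  }
  invisible(x)
}

#' Clip intensities to the canonical range
#'
#' @param x Numeric array.
#' @param lo,hi Range bounds (default the canonical `[0, 255]`).
#' @return `x` with every value clamped into `[lo, hi]`.
#' @export
clip_intensities <- function(x, lo = 0, hi = 255) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

#' Read / write a single cell image
#'
#' PNG and TIFF files are supported. File intensities in `[0, 1]` are mapped to
#' the canonical `[0, 255]` scale; grayscale files are promoted to RGB and an
#' alpha channel, if present, is dropped.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return An `H x W x 3` array on the `[0, 255]` scale.
#' @export
read_cell_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such image file: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      tif = ,
      tiff = tiff::readTIFF(path),
      abort(sprintf("unsupported image format '%s' for %s", ext, path))
    ),
    error = function(e) abort(sprintf("failed to read %s: %s", path, conditionMessage(e)))
  )
  d <- dim(raw)
  if (length(d) == 3L && d[3] %in% c(2L, 4L)) {
    raw <- raw[, , seq_len(d[3] - 1L), drop = FALSE] # drop alpha
    if (dim(raw)[3] == 1L) raw <- raw[, , 1L]
  }
  to_rgb(raw * 255)
}

#' @rdname read_cell_image
#' @param image `H x W x 3` array on the `[0, 255]` scale.
#' @export
write_cell_image <- function(image, path) {
  assert_rgb_image(image)
  scaled <- clip_intensities(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(scaled, target = path),
    tif = ,
    tiff = tiff::writeTIFF(scaled, where = path, bits.per.sample = 8L),
    abort(sprintf("unsupported image format '%s' for %s", ext, path))
  )
  invisible(path)
}

#' Classification-time preprocessing
#'
#' Brings an image to the classifier's input size either by bilinear resizing
#' or by extracting the centered window, the two conventions used for
#' single-cell crops (resize for 48x48 RBC-style crops, center crop for 66x66
#' cell-cycle-style crops).
#'
#' @param image `H x W x 3` array.
#' @param target Integer `(H, W)` output size.
#' @param method `"resize_bilinear"` or `"center_crop"`.
#' @return An array of size `target[1] x target[2] x 3`.
#' @details The crop offset is `floor((src - target) / 2)` on both axes; a crop
#'   target larger than the source is an error.
#' @export
preprocess_for_classifier <- function(image, target,
                                      method = c("resize_bilinear", "center_crop")) {
  assert_rgb_image(image)
  method <- match.arg(method)
  target <- as.integer(target)
  if (length(target) != 2L || any(target < 1L)) abort("target must be positive (H, W)")
  d <- dim(image)
  if (method == "center_crop") {
    if (any(target > d[1:2])) {
      abort(sprintf(
        "center_crop target (%d, %d) exceeds source (%d, %d)",
        target[1], target[2], d[1], d[2]
      ))
    }
    off <- (d[1:2] - target) %/% 2L
    image[off[1] + seq_len(target[1]), off[2] + seq_len(target[2]), , drop = FALSE]
  } else {
    if (all(target == d[1:2])) return(image)
    eb <- EBImage::Image(image / 255, colormode = "Color")
    out <- EBImage::resize(eb, w = target[1], h = target[2], filter = "bilinear")
    clip_intensities(EBImage::imageData(out) * 255)
  }
}

# Projective (perspective) warp with bilinear sampling. `m` maps output pixel
# coordinates (row, col, 1) to source coordinates; out-of-bounds samples take
# `fill`. Covers both affine and perspective jitter for pre-GAN enrichment.
warp_image <- function(image, m, fill = NULL) {
  assert_rgb_image(image)
  if (!is.matrix(m) || any(dim(m) != 3L)) abort("m must be a 3 x 3 matrix")
  d <- dim(image)
  h <- d[1]; w <- d[2]
  if (is.null(fill)) fill <- stats::median(image)
  grid <- cbind(
    rep(seq_len(h), times = w),
    rep(seq_len(w), each = h),
    1
  )
  src <- grid %*% t(m)
  sr <- src[, 1] / src[, 3]
  sc <- src[, 2] / src[, 3]
  inside <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
  r0 <- pmin(pmax(floor(sr), 1), h - 1)
  c0 <- pmin(pmax(floor(sc), 1), w - 1)
  fr <- sr - r0; fc <- sc - c0
  out <- array(fill, dim = d)
  if (any(inside)) {
    r0i <- r0[inside]; c0i <- c0[inside]
    fri <- fr[inside]; fci <- fc[inside]
    for (ch in 1:3) {
      plane <- image[, , ch]
      i00 <- plane[cbind(r0i, c0i)]
      i10 <- plane[cbind(r0i + 1, c0i)]
      i01 <- plane[cbind(r0i, c0i + 1)]
      i11 <- plane[cbind(r0i + 1, c0i + 1)]
      val <- i00 * (1 - fri) * (1 - fci) + i10 * fri * (1 - fci) +
        i01 * (1 - fri) * fci + i11 * fri * fci
      chan <- out[, , ch]
      chan[inside] <- val
      out[, , ch] <- chan
    }
  }
  out
}
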