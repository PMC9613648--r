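#' Sample a mixup coefficient
#'
#' Draws the mixup coefficient lambda uniformly on `[lam_low, lam_high]`.
#' The default bounds 0.15 and 0.85 keep the blended image dissimilar from
#' both reference images; a fresh lambda is drawn for every generated sample.
#' Randomness comes from R's global RNG, so calls are reproducible under
#' `set.seed()`.
#'
#' @param n Number of draws.
#' @param lam_low,lam_high Bounds, `0 <= lam_low <= lam_high <= 1`.
#' @return Numeric vector of length `n`.
#' @export
sample_lambda <- function(n = 1L, lam_low = 0.15, lam_high = 0.85) {
  if (!(is.numeric(lam_low) && is.numeric(lam_high)) ||
      lam_low > lam_high || lam_low < 0 || lam_high > 1) {
    abort("require 0 <= lam_low <= lam_high <= 1")
  }
  runif(n, lam_low, lam_high)
}

#' Standard mixup of two images
#'
#' Weighted linear interpolation `lam * i1 + (1 - lam) * i2`, applied
#' elementwise. Because both reference images share a class (pairs are drawn
#' within class), the blend keeps that class label; no label mixing is done.
#'
#' @param i1,i2 `H x W x 3` arrays with identical dimensions.
#' @param lam Mixup coefficient in `[0, 1]`.
#' @return The blended `H x W x 3` array. Every output pixel lies in the
#'   convex hull of the corresponding input pixels, so no clipping is needed.
#' @examples
#' a <- array(2, c(4, 4, 3)); b <- array(4, c(4, 4, 3))
#' mixup(a, b, 0.25)[1, 1, 1] # 3.5
#' @export
mixup <- function(i1, i2, lam) {
  assert_rgb_image(i1, "i1"); assert_rgb_image(i2, "i2")
  if (!all(dim(i1) == dim(i2))) abort("i1 and i2 must have identical dimensions")
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0 || lam > 1) {
    abort("lam must be a single value in [0, 1]")
  }
  lam * i1 + (1 - lam) * i2
}

#' Select a reference pair from a class pool
#'
#' Two distinct images are drawn uniformly without replacement from the pool —
#' in the full pipeline, the combined set of original and WGAN-div generated
#' images of one class.
#'
#' @param pool List of `H x W x 3` arrays of one class, length at least 2.
#' @return A list of the two selected images, with an `indices` attribute.
#' @export
select_pair <- function(pool) {
  if (!is.list(pool) || length(pool) < 2L) {
    abort("pool must contain at least 2 images")
  }
  idx <- sample.int(length(pool), 2L, replace = FALSE)
  structure(pool[idx], indices = idx)
}

#' Bilinear-interpolation mixup (double mixup)
#'
#' Applies standard mixup to the two synthetic images obtained from the
#' standard mixup of two pairs of reference images:
#' `mixup(mixup(i1, i2, lam_a), mixup(i3, i4, lam_b), lam_c)`. Exposed for
#' comparison studies; the default pipeline does not use it, since applying
#' the interpolation twice drifts the result away from the original pixel
#' distribution and weakens the regularisation effect, though it can be useful
#' when out-of-distribution sampling is desired.
#'
#' @param i1,i2,i3,i4 `H x W x 3` arrays with identical dimensions.
#' @param lam_a,lam_b,lam_c Mixup coefficients in `[0, 1]`.
#' @return The doubly blended `H x W x 3` array.
#' @export
bilinear_mixup <- function(i1, i2, i3, i4, lam_a, lam_b, lam_c) {
  mixup(mixup(i1, i2, lam_a), mixup(i3, i4, lam_b), lam_c)
}
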