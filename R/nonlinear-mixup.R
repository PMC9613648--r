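#' Colour-axis rotation specification
#'
#' A nonlinear-mixup rotation is defined by one colour axis (`"R"`, `"G"` or
#' `"B"`) and an angle `theta` in degrees. Each pixel of an image, viewed as a
#' point `(I_R, I_G, I_B)` in the RGB colour cube, is rotated about that axis:
#' rotation about B, for instance, moves the pixel on the circle centred at
#' `(0, 0, I_B)` with radius `sqrt(I_R^2 + I_G^2)`.
#'
#' @param axis One of `"R"`, `"G"`, `"B"`.
#' @param theta Angle in degrees (finite).
#' @return A `rotation_spec` object.
#' @export
rotation_spec <- function(axis, theta) {
  axis <- as.character(axis)
  if (length(axis) != 1L || !axis %in% c("R", "G", "B")) {
    abort("axis must be one of 'R', 'G', 'B'")
  }
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta)) {
    abort("theta must be a single finite angle in degrees")
  }
  structure(list(axis = axis, theta = theta), class = "rotation_spec")
}

#' Sample a random rotation
#'
#' The axis is uniform over \{R, G, B\} and `theta` uniform over
#' `[0, 360)` degrees; both are redrawn on every call, so each generated
#' image gets its own rotation.
#'
#' @return A `rotation_spec`.
#' @export
sample_rotation <- function() {
  rotation_spec(sample(c("R", "G", "B"), 1L), runif(1L, 0, 360))
}

#' 3D rotation matrix about a colour axis
#'
#' Returns the 3 x 3 rotation matrix for the given axis and angle, in the
#' row-vector convention: a pixel row vector `(I_R, I_G, I_B)` is transformed
#' as `pixel %*% rotation_matrix(spec)`. The matrices are orthogonal with
#' determinant 1 and leave the chosen axis component unchanged.
#'
#' @param spec A [rotation_spec()].
#' @return A 3 x 3 numeric matrix.
#' @export
rotation_matrix <- function(spec) {
  stopifnot(inherits(spec, "rotation_spec"))
  th <- spec$theta * pi / 180
  cs <- cos(th); sn <- sin(th)
  switch(spec$axis,
    R = matrix(c(
      1, 0, 0,
      0, cs, -sn,
      0, sn, cs
    ), 3, 3, byrow = TRUE),
    G = matrix(c(
      cs, 0, sn,
      0, 1, 0,
      -sn, 0, cs
    ), 3, 3, byrow = TRUE),
    B = matrix(c(
      cs, -sn, 0,
      sn, cs, 0,
      0, 0, 1
    ), 3, 3, byrow = TRUE)
  )
}

#' Rotate a single pixel in RGB colour space
#'
#' @param pixel Numeric length-3 vector `(I_R, I_G, I_B)`.
#' @param spec A [rotation_spec()].
#' @return The rotated length-3 vector (no clipping at this level; the
#'   component along the rotation axis is unchanged and the Euclidean norm is
#'   preserved).
#' @export
rotate_pixel <- function(pixel, spec) {
  if (!is.numeric(pixel) || length(pixel) != 3L || !all(is.finite(pixel))) {
    abort("pixel must be a finite numeric vector of length 3")
  }
  drop(matrix(pixel, 1, 3) %*% rotation_matrix(spec))
}

#' Rotate every pixel of an image about a colour axis
#'
#' Applies one rotation to all pixels (the spatial arrangement is untouched;
#' only colour coordinates move). Rotated intensities can leave the `[0, 255]`
#' cube; by default they are clipped back, which keeps a valid image. Set
#' `clip = FALSE` to inspect raw rotated values.
#'
#' @param image `H x W x 3` array.
#' @param spec A [rotation_spec()].
#' @param clip Clip the result into `[0, 255]`? Default `TRUE`.
#' @return The rotated `H x W x 3` array.
#' @export
rotate_image <- function(image, spec, clip = TRUE) {
  assert_rgb_image(image)
  d <- dim(image)
  px <- matrix(image, d[1] * d[2], 3L)
  out <- array(px %*% rotation_matrix(spec), dim = d)
  if (clip) out <- clip_intensities(out)
  out
}

#' Nonlinear mixup: mixup followed by 3D colour-space rotation
#'
#' Step 1 blends the two reference images with standard [mixup()]. Step 2
#' rotates every pixel of the blend about one colour axis at angle `theta`,
#' using a single `(axis, theta)` pair for the whole image. This combines a
#' spatial-domain interpolation with a colour-space transformation: the result
#' keeps the spatial distribution of the mixup image but a different colour
#' appearance, increasing the diversity of synthetic minority-class samples.
#'
#' With `theta = 0` the rotation is the identity, so the output is
#' bit-identical to `mixup(i1, i2, lam)`. For grayscale-derived images
#' (`I_R = I_G = I_B`) the rotation is still applied and changes hue.
#'
#' @inheritParams mixup
#' @param spec A [rotation_spec()]; defaults to a fresh random draw.
#' @param clip Clip rotated intensities into `[0, 255]`? Default `TRUE`.
#' @return The nonlinear-mixup `H x W x 3` array.
#' @export
nonlinear_mixup <- function(i1, i2, lam, spec = sample_rotation(), clip = TRUE) {
  rotate_image(mixup(i1, i2, lam), spec, clip = clip)
}
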