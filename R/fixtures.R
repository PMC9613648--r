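#' Default fixture class table
#'
#' Morphology parameters for the default five-class toy dataset: two majority
#' classes of about a thousand images each and three minority classes of a
#' few tens, mirroring the long-tailed regime of real single-cell collections
#' where minority morphologies are visually close to a majority class
#' (deliberately low inter-class difference, the hard case for classifiers).
#' Cells are centred elliptical blobs with class-specific radius,
#' eccentricity, intensity and a mild per-channel tint (as from staining),
#' plus Gaussian noise.
#'
#' @return Tibble with one row per class: `name`, `count`, `radius_mean`,
#'   `radius_sd`, `eccentricity`, `fg_mean`, `fg_sd`, `bg`, `noise_sd`,
#'   `tint_r`, `tint_g`, `tint_b`, `minority`.
#' @export
default_fixture_classes <- function() {
  tibble(
    name = c("round_small", "round_large", "mitotic_a", "mitotic_b", "mitotic_c"),
    count = c(1000L, 1000L, 40L, 25L, 15L),
    radius_mean = c(9, 17, 11, 13, 15),
    radius_sd = c(1.2, 1.2, 1.2, 1.2, 1.2),
    eccentricity = c(0.1, 0.1, 0.35, 0.35, 0.2),
    fg_mean = c(150, 150, 170, 130, 180),
    fg_sd = c(12, 12, 12, 12, 12),
    bg = c(30, 30, 30, 30, 30),
    noise_sd = c(10, 10, 10, 10, 10),
    tint_r = c(1, 1, 1, 0.85, 0.9),
    tint_g = c(1, 1, 0.9, 1, 0.9),
    tint_b = c(1, 1, 0.8, 0.9, 1),
    minority = c(FALSE, FALSE, TRUE, TRUE, TRUE)
  )
}

#' Fixture generator configuration
#'
#' @param classes Class table as returned by [default_fixture_classes()]
#'   (columns may be overridden, e.g. smaller `count`s for quick tests).
#' @param image_size Integer `(H, W)`, default 48 x 48.
#' @return A `fixture_config`.
#' @export
fixture_config <- function(classes = default_fixture_classes(),
                           image_size = c(48L, 48L)) {
  required <- c("name", "count", "radius_mean", "radius_sd", "eccentricity",
                "fg_mean", "fg_sd", "bg", "noise_sd", "tint_r", "tint_g",
                "tint_b", "minority")
  missing_cols <- setdiff(required, names(classes))
  if (length(missing_cols)) {
    abort(sprintf("classes table lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  image_size <- as.integer(image_size)
  if (any(classes$count < 1L)) abort("class counts must be >= 1")
  if (any(classes$radius_mean >= min(image_size) / 2)) {
    abort("blob radius must be below half the image size")
  }
  if (any(classes$fg_mean < 0 | classes$fg_mean > 255 | classes$bg < 0 | classes$bg > 255)) {
    abort("intensities must lie in [0, 255]")
  }
  structure(list(classes = classes, image_size = image_size),
            class = "fixture_config")
}

# One blob image. The ellipse is centred (sub-pixel jitter < 0.5 px), with a
# random orientation; edges are smoothed over ~1.5 px.
blob_image <- function(h, w, params) {
  r <- max(2, rnorm(1, params$radius_mean, params$radius_sd))
  fg <- rnorm(1, params$fg_mean, params$fg_sd)
  phi <- runif(1, 0, 2 * pi)
  cy <- (h + 1) / 2 + runif(1, -0.5, 0.5)
  cx <- (w + 1) / 2 + runif(1, -0.5, 0.5)
  a <- r
  b <- r * (1 - params$eccentricity)
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- yy * cos(phi) + xx * sin(phi)
  v <- -yy * sin(phi) + xx * cos(phi)
  dist <- sqrt((u / a)^2 + (v / b)^2)
  mask <- stats::plogis((1 - dist) * r / 1.5)
  base <- params$bg + (fg - params$bg) * mask
  tint <- c(params$tint_r, params$tint_g, params$tint_b)
  img <- array(0, c(h, w, 3L))
  for (ch in 1:3) {
    img[, , ch] <- base * tint[ch] + rnorm(h * w, sd = params$noise_sd)
  }
  clip_intensities(img)
}

#' Generate a toy imbalanced single-cell dataset
#'
#' Seeded, deterministic generator of centred elliptical-blob "cells" with
#' class-dependent morphology, used as the stand-in for real single-cell
#' crops in tests and the end-to-end toy experiment.
#'
#' @param config A [fixture_config()].
#' @param seed Integer seed; the same seed yields a bit-identical dataset.
#' @return A `cell_dataset` with minority flags taken from the class table.
#' @export
make_toy_dataset <- function(config = fixture_config(), seed = 1L) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(seed)
  h <- config$image_size[1]; w <- config$image_size[2]
  cls_tab <- config$classes[order(config$classes$name), ]
  images <- list()
  for (i in seq_len(nrow(cls_tab))) {
    params <- as.list(cls_tab[i, ])
    images[[params$name]] <- lapply(seq_len(params$count), function(j) {
      blob_image(h, w, params)
    })
  }
  cell_dataset(images, minority = cls_tab$name[cls_tab$minority])
}
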