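test_that("toy datasets honour counts, stay in range and are bit-reproducible", {
  classes <- default_fixture_classes()
  classes$count <- c(25L, 25L, 6L, 5L, 4L)
  cfg <- fixture_config(classes)
  d1 <- make_toy_dataset(cfg, seed = 3)
  d2 <- make_toy_dataset(cfg, seed = 3)
  expect_identical(d1, d2)
  counts <- dataset_counts(d1)
  expect_equal(counts$count, classes$count[match(counts$class, classes$name)])
  for (cls in d1$classes) {
    for (img in d1$images[[cls]]) {
      expect_true(all(img >= 0 & img <= 255))
      expect_equal(dim(img), c(48L, 48L, 3L))
    }
  }
  expect_setequal(d1$minority, c("mitotic_a", "mitotic_b", "mitotic_c"))
})

test_that("blob centroids sit within a pixel of the image centre", {
  classes <- default_fixture_classes()[1:2, ]
  classes$count <- c(10L, 10L)
  classes$noise_sd <- c(0, 0)
  ds <- make_toy_dataset(fixture_config(classes), seed = 5)
  for (cls in ds$classes) {
    for (img in ds$images[[cls]]) {
      plane <- img[, , 1] - min(img[, , 1])
      w <- plane / sum(plane)
      cy <- sum(row(plane) * w); cx <- sum(col(plane) * w)
      expect_lt(abs(cy - 24.5), 1)
      expect_lt(abs(cx - 24.5), 1)
    }
  }
})

test_that("classes with distinct radii are separable by a foreground-area threshold", {
  # radius means 6 vs 14 px, sd 1: a threshold between the area distributions
  # classifies a held-out set with > 95% accuracy (distributions ~4 sd apart)
  classes <- default_fixture_classes()[1:2, ]
  classes$name <- c("small", "large")
  classes$count <- c(100L, 100L)
  classes$radius_mean <- c(6, 14)
  classes$radius_sd <- c(1, 1)
  classes$eccentricity <- c(0.1, 0.1)
  classes$minority <- c(FALSE, FALSE)
  ds <- make_toy_dataset(fixture_config(classes, c(40L, 40L)), seed = 6)
  area <- function(img) sum(img[, , 1] > (30 + 150) / 2)
  a_small <- vapply(ds$images$small, area, 0)
  a_large <- vapply(ds$images$large, area, 0)
  thresh <- pi * 10^2 # halfway radius
  acc <- (sum(a_small < thresh) + sum(a_large >= thresh)) / 200
  expect_gt(acc, 0.95)
})

test_that("class-conditional mean images differ above the noise floor", {
  classes <- default_fixture_classes()
  classes$count <- rep(30L, 5)
  ds <- make_toy_dataset(fixture_config(classes), seed = 7)
  mean_img <- function(pool) Reduce(`+`, pool) / length(pool)
  m1 <- mean_img(ds$images$round_small)
  m2 <- mean_img(ds$images$round_large)
  noise_floor <- 10 / sqrt(30) # pixel noise sd shrunk by averaging
  expect_gt(mean(abs(m1 - m2)), 3 * noise_floor)
})

test_that("imbalance ratios divide the largest class count by each class count", {
  ds <- small_blob_dataset(counts = c(1000L, 500L, 30L, 30L, 30L))
  ir <- imbalance_ratio(ds)
  expect_equal(ir$imbalance_ratio[ir$class == "round_large"], 1000 / 500)
  expect_equal(max(ir$imbalance_ratio), 1000 / 30, tolerance = 1e-12)
  expect_equal(min(ir$imbalance_ratio), 1)
  balanced <- small_blob_dataset(counts = rep(10L, 5))
  expect_true(all(imbalance_ratio(balanced)$imbalance_ratio == 1))
  single <- cell_dataset(list(only = list(const_image(1))))
  expect_equal(imbalance_ratio(single)$imbalance_ratio, 1)
})

test_that("invalid morphology parameters are rejected", {
  classes <- default_fixture_classes()
  classes$count[1] <- 0L
  expect_error(fixture_config(classes), "counts")
  classes <- default_fixture_classes()
  classes$radius_mean[1] <- 40
  expect_error(fixture_config(classes), "radius")
  classes <- default_fixture_classes()
  classes$fg_mean[1] <- 300
  expect_error(fixture_config(classes), "intensities")
})
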