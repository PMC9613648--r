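# Shared in-code fixtures: tiny deterministic images and datasets.

const_image <- function(value, h = 4L, w = 4L) array(value, c(h, w, 3L))

random_image <- function(h = 6L, w = 6L) array(runif(h * w * 3L, 0, 255), c(h, w, 3L))

# Small imbalanced blob dataset (40x40 so the default morphologies fit).
small_blob_dataset <- function(seed = 42L,
                               counts = c(30L, 30L, 8L, 6L, 5L),
                               image_size = c(40L, 40L)) {
  classes <- default_fixture_classes()
  classes$count <- as.integer(counts)
  make_toy_dataset(fixture_config(classes, image_size), seed = seed)
}

# Deterministic stand-in "wgan" pools: noisy copies of class images.
fake_pools <- function(dataset, per_class = 6L, seed = 7L) {
  set.seed(seed)
  pools <- list()
  for (cls in dataset$minority) {
    src <- dataset$images[[cls]]
    pools[[cls]] <- lapply(seq_len(per_class), function(i) {
      img <- src[[(i %% length(src)) + 1L]]
      clip_intensities(img + array(rnorm(length(img), sd = 5), dim = dim(img)))
    })
  }
  pools
}
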