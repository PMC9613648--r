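#' Minority-focussed sampler configuration
#'
#' Each mini-batch of original images is supplemented with a batch of only
#' synthetic minority-class images. Per oversampling unit `n` of a minority
#' class, the supplement contains exactly 4 images: 2 WGAN-div, 1 mixup and
#' 1 nonlinear mixup. The total batch size must be a power of two `2^m`
#' (`m` usually > 4), so the configuration must satisfy
#' `originals_per_batch + 4 * sum(n) == 2^m`.
#'
#' @param n_per_class Named integer vector mapping minority class names to
#'   their oversampling factor `n` (>= 0). May be empty.
#' @param originals_per_batch Original images per batch (>= 1).
#' @param m Batch exponent; total batch size is `2^m`.
#' @param pad_last How the final, partial original chunk of an epoch is
#'   handled: `TRUE` (default) pads it with originals resampled with
#'   replacement so every batch keeps size `2^m`; `FALSE` drops it.
#' @return A `sampler_config`.
#' @examples
#' # cell-cycle-style setup: 8 originals + n = (2, 2, 1, 1) -> 32
#' sampler_config(c(ana = 2, meta = 2, pro = 1, telo = 1), 8, m = 5)
#' @export
sampler_config <- function(n_per_class, originals_per_batch, m,
                           pad_last = TRUE) {
  n_per_class <- if (length(n_per_class)) {
    v <- as.integer(n_per_class)
    names(v) <- names(n_per_class)
    v
  } else integer(0)
  if (length(n_per_class) && (is.null(names(n_per_class)) || any(names(n_per_class) == ""))) {
    abort("n_per_class must be a named vector (minority class -> n)")
  }
  if (any(n_per_class < 0L)) abort("oversampling factors n must be >= 0")
  originals_per_batch <- as.integer(originals_per_batch)
  m <- as.integer(m)
  if (originals_per_batch < 1L) abort("originals_per_batch must be >= 1")
  total <- originals_per_batch + 4L * sum(n_per_class)
  if (total != 2L^m) {
    abort(sprintf(
      "originals_per_batch + 4 * sum(n) = %d + %d = %d, but 2^m = %d (%s of %d)",
      originals_per_batch, 4L * sum(n_per_class), total, 2L^m,
      if (total < 2L^m) "shortfall" else "excess", abs(total - 2L^m)
    ))
  }
  structure(
    list(
      n_per_class = n_per_class, originals_per_batch = originals_per_batch,
      m = m, pad_last = isTRUE(pad_last)
    ),
    class = "sampler_config"
  )
}

#' Batch composition plan
#'
#' Expands a [sampler_config()] into per-class synthetic counts: a minority
#' class with factor `n` contributes `2 n` WGAN-div, `n` mixup and `n`
#' nonlinear-mixup images. The plan's total equals
#' `originals_per_batch + 4 * sum(n) = 2^m`.
#'
#' @param config A `sampler_config`.
#' @return A tibble with one row per minority class (`class`, `n`, `wgan`,
#'   `mixup`, `nonlinear_mixup`) and attributes `originals` and `total`.
#' @export
batch_plan <- function(config) {
  stopifnot(inherits(config, "sampler_config"))
  plan <- tibble(
    class = names(config$n_per_class) %||% character(0),
    n = unname(config$n_per_class),
    wgan = 2L * unname(config$n_per_class),
    mixup = unname(config$n_per_class),
    nonlinear_mixup = unname(config$n_per_class)
  )
  structure(
    plan,
    originals = config$originals_per_batch,
    total = config$originals_per_batch +
      sum(plan$wgan) + sum(plan$mixup) + sum(plan$nonlinear_mixup),
    class = c("batch_plan", class(plan))
  )
}

#' Total batch size of a plan
#' @param plan A [batch_plan()].
#' @return Integer total (originals + all synthetic images).
#' @export
batch_total <- function(plan) attr(plan, "total")

#' Compose one minority-focussed mini-batch
#'
#' Originals are drawn uniformly from the full dataset (all classes); for each
#' minority class, WGAN-div images are drawn with replacement from its
#' pre-generated pool while mixup and nonlinear-mixup images are generated on
#' the fly from pairs selected over the combined pool (class originals plus
#' WGAN pool), each with a fresh lambda — and a fresh colour-axis rotation for
#' the nonlinear ones. Items are shuffled.
#'
#' @param dataset A `cell_dataset` of original images.
#' @param wgan_pools Named list mapping each minority class with `n > 0` to a
#'   non-empty list of generated images.
#' @param config A [sampler_config()].
#' @param original_ids Optional tibble with columns `class`, `index` choosing
#'   the original images explicitly (used by [epoch_stream()]); by default
#'   they are sampled uniformly.
#' @param lam_low,lam_high Mixup coefficient bounds.
#' @param rotate Apply the colour rotation for nonlinear-mixup items
#'   (default `TRUE`).
#' @return A `mini_batch` tibble with columns `image` (list of arrays),
#'   `class` and `source` (factor: original / wgan / mixup / nonlinear_mixup).
#' @export
compose_batch <- function(dataset, wgan_pools, config, original_ids = NULL,
                          lam_low = 0.15, lam_high = 0.85, rotate = TRUE) {
  stopifnot(inherits(dataset, "cell_dataset"), inherits(config, "sampler_config"))
  counts <- dataset_counts(dataset)
  index <- tibble(
    class = rep(counts$class, counts$count),
    index = unlist(lapply(counts$count, seq_len), use.names = FALSE)
  )
  if (is.null(original_ids)) {
    pick <- sample.int(nrow(index), config$originals_per_batch,
                       replace = nrow(index) < config$originals_per_batch)
    original_ids <- index[pick, ]
  }
  items_img <- vector("list", 0L)
  items_cls <- character(0)
  items_src <- character(0)
  for (i in seq_len(nrow(original_ids))) {
    items_img[[length(items_img) + 1L]] <-
      dataset$images[[original_ids$class[i]]][[original_ids$index[i]]]
  }
  items_cls <- original_ids$class
  items_src <- rep("original", nrow(original_ids))
  active <- names(config$n_per_class)[config$n_per_class > 0L]
  for (cls in active) {
    pool_w <- wgan_pools[[cls]]
    if (is.null(pool_w) || !length(pool_w)) {
      abort(sprintf("minority class '%s' has no WGAN pool", cls))
    }
    combined <- c(dataset$images[[cls]], pool_w)
    if (length(combined) < 2L) {
      abort(sprintf("combined pool of class '%s' has fewer than 2 images", cls))
    }
    n_c <- config$n_per_class[[cls]]
    for (j in seq_len(2L * n_c)) {
      items_img[[length(items_img) + 1L]] <- pool_w[[sample.int(length(pool_w), 1L)]]
      items_cls <- c(items_cls, cls)
      items_src <- c(items_src, "wgan")
    }
    for (j in seq_len(n_c)) {
      pair <- select_pair(combined)
      items_img[[length(items_img) + 1L]] <-
        mixup(pair[[1]], pair[[2]], sample_lambda(1L, lam_low, lam_high))
      items_cls <- c(items_cls, cls)
      items_src <- c(items_src, "mixup")
    }
    for (j in seq_len(n_c)) {
      pair <- select_pair(combined)
      lam <- sample_lambda(1L, lam_low, lam_high)
      spec <- sample_rotation()
      items_img[[length(items_img) + 1L]] <- if (rotate) {
        nonlinear_mixup(pair[[1]], pair[[2]], lam, spec)
      } else {
        mixup(pair[[1]], pair[[2]], lam)
      }
      items_cls <- c(items_cls, cls)
      items_src <- c(items_src, "nonlinear_mixup")
    }
  }
  ord <- sample.int(length(items_img))
  out <- tibble(
    image = items_img[ord],
    class = items_cls[ord],
    source = factor(items_src[ord],
                    levels = c("original", "wgan", "mixup", "nonlinear_mixup"))
  )
  structure(out, class = c("mini_batch", class(out)))
}

#' Stream of minority-focussed batches over one epoch
#'
#' Originals are permuted once and consumed in chunks of
#' `originals_per_batch`, so every original appears at most once per epoch
#' (exactly once when `pad_last = TRUE`, where the final partial chunk is
#' padded with originals resampled with replacement to preserve the `2^m`
#' batch size). Synthetic images are drawn fresh, with replacement, for every
#' batch.
#'
#' @inheritParams compose_batch
#' @return List of `mini_batch` tibbles,
#'   `ceiling(n_originals / originals_per_batch)` of them (or `floor` when
#'   `pad_last = FALSE`).
#' @export
epoch_stream <- function(dataset, wgan_pools, config,
                         lam_low = 0.15, lam_high = 0.85, rotate = TRUE) {
  chunks <- epoch_chunks(dataset, config)
  lapply(chunks, function(ids) {
    compose_batch(dataset, wgan_pools, config, original_ids = ids,
                  lam_low = lam_low, lam_high = lam_high, rotate = rotate)
  })
}

# Permute originals and split them into per-batch id tibbles.
epoch_chunks <- function(dataset, config) {
  counts <- dataset_counts(dataset)
  index <- tibble(
    class = rep(counts$class, counts$count),
    index = unlist(lapply(counts$count, seq_len), use.names = FALSE)
  )
  n <- nrow(index)
  perm <- sample.int(n)
  per <- config$originals_per_batch
  n_full <- n %/% per
  n_batches <- if (config$pad_last && n %% per > 0L) n_full + 1L else n_full
  lapply(seq_len(n_batches), function(b) {
    lo <- (b - 1L) * per + 1L
    hi <- min(b * per, n)
    ids <- perm[lo:hi]
    if (length(ids) < per) {
      ids <- c(ids, sample.int(n, per - length(ids), replace = TRUE))
    }
    index[ids, ]
  })
}

#' Standard-sampling baseline stream
#'
#' The comparison sampler: all synthetic images are merged into the original
#' dataset and batches of `2^m` are drawn uniformly from the merged pool, with
#' no supplementary batch. The expected minority fraction of a batch then
#' equals the merged pool's minority fraction.
#'
#' @param dataset A `cell_dataset`.
#' @param synthetic Named list (class -> list of images) merged into the pool;
#'   may be empty.
#' @param batch_size Images per batch.
#' @param n_batches Number of batches to draw.
#' @return List of `mini_batch` tibbles with sources tagged original/wgan.
#' @export
standard_stream <- function(dataset, synthetic = list(), batch_size, n_batches) {
  stopifnot(inherits(dataset, "cell_dataset"))
  imgs <- list(); cls <- character(0); src <- character(0)
  for (cc in dataset$classes) {
    pool <- dataset$images[[cc]]
    imgs <- c(imgs, pool)
    cls <- c(cls, rep(cc, length(pool)))
    src <- c(src, rep("original", length(pool)))
  }
  for (cc in names(synthetic)) {
    pool <- synthetic[[cc]]
    imgs <- c(imgs, pool)
    cls <- c(cls, rep(cc, length(pool)))
    src <- c(src, rep("wgan", length(pool)))
  }
  lapply(seq_len(n_batches), function(b) {
    pick <- sample.int(length(imgs), batch_size, replace = length(imgs) < batch_size)
    out <- tibble(
      image = imgs[pick],
      class = cls[pick],
      source = factor(src[pick],
                      levels = c("original", "wgan", "mixup", "nonlinear_mixup"))
    )
    structure(out, class = c("mini_batch", class(out)))
  })
}

#' Batch manifest
#'
#' Summarises a mini-batch (or a list of them) as a tidy table of class and
#' source-tag counts, matching the optional CSV manifest logged during
#' training.
#'
#' @param batch A `mini_batch` or list of them.
#' @return A tibble with `batch`, `class`, `source`, `count`.
#' @export
batch_manifest <- function(batch) {
  batches <- if (inherits(batch, "mini_batch")) list(batch) else batch
  bind_rows(imap(batches, function(b, i) {
    out <- count(tibble(class = b$class, source = b$source),
                 .data$class, .data$source, name = "count")
    out$batch <- as.integer(i)
    out[, c("batch", "class", "source", "count")]
  }))
}
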