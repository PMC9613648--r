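#' Train WGAN-div models and generate per-class pools
#'
#' For each minority class of the dataset: enrich the original pool with
#' handcrafted augmentation when it is below `enrich_to`, train a WGAN-div
#' model on the (enriched) pool, and generate `pool_size` synthetic images
#' from the checkpointed generator.
#'
#' @param dataset A `cell_dataset` with minority flags set.
#' @param config A [wgan_div_config()] shared by all classes.
#' @param pool_size Generated images per class.
#' @param enrich_to Pre-GAN enrichment target for small pools (`0` disables).
#' @param image_size Optional `(H, W)`; when given, training and generation
#'   run at this resolution (images resized bilinearly first).
#' @param seed Base seed; each class uses a distinct derived seed.
#' @return Named list: per class, a list with `fit` (the `wgan_div_fit`) and
#'   `pool` (generated images).
#' @export
prepare_wgan_pools <- function(dataset, config = wgan_div_config(),
                               pool_size = 200L, enrich_to = 160L,
                               image_size = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "cell_dataset"))
  out <- list()
  for (i in seq_along(dataset$minority)) {
    cls <- dataset$minority[i]
    pool <- dataset$images[[cls]]
    if (!is.null(image_size)) {
      pool <- lapply(pool, preprocess_for_classifier,
                     target = image_size, method = "resize_bilinear")
    }
    cls_seed <- (seed * 1000L + i) %% .Machine$integer.max
    set.seed(cls_seed)
    if (enrich_to > length(pool)) {
      pool <- enrich_minority_pool(pool, enrich_to)
    }
    cfg <- config
    cfg$seed <- cls_seed
    fit <- train_wgan_div(pool, cfg)
    out[[cls]] <- list(fit = fit, pool = generate_samples(fit, pool_size, seed = cls_seed + 1L))
  }
  out
}

#' End-to-end toy experiment: full method vs no-oversampling baseline
#'
#' Runs the whole pipeline on the synthetic fixture at desk scale: generate an
#' imbalanced training set and a balanced held-out test set; train WGAN-div
#' models for the minority classes and generate pools; train the toy
#' classifier with the minority-focussed sampler (supplementing each batch of
#' originals with 2 WGAN + 1 mixup + 1 nonlinear-mixup images per n-unit per
#' minority class); and train the baseline classifier on plain uniform
#' batches with the same optimisation-step budget. Both arms are evaluated on
#' the same test set.
#'
#' @param seed Integer seed driving every random choice of the run.
#' @param fixture A [fixture_config()] for the training set.
#' @param test_per_class Held-out images per class.
#' @param n_per_class Oversampling factors; default `n = 1` for every
#'   minority class of the fixture.
#' @param originals_per_batch,m Sampler arithmetic (must satisfy
#'   `originals + 4 sum(n) = 2^m`); defaults derive `originals_per_batch`
#'   from `m = 5` and the chosen `n`.
#' @param image_size Working resolution for GAN and classifier.
#' @param epochs Classifier epochs.
#' @param wgan_config A [wgan_div_config()].
#' @param pool_size,enrich_to WGAN pool sizes (see [prepare_wgan_pools()]).
#' @param baseline_only,augmented_only Skip one arm if wanted.
#' @param ... Passed on to [train_toy_classifier()].
#' @return A `toy_experiment` list: `augmented` and `baseline` (each with
#'   `fit` and `report`), `wgan`, `comparison` tibble, and the configs used.
#' @export
run_toy_experiment <- function(seed = 1L, fixture = fixture_config(),
                               test_per_class = 60L, n_per_class = NULL,
                               originals_per_batch = NULL, m = 5L,
                               image_size = c(24L, 24L), epochs = 6L,
                               wgan_config = wgan_div_config(),
                               pool_size = 200L, enrich_to = 160L,
                               baseline_only = FALSE, augmented_only = FALSE,
                               ...) {
  seed <- as.integer(seed)
  train <- make_toy_dataset(fixture, seed = seed)
  test_tab <- fixture$classes
  test_tab$count <- as.integer(test_per_class)
  test <- make_toy_dataset(fixture_config(test_tab, fixture$image_size),
                           seed = seed + 7919L)
  minority <- train$minority
  if (is.null(n_per_class)) {
    n_per_class <- stats::setNames(rep(1L, length(minority)), minority)
  }
  if (is.null(originals_per_batch)) {
    originals_per_batch <- 2L^m - 4L * sum(n_per_class)
  }
  sampler <- sampler_config(n_per_class, originals_per_batch, m)
  n_orig <- sum(dataset_counts(train)$count)
  budget <- ceiling(n_orig / originals_per_batch)

  wgan <- NULL; aug <- NULL; base <- NULL
  if (!baseline_only) {
    wgan <- prepare_wgan_pools(train, wgan_config, pool_size = pool_size,
                               enrich_to = enrich_to, image_size = image_size,
                               seed = seed)
    pools <- lapply(wgan, `[[`, "pool")
    fit_a <- train_toy_classifier(train, wgan_pools = pools, sampler = sampler,
                                  epochs = epochs, image_size = image_size,
                                  seed = seed, ...)
    aug <- list(fit = fit_a, report = evaluate_classifier(fit_a, test))
  }
  if (!augmented_only) {
    fit_b <- train_toy_classifier(train, sampler = NULL, epochs = epochs,
                                  image_size = image_size,
                                  steps_per_epoch = budget, seed = seed, ...)
    base <- list(fit = fit_b, report = evaluate_classifier(fit_b, test))
  }
  comparison <- bind_rows(
    if (!is.null(aug)) mutate(tidy(aug$report), arm = "augmented"),
    if (!is.null(base)) mutate(tidy(base$report), arm = "baseline")
  )
  structure(
    list(
      augmented = aug, baseline = base, wgan = wgan,
      comparison = comparison, sampler = sampler, seed = seed,
      minority = minority
    ),
    class = "toy_experiment"
  )
}

#' Mean minority-class F1 of an experiment arm
#'
#' @param experiment A `toy_experiment`.
#' @param arm `"augmented"` or `"baseline"`.
#' @return Mean F1 over the minority classes of that arm's report.
#' @export
minority_f1 <- function(experiment, arm = c("augmented", "baseline")) {
  arm <- match.arg(arm)
  rep <- experiment[[arm]]
  if (is.null(rep)) abort(sprintf("experiment has no '%s' arm", arm))
  pc <- rep$report$per_class
  mean(pc$f1[pc$class %in% experiment$minority])
}

#' @export
print.toy_experiment <- function(x, ...) {
  cat("<toy_experiment>\n")
  if (!is.null(x$augmented)) {
    cat(sprintf("  augmented: macro F1 %.3f | minority F1 %.3f\n",
                x$augmented$report$macro_f1, minority_f1(x, "augmented")))
  }
  if (!is.null(x$baseline)) {
    cat(sprintf("  baseline : macro F1 %.3f | minority F1 %.3f\n",
                x$baseline$report$macro_f1, minority_f1(x, "baseline")))
  }
  invisible(x)
}

#' @export
autoplot.toy_experiment <- function(object, ...) {
  ggplot(object$comparison,
         aes(x = .data$class, y = .data$f1, fill = .data$arm)) +
    geom_col(position = "dodge") +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = NULL, y = "F1 score", fill = NULL) +
    theme_minimal()
}
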