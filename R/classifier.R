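# Small convolutional classifier used by the end-to-end toy experiment:
# conv(3x3, 8, stride 2) -> ReLU -> conv(3x3, 16, stride 2) -> ReLU -> dense.
# Inputs are preprocessed images scaled to [0, 1] and flattened (H, W, C).

build_toy_classifier <- function(h, w, n_classes) {
  c1 <- nn_conv(h, w, 3L, filters = 8L, k = 3L, stride = 2L)
  c2 <- nn_conv(c1$oh, c1$ow, 8L, filters = 16L, k = 3L, stride = 2L)
  nn_net(list(c1, nn_act("relu"), c2, nn_act("relu"),
              nn_dense(c2$d_out, n_classes, init_scale = sqrt(1 / c2$d_out))))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

batch_to_matrix <- function(images, target, method) {
  x <- matrix(0, length(images), target[1] * target[2] * 3L)
  for (i in seq_along(images)) {
    x[i, ] <- as.numeric(preprocess_for_classifier(images[[i]], target, method)) / 255
  }
  x
}

#' Train the toy convolutional classifier
#'
#' Trains a small convolutional network (2 conv layers + dense softmax) with
#' cross-entropy loss and momentum SGD (momentum 0.9, weight decay 1e-4 by
#' default) under a step-decay learning-rate schedule. With a
#' [sampler_config()] the minority-focussed sampler composes every batch
#' (originals supplemented by 2 WGAN + 1 mixup + 1 nonlinear-mixup images per
#' n-unit per minority class); without one, plain uniform batches of `2^m`
#' originals are used — the no-oversampling baseline — over the same number
#' of optimisation steps so both arms get an identical budget. The sampler
#' and augmentations are classifier-agnostic; this network is simply small
#' enough that the full pipeline runs in minutes on one CPU.
#'
#' @param dataset Training `cell_dataset`.
#' @param wgan_pools Named list of per-minority-class generated image lists
#'   (required when `sampler` is given with any `n > 0`).
#' @param sampler A [sampler_config()], or `NULL` for the baseline.
#' @param epochs Passes over the originals.
#' @param image_size Classifier input size `(H, W)`.
#' @param preprocess `"resize_bilinear"` or `"center_crop"`.
#' @param lr Initial learning rate.
#' @param momentum,weight_decay Momentum-SGD parameters.
#' @param gamma,step_size Step-decay schedule: the learning rate is multiplied
#'   by `gamma` every `step_size` epochs.
#' @param lam_low,lam_high Mixup coefficient bounds used by the sampler.
#' @param rotate Use the colour rotation for nonlinear-mixup items.
#' @param steps_per_epoch Optional override of the optimisation steps per
#'   epoch (used to give the baseline the same step budget as an augmented
#'   run).
#' @param seed Integer seed fixing initialisation and batch composition.
#' @return A `toy_classifier_fit` (with `tidy()`, `glance()`, `autoplot()`
#'   methods and a training trace).
#' @export
train_toy_classifier <- function(dataset, wgan_pools = NULL, sampler = NULL,
                                 epochs = 6L, image_size = c(24L, 24L),
                                 preprocess = "resize_bilinear",
                                 lr = 0.02, momentum = 0.9, weight_decay = 1e-4,
                                 gamma = 0.1, step_size = 4L,
                                 lam_low = 0.15, lam_high = 0.85, rotate = TRUE,
                                 steps_per_epoch = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "cell_dataset"))
  set.seed(seed)
  classes <- dataset$classes
  n_classes <- length(classes)
  target <- as.integer(image_size)
  net <- build_toy_classifier(target[1], target[2], n_classes)
  opt <- opt_new(net, "sgdm", lr = lr, momentum = momentum,
                 weight_decay = weight_decay)

  # cache preprocessed originals (and pools) once
  cached <- lapply(dataset$images, function(pool) {
    lapply(pool, preprocess_for_classifier, target = target, method = preprocess)
  })
  cached_ds <- cell_dataset(cached, minority = dataset$minority)
  pools_pp <- if (!is.null(wgan_pools)) {
    lapply(wgan_pools, function(pool) {
      lapply(pool, preprocess_for_classifier, target = target, method = preprocess)
    })
  } else list()

  n_orig <- sum(dataset_counts(dataset)$count)
  if (is.null(steps_per_epoch)) {
    steps_per_epoch <- if (is.null(sampler)) {
      ceiling(n_orig / 32L)
    } else {
      ceiling(n_orig / sampler$originals_per_batch)
    }
  }
  batch_size <- if (is.null(sampler)) 32L else batch_total(batch_plan(sampler))

  # flat index of originals for the baseline arm
  counts <- dataset_counts(cached_ds)
  flat_cls <- rep(counts$class, counts$count)
  flat_idx <- unlist(lapply(counts$count, seq_len), use.names = FALSE)

  trace <- list()
  step_id <- 0L
  for (epoch in seq_len(epochs)) {
    lr_now <- lr * gamma^((epoch - 1L) %/% step_size)
    chunks <- if (!is.null(sampler)) epoch_chunks(cached_ds, sampler) else NULL
    for (s in seq_len(steps_per_epoch)) {
      if (!is.null(sampler)) {
        if (s > length(chunks)) break
        mb <- compose_batch(cached_ds, pools_pp, sampler,
                            original_ids = chunks[[s]],
                            lam_low = lam_low, lam_high = lam_high,
                            rotate = rotate)
        imgs <- mb$image
        labels <- mb$class
      } else {
        pick <- sample.int(length(flat_cls), batch_size,
                           replace = length(flat_cls) < batch_size)
        imgs <- lapply(pick, function(ii) cached_ds$images[[flat_cls[ii]]][[flat_idx[ii]]])
        labels <- flat_cls[pick]
      }
      x <- matrix(0, length(imgs), target[1] * target[2] * 3L)
      for (i in seq_along(imgs)) x[i, ] <- as.numeric(imgs[[i]]) / 255
      y <- match(labels, classes)
      fw <- nn_forward(net, x, keep_cache = TRUE)
      probs <- softmax_rows(fw$out)
      nb <- nrow(x)
      loss <- -mean(log(pmax(probs[cbind(seq_len(nb), y)], 1e-12)))
      dlogits <- probs
      dlogits[cbind(seq_len(nb), y)] <- dlogits[cbind(seq_len(nb), y)] - 1
      dlogits <- dlogits / nb
      grads <- nn_backward(net, x, fw$caches, dlogits)$grads
      st <- opt_step(net, opt, grads, lr = lr_now)
      net <- st$net; opt <- st$opt
      step_id <- step_id + 1L
      trace[[step_id]] <- c(epoch = epoch, step = step_id, loss = loss, lr = lr_now)
    }
  }
  trace <- as_tibble(do.call(rbind, trace))
  structure(
    list(
      net = net, classes = classes, image_size = target,
      preprocess = preprocess, trace = trace,
      sampler = sampler, seed = seed
    ),
    class = "toy_classifier_fit"
  )
}

#' @export
print.toy_classifier_fit <- function(x, ...) {
  cat(sprintf(
    "<toy_classifier_fit> %d classes, %d training steps, final loss %.4f (%s sampling)\n",
    length(x$classes), nrow(x$trace), x$trace$loss[nrow(x$trace)],
    if (is.null(x$sampler)) "standard" else "minority-focussed"
  ))
  invisible(x)
}

#' Predict classes for a dataset or image list
#'
#' @param object A `toy_classifier_fit`.
#' @param newdata A `cell_dataset` or list of `H x W x 3` arrays.
#' @param ... Unused.
#' @return For a dataset, a tibble with `truth` and `pred`; for an image
#'   list, a character vector of predicted classes.
#' @export
predict.toy_classifier_fit <- function(object, newdata, ...) {
  predict_images <- function(images) {
    x <- batch_to_matrix(images, object$image_size, object$preprocess)
    probs <- softmax_rows(nn_forward(object$net, x)$out)
    object$classes[max.col(probs, ties.method = "first")]
  }
  if (inherits(newdata, "cell_dataset")) {
    counts <- dataset_counts(newdata)
    truth <- rep(counts$class, counts$count)
    images <- unlist(newdata$images[counts$class], recursive = FALSE)
    tibble(truth = truth, pred = predict_images(images))
  } else {
    predict_images(newdata)
  }
}

#' Evaluate a fitted toy classifier on a dataset
#'
#' @param fit A `toy_classifier_fit`.
#' @param dataset A `cell_dataset` with true labels.
#' @return An [evaluation_report()].
#' @export
evaluate_classifier <- function(fit, dataset) {
  preds <- predict(fit, dataset)
  evaluation_report(preds$truth, preds$pred, classes = fit$classes)
}

#' @export
tidy.toy_classifier_fit <- function(x, ...) x$trace

#' @export
glance.toy_classifier_fit <- function(x, ...) {
  tibble(
    steps = nrow(x$trace),
    final_loss = x$trace$loss[nrow(x$trace)],
    classes = length(x$classes),
    sampling = if (is.null(x$sampler)) "standard" else "minority_focussed"
  )
}

#' @export
autoplot.toy_classifier_fit <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$step, y = .data$loss)) +
    geom_line(colour = "steelblue") +
    labs(x = "training step", y = "cross-entropy loss") +
    theme_minimal()
}

#' @export
tidy.wgan_div_fit <- function(x, ...) x$trace

#' @export
glance.wgan_div_fit <- function(x, ...) {
  tibble(
    objective = x$config$objective,
    checkpoint_step = x$step,
    critic_loss_abs = x$critic_loss_abs,
    generator_steps = x$generator_steps,
    critic_steps = x$critic_steps,
    stopped = x$stopped
  )
}

#' @export
autoplot.wgan_div_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, -"step",
                              names_to = "series", values_to = "value")
  ggplot(long, aes(x = .data$step, y = .data$value, colour = .data$series)) +
    geom_line() +
    labs(x = "generator step", y = "objective value", colour = NULL) +
    theme_minimal()
}
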