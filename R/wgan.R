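# Image batches move through the GAN code as n x D matrices (images flattened
# column-major in (H, W, C) order). Helpers convert between lists of
# H x W x 3 arrays and batch matrices.

images_to_matrix <- function(images) {
  if (is.matrix(images)) return(images)
  if (!is.list(images) || !length(images)) abort("need a non-empty list of images")
  d <- dim(images[[1]])
  x <- matrix(0, length(images), prod(d))
  for (i in seq_along(images)) {
    assert_rgb_image(images[[i]])
    if (!all(dim(images[[i]]) == d)) abort("all images must share dimensions")
    x[i, ] <- as.numeric(images[[i]])
  }
  attr(x, "image_dim") <- d
  x
}

matrix_to_images <- function(x, image_dim) {
  lapply(seq_len(nrow(x)), function(i) array(x[i, ], dim = image_dim))
}

#' WGAN-div training configuration
#'
#' Hyperparameters of the Wasserstein-divergence GAN used to oversample a
#' minority class. Defaults follow common practice for this model family:
#' penalty exponent `p = 6` and weight `k = 2`, `n_critic = 4` critic updates
#' per generator update, learning rate `2e-4` with the adaptive-moment
#' optimiser, batch size 16. Classes with high intra-class variance (such as a
#' prophase-like pool containing a transitional sub-phase) are the documented
#' exception pattern: a lower learning rate (`2e-5`) and a higher `n_critic`
#' (10) help convergence there.
#'
#' @param p Penalty exponent (> 0).
#' @param k Penalty weight (>= 0).
#' @param n_critic Critic updates per generator update (>= 1).
#' @param learning_rate Step size for both networks.
#' @param batch_size Images per update (>= 2).
#' @param noise_dim Length of the generator input noise vector z.
#' @param max_steps Generator-step training budget.
#' @param objective `"wgan-div"` (divergence penalty, Adam) or `"wgan"`
#'   (weight clipping, RMSprop).
#' @param clip_threshold Weight-clipping bound for the `"wgan"` objective.
#' @param hidden_critic,hidden_generator Hidden-layer widths of the two
#'   fully-connected networks.
#' @param plateau_window Generator steps per smoothing window of the
#'   absolute critic objective.
#' @param plateau_patience Windows without improvement before stopping.
#' @param plateau_min_delta Minimum decrease of the smoothed absolute critic
#'   objective that counts as improvement.
#' @param seed Optional integer seed fixing the whole run.
#' @return A `wgan_div_config` list.
#' @export
wgan_div_config <- function(p = 6, k = 2, n_critic = 4L, learning_rate = 2e-4,
                            batch_size = 16L, noise_dim = 64L, max_steps = 200L,
                            objective = c("wgan-div", "wgan"),
                            clip_threshold = 0.01,
                            hidden_critic = c(128L, 128L),
                            hidden_generator = c(128L, 128L),
                            plateau_window = 20L, plateau_patience = 5L,
                            plateau_min_delta = 1e-3, seed = NULL) {
  objective <- match.arg(objective)
  if (p <= 0) abort("p must be > 0")
  if (k < 0) abort("k must be >= 0")
  if (n_critic < 1L) abort("n_critic must be >= 1")
  if (batch_size < 2L) abort("batch_size must be >= 2")
  structure(
    list(
      p = p, k = k, n_critic = as.integer(n_critic),
      learning_rate = learning_rate, batch_size = as.integer(batch_size),
      noise_dim = as.integer(noise_dim), max_steps = as.integer(max_steps),
      objective = objective, clip_threshold = clip_threshold,
      hidden_critic = as.integer(hidden_critic),
      hidden_generator = as.integer(hidden_generator),
      plateau_window = as.integer(plateau_window),
      plateau_patience = as.integer(plateau_patience),
      plateau_min_delta = plateau_min_delta, seed = seed
    ),
    class = "wgan_div_config"
  )
}

#' Construct critic and generator networks
#'
#' The critic is a fully-connected leaky-ReLU network ending in a single
#' unbounded linear score; the generator maps a noise vector through
#' fully-connected ReLU layers to a tanh image output in `[-1, 1]`.
#' `linear_critic()` builds a degenerate one-layer critic `D(x) = w . x + b`,
#' useful because its input gradient is `w` everywhere, which gives a closed
#' form for the divergence penalty.
#'
#' @param d_in Flattened image length seen by the critic.
#' @param hidden Integer vector of hidden-layer widths.
#' @param alpha Leaky-ReLU slope for the critic.
#' @return An `nn_net` network object.
#' @export
wgan_critic <- function(d_in, hidden = c(128L, 128L), alpha = 0.2) {
  layers <- list()
  prev <- d_in
  for (h in hidden) {
    layers <- c(layers, list(nn_dense(prev, h), nn_act("lrelu", alpha)))
    prev <- h
  }
  layers <- c(layers, list(nn_dense(prev, 1L)))
  structure(nn_net(layers), class = c("wgan_critic", "nn_net"))
}

#' @rdname wgan_critic
#' @param w Weight vector of a linear critic.
#' @param b Scalar bias.
#' @export
linear_critic <- function(w, b = 0) {
  net <- nn_net(list(nn_dense(length(w), 1L)))
  net$layers[[1]]$W <- matrix(w, ncol = 1L)
  net$layers[[1]]$b <- b
  structure(net, class = c("wgan_critic", "nn_net"))
}

wgan_generator <- function(noise_dim, d_out, hidden = c(128L, 128L)) {
  layers <- list()
  prev <- noise_dim
  for (h in hidden) {
    layers <- c(layers, list(nn_dense(prev, h), nn_act("relu")))
    prev <- h
  }
  layers <- c(layers, list(nn_dense(prev, d_out), nn_act("tanh")))
  nn_net(layers)
}

#' Critic scores and input gradients
#'
#' `critic_score()` evaluates the critic on a batch; `critic_input_gradient()`
#' returns the gradient of each sample's score with respect to the sample
#' itself, the quantity penalised by the divergence objective.
#'
#' @param critic An `nn_net` critic.
#' @param x A batch: `n x D` matrix or list of `H x W x 3` arrays.
#' @return `critic_score()`: numeric vector of n scores;
#'   `critic_input_gradient()`: an `n x D` matrix of per-sample gradients.
#' @export
critic_score <- function(critic, x) {
  x <- images_to_matrix(x)
  drop(nn_forward(critic, x)$out)
}

#' @rdname critic_score
#' @export
critic_input_gradient <- function(critic, x) {
  x <- images_to_matrix(x)
  fw <- nn_forward(critic, x, keep_cache = TRUE)
  nn_backward(critic, x, fw$caches, matrix(1, nrow(x), 1L), input_grad = TRUE)$dx
}

#' Sample interpolates between real and fake batches
#'
#' Each interpolate is a per-sample linear combination
#' `x_hat = u * x + (1 - u) * x_tilde` with `u` drawn independently and
#' uniformly on `[0, 1]`, the operational form of sampling between the real
#' and generated distributions for the divergence penalty.
#'
#' @param real,fake Batches of equal size and dimension (`n x D` matrices or
#'   lists of images).
#' @param u Optional fixed coefficient(s), recycled over samples; by default
#'   drawn uniformly per sample.
#' @return A batch in the same form as `real`.
#' @export
sample_interpolates <- function(real, fake, u = NULL) {
  as_images <- is.list(real)
  xr <- images_to_matrix(real)
  xf <- images_to_matrix(fake)
  if (!all(dim(xr) == dim(xf))) abort("real and fake batches must match in size and dimension")
  u <- if (is.null(u)) runif(nrow(xr)) else rep_len(u, nrow(xr))
  out <- xr * u + xf * (1 - u)
  if (as_images) matrix_to_images(out, dim(real[[1]])) else out
}

#' Wasserstein-divergence gradient penalty
#'
#' Computes `k * mean(||grad_xhat D(xhat)||^p)` over a batch of interpolates,
#' the penalty term of the divergence objective. For a linear critic
#' `D(x) = w . x` the gradient is `w` everywhere, so the penalty equals
#' `k * ||w||^p` exactly for any interpolates — the closed form used to
#' validate the implementation.
#'
#' @param critic An `nn_net` critic.
#' @param interpolates Batch of interpolates (`n x D` matrix or image list).
#' @param p Penalty exponent (default 6).
#' @param k Penalty weight (default 2).
#' @return A single penalty value.
#' @export
wdiv_penalty <- function(critic, interpolates, p = 6, k = 2) {
  g <- critic_input_gradient(critic, interpolates)
  if (!all(is.finite(g))) abort("non-finite critic gradient at interpolates")
  k * mean(rowSums(g^2)^(p / 2))
}

# Parameter gradients of the divergence penalty for a dense/leaky-ReLU critic
# (double backprop; second derivative of leaky-ReLU is zero a.e., so the
# activation masks are treated as constants, matching standard autograd).
wdiv_penalty_grads <- function(critic, x, p, k) {
  ly <- critic$layers
  ok <- length(ly) == 5L && ly[[1]]$type == "dense" && ly[[2]]$type == "lrelu" &&
    ly[[3]]$type == "dense" && ly[[4]]$type == "lrelu" && ly[[5]]$type == "dense"
  if (!ok) abort("penalty gradients require a dense/lrelu/dense/lrelu/dense critic")
  W1 <- ly[[1]]$W; W2 <- ly[[3]]$W; w3 <- drop(ly[[5]]$W)
  a <- ly[[2]]$alpha
  n <- nrow(x)
  z1 <- sweep(x %*% W1, 2, ly[[1]]$b, "+")
  d1 <- ifelse(z1 > 0, 1, a)
  a1 <- z1 * d1
  z2 <- sweep(a1 %*% W2, 2, ly[[3]]$b, "+")
  d2 <- ifelse(z2 > 0, 1, a)
  v2 <- sweep(d2, 2, w3, "*")
  u <- v2 %*% t(W2)
  v1 <- d1 * u
  g <- v1 %*% t(W1)                      # per-sample input gradients
  s2 <- rowSums(g^2)
  penalty <- k * mean(s2^(p / 2))
  r <- (k * p / n) * s2^(p / 2 - 1)
  cmat <- g * r
  dW1 <- crossprod(cmat, v1)
  dv1 <- cmat %*% W1
  du <- d1 * dv1
  dv2 <- du %*% W2
  dW2 <- crossprod(du, v2)
  dw3 <- colSums(dv2 * d2)
  list(penalty = penalty, dW1 = dW1, dW2 = dW2, dw3 = matrix(dw3, ncol = 1L))
}

#' Critic objectives, exactly as printed
#'
#' Two objective values the critic ascends during adversarial training.
#' The two published formulas use opposite sign conventions and both are kept
#' literally: the plain Wasserstein objective is
#' `mean(real_scores) - mean(fake_scores)` (Lipschitz enforced by weight
#' clipping), while the Wasserstein-divergence objective is
#' `mean(fake_scores) - mean(real_scores) - penalty`. Each defines an
#' internally consistent min–max game; the generator direction flips
#' accordingly (it descends the mean fake score under the divergence
#' objective and ascends it under the plain one).
#'
#' @param real_scores,fake_scores Critic scores of real and generated batches.
#' @param penalty Gradient penalty term (see [wdiv_penalty()]).
#' @return The scalar objective value.
#' @export
critic_objective_wgan_div <- function(real_scores, fake_scores, penalty) {
  if (!length(real_scores) || !length(fake_scores)) abort("empty score batch")
  if (!all(is.finite(c(real_scores, fake_scores, penalty)))) abort("non-finite scores")
  mean(fake_scores) - mean(real_scores) - penalty
}

#' @rdname critic_objective_wgan_div
#' @export
critic_objective_wgan <- function(real_scores, fake_scores) {
  if (!length(real_scores) || !length(fake_scores)) abort("empty score batch")
  if (!all(is.finite(c(real_scores, fake_scores)))) abort("non-finite scores")
  mean(real_scores) - mean(fake_scores)
}

#' Handcrafted enrichment of a small minority pool
#'
#' Before GAN training, very small pools (a few tens of images) are enlarged
#' to a few hundreds with classic handcrafted augmentation: random affine
#' transformations (rotation, scale, shear, translation), mild perspective
#' transformations, contrast changes and additive Gaussian noise, with
#' parameters redrawn per copy and results clipped to `[0, 255]`. The
#' originals are kept verbatim at the head of the returned pool.
#'
#' @param images Non-empty list of `H x W x 3` arrays.
#' @param target_count Desired pool size (>= number of inputs).
#' @return List of `target_count` images; the first `length(images)` entries
#'   are the untouched originals.
#' @export
enrich_minority_pool <- function(images, target_count) {
  if (!is.list(images) || !length(images)) abort("images must be a non-empty list")
  target_count <- as.integer(target_count)
  if (target_count < length(images)) abort("target_count must be >= number of input images")
  out <- images
  d <- dim(images[[1]])
  ctr <- (d[1:2] + 1) / 2
  i <- 0L
  while (length(out) < target_count) {
    src <- images[[(i %% length(images)) + 1L]]
    i <- i + 1L
    ang <- runif(1, -25, 25) * pi / 180
    sc <- runif(1, 0.9, 1.1)
    sh <- runif(1, -0.1, 0.1)
    tr <- runif(2, -2, 2)
    persp <- runif(2, -0.0015, 0.0015)
    rot <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    shear <- matrix(c(1, sh, 0, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    m <- diag(3)
    m[1:2, 3] <- ctr
    m <- m %*% (rot / sc) %*% shear
    m[3, 1:2] <- persp
    shift <- diag(3); shift[1:2, 3] <- -ctr + tr
    m <- m %*% shift
    img <- warp_image(src, m)
    cf <- runif(1, 0.8, 1.2)
    img <- (img - mean(img)) * cf + mean(img)
    img <- img + array(rnorm(prod(d), sd = runif(1, 1, 8)), dim = d)
    out[[length(out) + 1L]] <- clip_intensities(img)
  }
  out
}

#' Train a WGAN-div (or WGAN) model on one minority-class pool
#'
#' Alternating adversarial optimisation: exactly `n_critic` critic updates per
#' generator update. Under the divergence objective the critic ascends
#' `mean(fake) - mean(real) - k * E[||grad D(x_hat)||^p]` (Adam) and the
#' generator descends `mean(D(G(z)))`; under the plain Wasserstein objective
#' the critic ascends `mean(real) - mean(fake)` with weight clipping (RMSprop)
#' and the generator ascends `mean(D(G(z)))`. Training images are mapped to
#' `[-1, 1]` to match the generator's tanh output.
#'
#' Convergence is judged on the absolute critic objective: a moving average
#' over `plateau_window` generator steps is tracked, and when it stops
#' decreasing (no improvement beyond `plateau_min_delta` for
#' `plateau_patience` consecutive windows) training stops and the generator
#' snapshot at the best window is kept as the checkpoint; otherwise the run
#' ends at `max_steps`.
#'
#' @param pool Non-empty list of `H x W x 3` arrays (one class).
#' @param config A [wgan_div_config()].
#' @return A `wgan_div_fit` with the checkpointed generator, final critic,
#'   step counts and a per-step loss trace (`tidy()` returns the trace,
#'   `glance()` the summary, `autoplot()` plots it).
#' @export
train_wgan_div <- function(pool, config = wgan_div_config()) {
  stopifnot(inherits(config, "wgan_div_config"))
  if (!is.list(pool) || !length(pool)) abort("pool must be a non-empty list of images")
  if (!is.null(config$seed)) set.seed(config$seed)
  xall <- images_to_matrix(pool)
  image_dim <- attr(xall, "image_dim")
  xall <- xall / 127.5 - 1
  n <- nrow(xall); d <- ncol(xall)
  critic <- wgan_critic(d, config$hidden_critic)
  gen <- wgan_generator(config$noise_dim, d, config$hidden_generator)
  method <- if (config$objective == "wgan-div") "adam" else "rmsprop"
  opt_c <- opt_new(critic, method, lr = config$learning_rate)
  opt_g <- opt_new(gen, method, lr = config$learning_rate)
  bs <- config$batch_size
  trace_step <- integer(0); trace_cobj <- numeric(0); trace_gobj <- numeric(0)
  best <- Inf; best_gen <- gen; best_step <- 0L; bad_windows <- 0L
  critic_steps <- 0L; stopped <- "max_steps"

  draw_noise <- function() matrix(rnorm(bs * config$noise_dim), bs)
  for (step in seq_len(config$max_steps)) {
    cobj <- NA_real_
    for (j in seq_len(config$n_critic)) {
      real <- xall[sample.int(n, bs, replace = n < bs), , drop = FALSE]
      fake <- nn_forward(gen, draw_noise())$out
      fw_r <- nn_forward(critic, real, keep_cache = TRUE)
      fw_f <- nn_forward(critic, fake, keep_cache = TRUE)
      rs <- drop(fw_r$out); fs <- drop(fw_f$out)
      if (config$objective == "wgan-div") {
        xhat <- sample_interpolates(real, fake)
        pen <- wdiv_penalty_grads(critic, xhat, config$p, config$k)
        cobj <- critic_objective_wgan_div(rs, fs, pen$penalty)
        # descend -(objective): d/dscore real = +1/bs, fake = -1/bs, + penalty grads
        g_r <- nn_backward(critic, real, fw_r$caches, matrix(1 / bs, bs, 1L))$grads
        g_f <- nn_backward(critic, fake, fw_f$caches, matrix(-1 / bs, bs, 1L))$grads
        grads <- g_r
        for (li in seq_along(grads)) {
          if (!is.null(grads[[li]]$dW)) {
            grads[[li]]$dW <- grads[[li]]$dW + g_f[[li]]$dW
            grads[[li]]$db <- grads[[li]]$db + g_f[[li]]$db
          }
        }
        grads[[1]]$dW <- grads[[1]]$dW + pen$dW1
        grads[[3]]$dW <- grads[[3]]$dW + pen$dW2
        grads[[5]]$dW <- grads[[5]]$dW + pen$dw3
      } else {
        cobj <- critic_objective_wgan(rs, fs)
        g_r <- nn_backward(critic, real, fw_r$caches, matrix(-1 / bs, bs, 1L))$grads
        g_f <- nn_backward(critic, fake, fw_f$caches, matrix(1 / bs, bs, 1L))$grads
        grads <- g_r
        for (li in seq_along(grads)) {
          if (!is.null(grads[[li]]$dW)) {
            grads[[li]]$dW <- grads[[li]]$dW + g_f[[li]]$dW
            grads[[li]]$db <- grads[[li]]$db + g_f[[li]]$db
          }
        }
      }
      if (!is.finite(cobj)) {
        abort(sprintf("non-finite critic objective at generator step %d", step))
      }
      st <- opt_step(critic, opt_c, grads)
      critic <- st$net; opt_c <- st$opt
      if (config$objective == "wgan") {
        for (li in seq_along(critic$layers)) {
          if (!is.null(critic$layers[[li]]$W)) {
            critic$layers[[li]]$W <- clip_intensities(
              critic$layers[[li]]$W, -config$clip_threshold, config$clip_threshold
            )
            critic$layers[[li]]$b <- clip_intensities(
              critic$layers[[li]]$b, -config$clip_threshold, config$clip_threshold
            )
          }
        }
      }
      critic_steps <- critic_steps + 1L
    }
    # generator update
    z <- draw_noise()
    fw_g <- nn_forward(gen, z, keep_cache = TRUE)
    fake <- fw_g$out
    gsign <- if (config$objective == "wgan-div") 1 else -1
    gobj <- gsign * mean(drop(nn_forward(critic, fake)$out))
    if (!is.finite(gobj)) abort(sprintf("non-finite generator objective at step %d", step))
    dfake <- gsign * critic_input_gradient(critic, fake) / bs
    g_g <- nn_backward(gen, z, fw_g$caches, dfake)$grads
    st <- opt_step(gen, opt_g, g_g)
    gen <- st$net; opt_g <- st$opt
    trace_step <- c(trace_step, step)
    trace_cobj <- c(trace_cobj, cobj)
    trace_gobj <- c(trace_gobj, gobj)
    if (step %% config$plateau_window == 0L) {
      win <- mean(abs(utils::tail(trace_cobj, config$plateau_window)))
      if (win < best - config$plateau_min_delta) {
        best <- win; best_gen <- gen; best_step <- step; bad_windows <- 0L
      } else {
        bad_windows <- bad_windows + 1L
        if (bad_windows >= config$plateau_patience) {
          stopped <- "plateau"
          break
        }
      }
    }
  }
  if (best_step == 0L) { # budget shorter than one window
    best_gen <- gen; best_step <- length(trace_step); best <- mean(abs(trace_cobj))
  }
  structure(
    list(
      generator = best_gen, critic = critic, config = config,
      image_dim = image_dim, step = best_step, critic_loss_abs = best,
      generator_steps = length(trace_step), critic_steps = critic_steps,
      stopped = stopped,
      trace = tibble(
        step = trace_step,
        critic_objective = trace_cobj,
        generator_objective = trace_gobj
      )
    ),
    class = "wgan_div_fit"
  )
}

#' @export
print.wgan_div_fit <- function(x, ...) {
  cat(sprintf(
    "<wgan_div_fit> %s | %d generator steps (%d critic steps) | checkpoint at step %d (|critic loss| %.4f, %s)\n",
    x$config$objective, x$generator_steps, x$critic_steps, x$step,
    x$critic_loss_abs, x$stopped
  ))
  invisible(x)
}

#' Generate synthetic images from a trained generator checkpoint
#'
#' Draws noise vectors, runs the checkpointed generator and rescales its tanh
#' output affinely from `[-1, 1]` to the canonical `[0, 255]` scale (then
#' clips).
#'
#' @param fit A `wgan_div_fit`.
#' @param count Number of images (> 0).
#' @param seed Optional seed for the noise draws.
#' @return List of `count` `H x W x 3` arrays with the training dimensions.
#' @export
generate_samples <- function(fit, count, seed = NULL) {
  stopifnot(inherits(fit, "wgan_div_fit"))
  count <- as.integer(count)
  if (is.na(count) || count <= 0L) abort("count must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(rnorm(count * fit$config$noise_dim), count)
  x <- nn_forward(fit$generator, z)$out
  x <- clip_intensities((x + 1) * 127.5)
  matrix_to_images(x, fit$image_dim)
}
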