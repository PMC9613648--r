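test_that("interpolates are per-sample convex combinations of real and fake", {
  real <- matrix(2, 4, 3); fake <- matrix(6, 4, 3)
  expect_equal(sample_interpolates(real, fake, u = 1), real)
  expect_equal(sample_interpolates(real, fake, u = 0), fake)
  # u = 0.25 puts weight 0.25 on the real batch: 0.25*2 + 0.75*6 = 5
  expect_equal(sample_interpolates(real, fake, u = 0.25), matrix(5, 4, 3))
  set.seed(31)
  x <- sample_interpolates(real, fake)
  expect_true(all(x >= 2 & x <= 6))
  expect_error(sample_interpolates(real, matrix(6, 3, 3)), "match")
  # image-list form round-trips
  r_img <- list(const_image(10)); f_img <- list(const_image(20))
  out <- sample_interpolates(r_img, f_img, u = 0.5)
  expect_equal(out[[1]], const_image(15))
})

test_that("divergence penalty matches the analytic closed form for linear critics", {
  set.seed(32)
  # default p = 6, k = 2: k * ||w||^p, any interpolates
  w <- rnorm(30)
  critic <- linear_critic(w)
  xhat <- matrix(runif(8 * 30, -1, 1), 8)
  expect_equal(wdiv_penalty(critic, xhat), 2 * sum(w^2)^3, tolerance = 1e-6)
  # exact hand value: ||w|| = sqrt(2), p = 6, k = 2 -> 2 * (sqrt 2)^6 = 16
  critic2 <- linear_critic(c(1, 1, rep(0, 28)))
  expect_equal(wdiv_penalty(critic2, xhat, p = 6, k = 2), 16, tolerance = 1e-9)
  # randomized p and k
  for (i in 1:10) {
    p <- runif(1, 1, 8); k <- runif(1, 0, 4)
    w <- rnorm(12); xh <- matrix(rnorm(5 * 12), 5)
    expect_equal(wdiv_penalty(linear_critic(w), xh, p, k),
                 k * sqrt(sum(w^2))^p, tolerance = 1e-6)
  }
  # constant critic and k = 0
  expect_equal(wdiv_penalty(linear_critic(rep(0, 30)), xhat), 0)
  expect_equal(wdiv_penalty(critic, xhat, k = 0), 0)
})

test_that("penalty parameter gradients agree with finite differences", {
  set.seed(33)
  critic <- wgan_critic(10, hidden = c(6, 4))
  xh <- matrix(rnorm(5 * 10), 5)
  pg <- cellmixup:::wdiv_penalty_grads(critic, xh, p = 6, k = 2)
  expect_equal(pg$penalty, wdiv_penalty(critic, xh, 6, 2))
  eps <- 1e-6
  for (li in c(1L, 3L, 5L)) {
    analytic <- switch(as.character(li), "1" = pg$dW1, "3" = pg$dW2, "5" = pg$dw3)
    for (idx in sample(length(critic$layers[[li]]$W), 4)) {
      up <- critic; up$layers[[li]]$W[idx] <- up$layers[[li]]$W[idx] + eps
      dn <- critic; dn$layers[[li]]$W[idx] <- dn$layers[[li]]$W[idx] - eps
      num <- (wdiv_penalty(up, xh, 6, 2) - wdiv_penalty(dn, xh, 6, 2)) / (2 * eps)
      expect_equal(analytic[idx], num, tolerance = 1e-4)
    }
  }
})

test_that("critic objectives follow the printed formulas with opposed signs", {
  expect_equal(critic_objective_wgan_div(0.5, 1.0, 0.2), 0.3)
  expect_equal(critic_objective_wgan_div(c(1, 1), c(1, 1), 0), 0)
  expect_equal(critic_objective_wgan_div(0, 0, 0.7), -0.7)
  expect_equal(critic_objective_wgan(0.5, 1.0), -0.5)
  expect_equal(critic_objective_wgan(c(2, 4), c(2, 4)), 0)
  # with zero penalty the two printed conventions are exact negations
  set.seed(34)
  rs <- rnorm(8); fs <- rnorm(8)
  expect_equal(critic_objective_wgan_div(rs, fs, 0), -critic_objective_wgan(rs, fs))
  expect_error(critic_objective_wgan(numeric(0), 1), "empty")
})

test_that("minority pool enrichment keeps originals, hits the target and is seeded", {
  set.seed(35)
  orig <- lapply(1:5, function(i) random_image(12, 12))
  out <- enrich_minority_pool(orig, 40)
  expect_length(out, 40L)
  expect_identical(out[1:5], orig)
  for (img in out) expect_true(all(img >= 0 & img <= 255))
  expect_identical(enrich_minority_pool(orig, 5), orig)
  set.seed(36); a <- enrich_minority_pool(orig, 12)
  set.seed(36); b <- enrich_minority_pool(orig, 12)
  expect_identical(a, b)
  expect_error(enrich_minority_pool(list(), 5), "non-empty")
  # transformed copies genuinely differ from their sources
  expect_gt(mean(abs(out[[6]] - orig[[1]])), 1)
})

test_that("training alternates exactly n_critic critic steps per generator step and is deterministic", {
  set.seed(37)
  pool <- lapply(1:20, function(i) random_image(8, 8))
  cfg <- wgan_div_config(max_steps = 20L, n_critic = 4L, batch_size = 8L,
                         noise_dim = 8L, hidden_critic = c(16L, 16L),
                         hidden_generator = c(16L, 16L), seed = 5L)
  fit <- train_wgan_div(pool, cfg)
  expect_s3_class(fit, "wgan_div_fit")
  expect_identical(fit$critic_steps, 4L * fit$generator_steps)
  expect_true(all(is.finite(fit$trace$critic_objective)))
  expect_true(all(is.finite(fit$trace$generator_objective)))
  expect_lte(fit$step, cfg$max_steps)
  fit2 <- train_wgan_div(pool, cfg)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$step, fit2$step)
  # wgan objective path: weight clipping bounds every critic weight
  cfg_w <- wgan_div_config(objective = "wgan", max_steps = 5L, batch_size = 8L,
                           noise_dim = 8L, hidden_critic = c(16L, 16L),
                           hidden_generator = c(16L, 16L), clip_threshold = 0.01,
                           seed = 6L)
  fit_w <- train_wgan_div(pool, cfg_w)
  for (ly in fit_w$critic$layers) {
    if (!is.null(ly$W)) expect_true(all(abs(ly$W) <= 0.01 + 1e-12))
  }
})

test_that("generated samples have training dims, valid range and seeded determinism", {
  set.seed(38)
  pool <- lapply(1:12, function(i) random_image(8, 8))
  cfg <- wgan_div_config(max_steps = 8L, batch_size = 8L, noise_dim = 8L,
                         hidden_critic = c(16L, 16L), hidden_generator = c(16L, 16L),
                         seed = 9L)
  fit <- train_wgan_div(pool, cfg)
  s <- generate_samples(fit, 7, seed = 1)
  expect_length(s, 7L)
  expect_equal(dim(s[[1]]), c(8L, 8L, 3L))
  for (img in s) expect_true(all(img >= 0 & img <= 255))
  expect_identical(generate_samples(fit, 3, seed = 2), generate_samples(fit, 3, seed = 2))
  expect_error(generate_samples(fit, 0), "positive")
})

test_that("config defaults follow the published hyperparameters", {
  cfg <- wgan_div_config()
  expect_equal(cfg$p, 6)
  expect_equal(cfg$k, 2)
  expect_identical(cfg$n_critic, 4L)
  expect_equal(cfg$learning_rate, 2e-4)
  expect_error(wgan_div_config(p = 0), "p must")
  expect_error(wgan_div_config(n_critic = 0), "n_critic")
})
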