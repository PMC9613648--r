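test_that("batch plans reproduce the published configuration arithmetic", {
  # cell-cycle style: 8 originals, n = (2, 2, 1, 1) -> 24 synthetic, 32 total
  cc <- sampler_config(c(anaphase = 2, metaphase = 2, prophase = 1, telophase = 1),
                       originals_per_batch = 8, m = 5)
  plan <- batch_plan(cc)
  expect_equal(sum(plan$wgan) + sum(plan$mixup) + sum(plan$nonlinear_mixup), 24L)
  expect_equal(batch_total(plan), 32L)
  # RBC style: 12 originals, five classes at n = 1 -> 20 synthetic, 32 total
  rbc <- sampler_config(stats::setNames(rep(1L, 5), paste0("c", 1:5)),
                        originals_per_batch = 12, m = 5)
  expect_equal(batch_total(batch_plan(rbc)), 32L)
  # n = 1 contributes exactly 4 images: 2 wgan + 1 mixup + 1 nonlinear mixup
  one <- batch_plan(sampler_config(c(x = 1), originals_per_batch = 28, m = 5))
  expect_equal(one$wgan, 2L)
  expect_equal(one$mixup, 1L)
  expect_equal(one$nonlinear_mixup, 1L)
  # degenerate: no minority classes -> all-original batch of 2^m
  none <- sampler_config(integer(0), originals_per_batch = 16, m = 4)
  expect_equal(batch_total(batch_plan(none)), 16L)
  expect_equal(nrow(batch_plan(none)), 0L)
})

test_that("configs violating the 2^m constraint fail with the shortfall or excess", {
  expect_error(sampler_config(c(a = 1), 8, m = 5), "shortfall of 20")
  expect_error(sampler_config(c(a = 7), 8, m = 5), "excess of 4")
  expect_error(sampler_config(c(a = -1), 8, m = 5), ">= 0")
})

test_that("the 2^m conservation law holds across valid configs", {
  set.seed(41)
  for (i in 1:20) {
    m <- sample(4:7, 1)
    k <- sample(0:3, 1)
    n <- if (k > 0) stats::setNames(sample(0:3, k, replace = TRUE), paste0("c", seq_len(k))) else integer(0)
    orig <- 2L^m - 4L * sum(n)
    if (orig < 1L) next
    cfg <- sampler_config(n, orig, m)
    expect_equal(batch_total(batch_plan(cfg)), 2L^m)
    # raising any n by 1 adds exactly 4 synthetic images
    if (k > 0 && orig > 4L) {
      n2 <- n; n2[1] <- n2[1] + 1L
      cfg2 <- sampler_config(n2, orig - 4L, m)
      p1 <- batch_plan(cfg); p2 <- batch_plan(cfg2)
      expect_equal(
        sum(p2$wgan, p2$mixup, p2$nonlinear_mixup) -
          sum(p1$wgan, p1$mixup, p1$nonlinear_mixup), 4L)
    }
  }
})

test_that("composed batches match the plan, tag minority synthetics and are seeded", {
  ds <- small_blob_dataset()
  pools <- fake_pools(ds)
  pools$round_small <- pools$mitotic_a # a fourth oversampled class for this config
  cfg <- sampler_config(c(mitotic_a = 2, mitotic_b = 2, mitotic_c = 1, round_small = 1),
                        originals_per_batch = 8, m = 5)
  set.seed(42)
  mb <- compose_batch(ds, pools, cfg)
  expect_s3_class(mb, "mini_batch")
  expect_equal(nrow(mb), 32L)
  src <- table(mb$source)
  expect_equal(as.integer(src[c("original", "wgan", "mixup", "nonlinear_mixup")]),
               c(8L, 12L, 6L, 6L))
  # every synthetic item is labelled with a class that has n > 0
  synth <- mb[mb$source != "original", ]
  expect_true(all(synth$class %in% names(cfg$n_per_class)))
  # per-class synthetic counts follow 2n / n / n
  for (cls in names(cfg$n_per_class)) {
    n_c <- cfg$n_per_class[[cls]]
    expect_equal(sum(synth$class == cls & synth$source == "wgan"), 2L * n_c)
    expect_equal(sum(synth$class == cls & synth$source == "mixup"), n_c)
    expect_equal(sum(synth$class == cls & synth$source == "nonlinear_mixup"), n_c)
  }
  set.seed(43); a <- compose_batch(ds, pools, cfg)
  set.seed(43); b <- compose_batch(ds, pools, cfg)
  expect_identical(a, b)
  expect_error(compose_batch(ds, pools["mitotic_a"], cfg), "mitotic_b")
})

test_that("epoch streams partition the originals and pad the last batch", {
  ds <- small_blob_dataset(counts = c(20L, 20L, 6L, 5L, 5L)) # 56 originals
  pools <- fake_pools(ds)
  cfg <- sampler_config(c(mitotic_a = 1), originals_per_batch = 28, m = 5)
  set.seed(44)
  batches <- epoch_stream(ds, pools, cfg)
  expect_length(batches, 2L) # 56 / 28
  for (b in batches) expect_equal(nrow(b), 32L)
  cfg_pad <- sampler_config(c(mitotic_a = 1), originals_per_batch = 12, m = 4)
  set.seed(45)
  batches <- epoch_stream(ds, pools, cfg_pad)
  expect_length(batches, ceiling(56 / 12))
  for (b in batches) expect_equal(nrow(b), 16L)
  # dropping instead of padding is available
  cfg_drop <- sampler_config(c(mitotic_a = 1), 12, m = 4, pad_last = FALSE)
  set.seed(45)
  expect_length(epoch_stream(ds, pools, cfg_drop), 56 %/% 12)
})

test_that("the standard-sampling baseline reflects the merged pool's minority fraction", {
  ds <- small_blob_dataset(counts = c(30L, 30L, 8L, 6L, 5L))
  pools <- fake_pools(ds, per_class = 10L)
  set.seed(46)
  batches <- standard_stream(ds, pools, batch_size = 32L, n_batches = 150L)
  frac <- mean(vapply(batches, function(b) mean(b$class %in% ds$minority), 0))
  pool_frac <- (8 + 6 + 5 + 30) / (30 + 30 + 8 + 6 + 5 + 30)
  expect_equal(frac, pool_frac, tolerance = 0.05)
})
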