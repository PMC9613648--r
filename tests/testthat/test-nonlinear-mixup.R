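test_that("rotation matrices are orthogonal with determinant 1 and match the printed forms", {
  expect_equal(rotation_matrix(rotation_spec("R", 0)), diag(3))
  expect_equal(rotation_matrix(rotation_spec("G", 0)), diag(3))
  expect_equal(rotation_matrix(rotation_spec("B", 0)), diag(3))
  expect_equal(rotation_matrix(rotation_spec("B", 90)),
               matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE),
               tolerance = 1e-12)
  set.seed(21)
  for (i in 1:25) {
    spec <- rotation_spec(sample(c("R", "G", "B"), 1), runif(1, -720, 720))
    m <- rotation_matrix(spec)
    expect_equal(t(m) %*% m, diag(3), tolerance = 1e-9)
    expect_equal(det(m), 1, tolerance = 1e-9)
  }
  expect_error(rotation_spec("X", 10), "axis")
})

test_that("pixel rotation follows the row-vector convention and fixes the axis component", {
  expect_equal(rotate_pixel(c(1, 0, 0), rotation_spec("B", 90)), c(0, -1, 0),
               tolerance = 1e-12)
  expect_equal(rotate_pixel(c(0, 0, 7), rotation_spec("B", 123)), c(0, 0, 7))
  # radius sqrt(I_R^2 + I_G^2) preserved under B-axis rotation
  p <- rotate_pixel(c(3, 4, 7), rotation_spec("B", 77.7))
  expect_equal(sqrt(p[1]^2 + p[2]^2), 5, tolerance = 1e-9)
  expect_equal(p[3], 7)
  set.seed(22)
  for (i in 1:20) {
    px <- runif(3, -255, 255)
    axis <- sample(c("R", "G", "B"), 1)
    spec <- rotation_spec(axis, runif(1, 0, 360))
    out <- rotate_pixel(px, spec)
    expect_equal(sqrt(sum(out^2)), sqrt(sum(px^2)), tolerance = 1e-9) # norm preserved
    ax_i <- match(axis, c("R", "G", "B"))
    expect_equal(out[ax_i], px[ax_i], tolerance = 1e-9)
  }
})

test_that("rotations about a common axis compose additively in angle", {
  set.seed(23)
  for (axis in c("R", "G", "B")) {
    t1 <- runif(1, 0, 360); t2 <- runif(1, 0, 360)
    expect_equal(
      rotation_matrix(rotation_spec(axis, t1)) %*% rotation_matrix(rotation_spec(axis, t2)),
      rotation_matrix(rotation_spec(axis, t1 + t2)),
      tolerance = 1e-9
    )
  }
})

test_that("sampled rotations cover axes uniformly with theta in [0, 360)", {
  set.seed(24)
  specs <- replicate(3e4, sample_rotation(), simplify = FALSE)
  axes <- table(vapply(specs, `[[`, "", "axis")) / 3e4
  expect_true(all(abs(axes - 1 / 3) < 0.01))
  thetas <- vapply(specs, `[[`, 0, "theta")
  expect_true(all(thetas >= 0 & thetas < 360))
  set.seed(77); s1 <- replicate(5, sample_rotation(), simplify = FALSE)
  set.seed(77); s2 <- replicate(5, sample_rotation(), simplify = FALSE)
  expect_identical(s1, s2)
})

test_that("nonlinear mixup reduces to mixup at theta 0 and preserves the rotation-axis channel", {
  set.seed(25)
  i1 <- random_image(); i2 <- random_image()
  lam <- sample_lambda()
  expect_identical(nonlinear_mixup(i1, i2, lam, rotation_spec("G", 0)),
                   mixup(i1, i2, lam))
  spec <- rotation_spec("R", 211.5)
  out <- nonlinear_mixup(i1, i2, lam, spec, clip = FALSE)
  expect_equal(out[, , 1], mixup(i1, i2, lam)[, , 1]) # R channel untouched
  # inverse rotation recovers the mixup image when nothing clipped
  back <- rotate_image(out, rotation_spec("R", -211.5), clip = FALSE)
  expect_equal(back, mixup(i1, i2, lam), tolerance = 1e-6)
})

test_that("out-of-cube rotated intensities clip to [0, 255]", {
  px <- array(c(255, 0, 0), c(1, 1, 3))
  out <- rotate_image(px, rotation_spec("B", 90), clip = FALSE)
  expect_equal(drop(out), c(0, -255, 0), tolerance = 1e-9)
  clipped <- rotate_image(px, rotation_spec("B", 90))
  expect_equal(drop(clipped), c(0, 0, 0), tolerance = 1e-9)
  set.seed(26)
  big <- nonlinear_mixup(random_image(), random_image(), 0.4)
  expect_true(all(big >= 0 & big <= 255))
})
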