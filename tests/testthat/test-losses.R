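test_that("bce matches the longhand oracle and its closed forms", {
  set.seed(10)
  p <- array(stats::runif(49, 0.02, 0.98), c(7, 7, 1))
  expect_equal(bce(p, 1), oracle_bce(p, 1), tolerance = 1e-12)
  expect_equal(bce(p, 0), oracle_bce(p, 0), tolerance = 1e-12)
  # closed form at the uninformed prediction
  half <- array(0.5, c(3, 3, 1))
  expect_equal(bce(half, 1), log(2), tolerance = 1e-12)
  expect_equal(bce(half, 0), log(2), tolerance = 1e-12)
  # clamping keeps extreme predictions finite
  expect_true(is.finite(bce(array(0, c(2, 2, 1)), 1)))
  expect_equal(bce(array(0, c(2, 2, 1)), 1), -log(1e-7), tolerance = 1e-9)
  expect_error(bce(half, 0.5), "0 or 1")
  expect_error(bce(array(NaN, c(2, 2, 1)), 1), "non-finite")
})

test_that("L1-type losses match loop oracles and vanish at equality", {
  set.seed(11)
  x <- rand_img(12); y <- rand_img(12)
  rx <- rand_img(12); ry <- rand_img(12)
  expect_equal(cycle_loss(x, rx, y, ry), oracle_l1(rx, x) + oracle_l1(ry, y),
               tolerance = 1e-12)
  expect_equal(identity_loss(y, ry, x, rx), oracle_l1(ry, y) + oracle_l1(rx, x),
               tolerance = 1e-12)
  expect_equal(voxel_loss(ry, y, rx, x), oracle_l1(ry, y) + oracle_l1(rx, x),
               tolerance = 1e-12)
  expect_equal(cycle_loss(x, x, y, y), 0)
  expect_equal(voxel_loss(y, y, x, x), 0)
  expect_error(cycle_loss(x, rand_img(6), y, ry), "shapes")
})

test_that("gradient-difference loss matches the oracle and ignores DC shifts", {
  set.seed(12)
  fy <- rand_img(10); y <- rand_img(10)
  fx <- rand_img(10); x <- rand_img(10)
  expect_equal(gradient_difference_loss(fy, y, fx, x),
               oracle_gd_one(as2d(fy), as2d(y)) + oracle_gd_one(as2d(fx), as2d(x)),
               tolerance = 1e-12)
  # adding a constant to any image leaves the loss unchanged
  expect_equal(gradient_difference_loss(fy + 3, y, fx, x - 1),
               gradient_difference_loss(fy, y, fx, x), tolerance = 1e-12)
  expect_equal(gradient_difference_loss(y, y, x, x), 0)
})

test_that("ssim loss is -log SSIM per direction and zero at identity", {
  set.seed(13)
  y <- rand_img(16); x <- rand_img(16)
  fy <- y + array(stats::rnorm(256, sd = 0.05), c(16, 16, 1))
  fx <- x + array(stats::rnorm(256, sd = 0.05), c(16, 16, 1))
  expected <- -log(oracle_ssim(as2d(fy), as2d(y), 2)) -
    log(oracle_ssim(as2d(fx), as2d(x), 2))
  expect_equal(ssim_loss(fy, y, fx, x), expected, tolerance = 1e-8)
  expect_equal(ssim_loss(y, y, x, x), 0, tolerance = 1e-12)
  expect_gt(ssim_loss(fy, y, fx, x), 0)
})

test_that("perceptual loss is deterministic, non-negative, zero at identity", {
  set.seed(14)
  y <- rand_img(16)
  fy <- rand_img(16)
  v1 <- perceptual_loss(fy, y)
  v2 <- perceptual_loss(fy, y)
  expect_identical(v1, v2)
  expect_gt(v1, 0)
  expect_equal(perceptual_loss(y, y), 0)
  # the frozen extractor is seed-reproducible and never touches the RNG state
  set.seed(99); before <- .Random.seed
  e1 <- feature_extractor()
  expect_identical(.Random.seed, before)
  e2 <- feature_extractor()
  expect_equal(lapply(e1$layers, function(l) ctsynth:::ad_value(l$w)),
               lapply(e2$layers, function(l) ctsynth:::ad_value(l$w)))
})

test_that("adversarial and discriminator losses combine BCE terms correctly", {
  set.seed(15)
  gy <- array(stats::runif(9, 0.05, 0.95), c(3, 3, 1))
  gx <- array(stats::runif(9, 0.05, 0.95), c(3, 3, 1))
  ry <- array(stats::runif(9, 0.05, 0.95), c(3, 3, 1))
  rx <- array(stats::runif(9, 0.05, 0.95), c(3, 3, 1))
  expect_equal(adversarial_loss(gy, gx), oracle_bce(gy, 1) + oracle_bce(gx, 1),
               tolerance = 1e-12)
  expect_equal(discriminator_loss(ry, gy, rx, gx),
               0.5 * (oracle_bce(ry, 1) + oracle_bce(gy, 0) +
                        oracle_bce(rx, 1) + oracle_bce(gx, 0)),
               tolerance = 1e-12)
  # maximally confused discriminator: all grids at 0.5 give 2 log 2
  half <- array(0.5, c(3, 3, 1))
  expect_equal(discriminator_loss(half, half, half, half), 2 * log(2),
               tolerance = 1e-12)
})

test_that("generator_total applies the published weights", {
  parts <- list(adv = 1, cyc = 1, id = 1, gd = 1, perceptual = 1, ssim = 1,
                vox = 1)
  bd <- generator_total(parts)
  # 1 + 10 + 10 + 10 + 1 + 0.5 + 10
  expect_equal(bd$total, 42.5)
  expect_s3_class(bd, "loss_breakdown")
  w2 <- loss_weights(lambda_cyc = 2, lambda_id = 0, lambda_gd = 1,
                     lambda_vox = 3, lambda_ssim = 1)
  expect_equal(generator_total(parts, w2)$total, 1 + 2 + 0 + 1 + 1 + 1 + 3)
  expect_error(generator_total(parts[-1]), "missing loss components")
  parts$cyc <- -1
  expect_error(generator_total(parts), "non-negative")
  expect_error(loss_weights(lambda_cyc = -1), "non-negative")
})

test_that("loss weights default to the published operating point", {
  w <- loss_weights()
  expect_equal(w$lambda_cyc, 10)
  expect_equal(w$lambda_id, 10)
  expect_equal(w$lambda_gd, 10)
  expect_equal(w$lambda_vox, 10)
  expect_equal(w$lambda_ssim, 0.5)
})
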