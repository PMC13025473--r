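test_that("one Adam step on a single parameter matches the oracle", {
  p <- ctsynth:::ad_param(c(1, -2, 3))
  p$g <- c(0.5, -1, 2)
  st <- ctsynth:::adam_init(list(a = p))
  st <- ctsynth:::adam_step(list(a = p), st, lr = 0.1, beta1 = 0.5,
                            beta2 = 0.999)
  ref <- oracle_adam_step(c(1, -2, 3), c(0.5, -1, 2), m = c(0, 0, 0),
                          v = c(0, 0, 0), t = 1, lr = 0.1, beta1 = 0.5,
                          beta2 = 0.999)
  expect_equal(ctsynth:::ad_value(p), ref$theta, tolerance = 1e-12)
  # second step keeps moment state
  p$g <- c(1, 1, 1)
  st <- ctsynth:::adam_step(list(a = p), st, 0.1, 0.5, 0.999)
  ref2 <- oracle_adam_step(ref$theta, c(1, 1, 1), ref$m, ref$v, t = 2,
                           lr = 0.1, beta1 = 0.5, beta2 = 0.999)
  expect_equal(ctsynth:::ad_value(p), ref2$theta, tolerance = 1e-12)
  # Adam minimizes a simple quadratic
  q <- ctsynth:::ad_param(5)
  stq <- ctsynth:::adam_init(list(q = q))
  for (i in 1:300) {
    q$g <- 2 * ctsynth:::ad_value(q)
    stq <- ctsynth:::adam_step(list(q = q), stq, 0.05, 0.5, 0.999)
  }
  expect_lt(abs(ctsynth:::ad_value(q)), 0.05)
})

test_that("check_split flags shared patients and passes disjoint ones", {
  ok <- check_split(c("A", "B", "C"), c("D", "E"))
  expect_equal(ok$status, "pass")
  expect_length(ok$shared, 0L)
  bad <- check_split(c("A", "B", "C"), c("C", "D"))
  expect_equal(bad$status, "fail")
  expect_equal(bad$shared, "C")
  expect_match(bad$message, "leakage")
  expect_warning(check_split(c("A"), character(0)), "no patients")
})

test_that("train_cyclegan refuses leaking manifests", {
  dir <- withr::local_tempdir()
  man <- generate_phantom_dataset(phantom_spec(seed = 50), n_patients = 2,
                                  slices_per_patient = 1, out = dir)
  expect_error(train_cyclegan(man, train_config(epochs = 1), test_manifest = man),
               "refusing to train")
})

test_that("a short fit returns a well-formed cyclegan object", {
  pairs <- toy_pairs(n = 2, size = 32)
  cfg <- train_config(epochs = 2, seed = 42,
                      generator = generator_config(base_filters = 16L,
                                                   n_levels = 2L,
                                                   n_res_blocks = 1L),
                      discriminator = tiny_preset()$discriminator)
  fit <- fit_cyclegan(pairs, cfg)
  expect_s3_class(fit, "cyclegan")
  expect_equal(nrow(fit$history), 2L)
  expect_true(all(is.finite(as.matrix(fit$history))))
  expect_true(all(as.matrix(fit$history) >= 0))
  # losses include every component of the composite objective
  expect_setequal(colnames(fit$history),
                  c("adv", "cyc", "id", "gd", "perceptual", "ssim", "vox",
                    "total", "disc"))
  # the recorded total honors the weighting identity up to numerical noise
  h <- fit$history
  w <- cfg$weights
  recomputed <- h$adv + w$lambda_cyc * h$cyc + w$lambda_id * h$id +
    w$lambda_gd * h$gd + h$perceptual + w$lambda_ssim * h$ssim +
    w$lambda_vox * h$vox
  expect_equal(h$total, recomputed, tolerance = 1e-8)
  # S3 surface
  expect_output(print(fit), "CycleGAN")
  expect_output(summary(fit), "Loss history")
  expect_type(coef(fit), "list")
  expect_gt(length(coef(fit, "d_x")), 0)

  # deterministic given the seed
  fit2 <- fit_cyclegan(pairs, cfg)
  expect_equal(coef(fit)[["stem.w"]], coef(fit2)[["stem.w"]], tolerance = 1e-12)

  # inference mirrors geometry and bounds HU by the normalization range
  nv <- ct_volume("T01", list(pairs[[1]]$ncct), 0, series_kind = "NCCT")
  sv <- synthesize(nv, fit)
  expect_s3_class(sv, "ct_volume")
  expect_equal(sv$series_kind, "sCECT")
  expect_equal(dim(sv$slices[[1]]), dim(nv$slices[[1]]))
  expect_equal(sv$slice_positions, nv$slice_positions)
  expect_true(all(sv$slices[[1]] >= -1024 & sv$slices[[1]] <= 1024))
  expect_equal(predict(fit, nv)$slices[[1]], sv$slices[[1]], tolerance = 1e-12)

  # checkpoints reproduce the fit exactly
  ck <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(fit, ck)
  back <- load_checkpoint(ck)
  expect_equal(synthesize(nv, back)$slices[[1]], sv$slices[[1]],
               tolerance = 1e-12)
  expect_equal(as.matrix(back$history), as.matrix(fit$history),
               tolerance = 1e-12)
  expect_error(load_checkpoint(ck, config = train_config(epochs = 3)),
               "different configuration")
  # synthesize accepts a checkpoint path directly
  expect_equal(synthesize(nv, ck)$slices[[1]], sv$slices[[1]],
               tolerance = 1e-12)
})

test_that("training reduces the composite loss on a paired toy problem", {
  pairs <- toy_pairs(n = 3, size = 32, seed = 11)
  cfg <- train_config(epochs = 4, seed = 7,
                      generator = tiny_preset()$generator,
                      discriminator = tiny_preset()$discriminator)
  fit <- fit_cyclegan(pairs, cfg)
  h <- fit$history
  expect_lt(h$total[4], h$total[1])
  expect_lt(h$vox[4], h$vox[1])
})
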