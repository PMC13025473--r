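test_that("phantom generation is deterministic given the seed", {
  spec <- phantom_spec(seed = 5)
  p1 <- generate_phantom_pair(spec)
  p2 <- generate_phantom_pair(spec)
  expect_identical(p1$ncct, p2$ncct)
  expect_identical(p1$cect, p2$cect)
  expect_identical(p1$masks, p2$masks)
  p3 <- generate_phantom_pair(spec, seed = 6)
  expect_false(identical(p1$ncct, p3$ncct))
  # generation restores the caller's RNG state
  set.seed(123); before <- .Random.seed
  invisible(generate_phantom_pair(spec))
  expect_identical(.Random.seed, before)
})

test_that("phantom masks are disjoint and cover the image", {
  p <- generate_phantom_pair(phantom_spec(seed = 8))
  m <- p$masks
  total <- m$background + m$soft_tissue + m$vessel + m$node
  expect_true(all(total == 1))  # partition: each pixel in exactly one class
  expect_gt(sum(m$vessel), 0)
  expect_gt(sum(m$node), 0)
  expect_gt(sum(m$soft_tissue), sum(m$vessel))  # bulk of the body disc
})

test_that("clean phantom compartments carry the configured HU values", {
  spec <- phantom_spec(noise_sd = 0, misalignment_px = 0, seed = 9)
  p <- generate_phantom_pair(spec)
  expect_true(all(p$ncct[p$masks$background] == -1000))
  expect_true(all(p$ncct[p$masks$soft_tissue] == 40))
  expect_true(all(p$ncct[p$masks$vessel] == 45))
  expect_true(all(p$ncct[p$masks$node] == 35))
  expect_true(all(p$cect[p$masks$vessel] == 295))  # 45 + 250
  expect_true(all(p$cect[p$masks$node] == 95))     # 35 + 60
  expect_true(all(p$cect[p$masks$soft_tissue] == 40))
  expect_identical(p$shift, c(0L, 0L))
})

test_that("noise-free MAE equals the closed-form area-weighted enhancement", {
  spec <- phantom_spec(noise_sd = 0, misalignment_px = 0, seed = 10)
  p <- generate_phantom_pair(spec)
  expected <- (sum(p$masks$vessel) * 250 + sum(p$masks$node) * 60) /
    length(p$ncct)
  expect_equal(mae(p$cect, p$ncct), expected, tolerance = 1e-12)
  expect_equal(phantom_expected_mae(p), expected, tolerance = 1e-12)
  # the closed form also matches on the retained clean images of a noisy pair
  pn <- generate_phantom_pair(phantom_spec(seed = 10))
  expect_equal(mae(pn$cect_clean, pn$ncct_clean), phantom_expected_mae(pn),
               tolerance = 1e-12)
})

test_that("misalignment translates the CECT by the recorded integer shift", {
  spec <- phantom_spec(noise_sd = 0, misalignment_px = 3, seed = 12)
  p <- generate_phantom_pair(spec)
  expect_true(all(abs(p$shift) <= 3))
  # undoing the recorded shift recovers the clean CECT on the overlap
  s <- nrow(p$cect_clean)
  shifted <- ctsynth:::translate_int(p$cect_clean, p$shift[1], p$shift[2], -1000)
  expect_identical(p$cect, shifted)
})

test_that("suggested ROIs land inside their compartments", {
  p <- generate_phantom_pair(phantom_spec(seed = 14))
  r <- ctsynth:::suggest_rois(p)
  expect_equal(r$label, "vessel")
  tm <- ctsynth:::roi_mask(r$target, dim(p$ncct))
  expect_true(all(p$masks$vessel[tm]))
  bm <- ctsynth:::roi_mask(r$background, dim(p$ncct))
  expect_true(all(p$masks$soft_tissue[bm]))
})

test_that("dataset generation writes readable series plus a manifest", {
  dir <- withr::local_tempdir()
  man <- generate_phantom_dataset(phantom_spec(seed = 15), n_patients = 3,
                                  slices_per_patient = 2, out = dir)
  expect_s3_class(man, "phantom_manifest")
  expect_length(man$patients, 3L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_manifest(dir)
  expect_equal(names(back$patients), names(man$patients))
  v <- read_ct_series(file.path(dir, "PHANTOM001", "ncct"), series_kind = "NCCT")
  expect_length(v$slices, 2L)
  expect_equal(dim(v$slices[[1]]), c(64L, 64L))
  # same seed regenerates identical pixel data
  dir2 <- withr::local_tempdir()
  generate_phantom_dataset(phantom_spec(seed = 15), n_patients = 3,
                           slices_per_patient = 2, out = dir2)
  v2 <- read_ct_series(file.path(dir2, "PHANTOM001", "ncct"), series_kind = "NCCT")
  expect_identical(v$slices, v2$slices)
  # refuses to clobber without overwrite
  expect_error(generate_phantom_dataset(phantom_spec(seed = 15), 1, 1, out = dir),
               "not empty")
})

test_that("split_manifest separates patients without overlap", {
  dir <- withr::local_tempdir()
  man <- generate_phantom_dataset(phantom_spec(seed = 16), n_patients = 6,
                                  slices_per_patient = 1, out = dir)
  sp <- split_manifest(man, test_fraction = 1 / 3, seed = 2)
  expect_length(sp$test$patients, 2L)
  expect_length(sp$train$patients, 4L)
  expect_length(intersect(names(sp$train$patients), names(sp$test$patients)), 0L)
  expect_setequal(c(names(sp$train$patients), names(sp$test$patients)),
                  names(man$patients))
  # at least one test patient even for tiny fractions
  sp2 <- split_manifest(man, test_fraction = 0.01, seed = 2)
  expect_gte(length(sp2$test$patients), 1L)
  expect_error(split_manifest(man, test_fraction = 1), "no training patients")
})

test_that("load_pairs returns one HU pair per slice with patient tags", {
  dir <- withr::local_tempdir()
  man <- generate_phantom_dataset(phantom_spec(seed = 17), n_patients = 2,
                                  slices_per_patient = 3, out = dir)
  pairs <- load_pairs(man)
  expect_length(pairs, 6L)
  expect_setequal(unique(vapply(pairs, `[[`, character(1), "patient")),
                  c("PHANTOM001", "PHANTOM002"))
  expect_true(all(vapply(pairs, function(p) is.matrix(p$ncct) &&
                           identical(dim(p$ncct), dim(p$cect)), logical(1))))
})
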