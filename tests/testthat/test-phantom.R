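test_that("the same seed reproduces the phantom bit for bit", {
  a <- generate_phantom(tissues = default_phantom_tissues(c(24, 24, 12)),
                        dim = c(24, 24, 12), slices_per_station = 6,
                        noise_sigma = 8, seed = 123)
  b <- generate_phantom(tissues = default_phantom_tissues(c(24, 24, 12)),
                        dim = c(24, 24, 12), slices_per_station = 6,
                        noise_sigma = 8, seed = 123)
  expect_identical(a$study$stations[[1]]$signals, b$study$stations[[1]]$signals)
  expect_identical(a$truth$adc_true, b$truth$adc_true)

  c2 <- generate_phantom(tissues = default_phantom_tissues(c(24, 24, 12)),
                         dim = c(24, 24, 12), slices_per_station = 6,
                         noise_sigma = 8, seed = 124)
  expect_false(identical(a$study$stations[[1]]$signals[["50"]],
                         c2$study$stations[[1]]$signals[["50"]]))
})

test_that("tissue ADC draws respect the class bands and masks are disjoint", {
  ph <- cached_phantom()
  tr <- ph$truth
  expect_true(all(tr$adc_true[tr$masks$marrow$voxels] < 650))
  les <- tr$adc_true[tr$masks$lesion$voxels]
  expect_true(all(les >= 650 & les <= 1400))
  expect_true(all(tr$adc_true[tr$masks$necrosis$voxels] > 1400))

  total <- Reduce(`+`, lapply(tr$masks, function(m) m$voxels * 1L))
  expect_true(all(total == 1L))  # every voxel claimed exactly once
})

test_that("noiseless phantom signals invert exactly through fit_adc", {
  fx <- cached_fused()
  tr <- fx$ph$truth
  body <- !tr$masks$background$voxels
  expect_true(all(fx$adc$valid[body]))
  rel <- abs(fx$adc$values[body] - tr$adc_true[body]) /
    pmax(tr$adc_true[body], 1)
  expect_lt(max(rel), 1e-9)
})

test_that("overlapping primitives are ambiguous unless nesting is requested", {
  g <- c(16, 16, 8)
  tissues <- list(
    tissue_spec("marrow", "box", c(8, 8, 4), c(4, 4, 4), S0 = 400,
                adc_mean = 350, adc_sd = 0),
    tissue_spec("lesion", "ellipsoid", c(8, 8, 4), c(2, 2, 2), S0 = 550,
                adc_mean = 1000, adc_sd = 0)
  )
  expect_error(
    generate_phantom(tissues, dim = g, slices_per_station = 8,
                     overlap = "error"),
    "ambiguous tissue assignment")
  ph <- generate_phantom(tissues, dim = g, slices_per_station = 8,
                         overlap = "nest")
  expect_gt(mask_count(ph$truth$masks$lesion), 0)
})

test_that("a perfect observer returns the fully cleaned threshold mask", {
  fx <- cached_fused()
  obs <- simulate_observer(fx$ph$truth, fx$computed,
                           observer_spec(seed = 17), session = 1)
  expect_equal(obs$threshold, fx$ph$truth$nominal_threshold)
  ideal <- apply_edit_script(threshold_mask(fx$computed, 41),
                             fx$ph$truth$confounder_cuts)
  expect_identical(obs$mask$voxels, ideal$voxels)
})

test_that("observers with identical spec and seed agree perfectly", {
  fx <- cached_fused()
  spec <- observer_spec(threshold_jitter = 5, edit_miss_prob = 0.3,
                        edit_extra_rate = 2, seed = 99)
  o1 <- simulate_observer(fx$ph$truth, fx$computed, spec, session = 1)
  o2 <- simulate_observer(fx$ph$truth, fx$computed, spec, session = 1)
  expect_identical(dice(o1$mask, o2$mask), 1)
  # a different session draws a different threshold under jitter
  o3 <- simulate_observer(fx$ph$truth, fx$computed, spec, session = 2)
  expect_false(isTRUE(all.equal(o1$threshold, o3$threshold)))
})

test_that("measurement matrix generator hits its ICC design points", {
  expect_equal(icc_a1(generate_measurement_matrix(30, 3, 3, 0, 0,
                                                  seed = 4))$estimate, 1)
  noisy <- generate_measurement_matrix(400, 3, 0, 0, 1, seed = 5)
  expect_lt(abs(icc_a1(noisy)$estimate), 0.1)
  m <- generate_measurement_matrix(500, 2, 3, 0, 1, seed = 6)
  expect_equal(icc_a1(m)$estimate, 0.9, tolerance = 0.05)
})

test_that("phantom exports round trip through the readers", {
  ph <- generate_phantom(tissues = default_phantom_tissues(c(16, 16, 9)),
                         dim = c(16, 16, 9), slices_per_station = 3, seed = 8)
  dir <- withr::local_tempdir()
  export_phantom(ph, dir)
  study <- read_dwi_series(dir)
  expect_length(study$stations, 3)
  m <- read_mask(file.path(dir, "truth_mask_lesion.nii"))
  expect_identical(m$voxels, ph$truth$masks$lesion$voxels)
  feats <- utils::read.csv(file.path(dir, "truth_features.csv"))
  expect_true("lesion" %in% feats$class)
})
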