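adc_from_values <- function(values, dim) {
  g <- vol_geometry(table1_spacing, dim)
  adc_map(array(values, dim), array(TRUE, dim), g, c(50, 900))
}

test_that("hand-worked three-value example is exact", {
  adc <- adc_from_values(c(650, 1025, 1400), c(3, 1, 1))
  lesion <- mask3d(array(TRUE, c(3, 1, 1)), adc$geometry)
  f <- compute_features(adc, lesion)
  expect_identical(f$n_voxels, 3L)
  expect_equal(f$volume_ml, 3 * 1.6 * 1.6 * 5.0 / 1000)  # 0.0384 ml
  expect_equal(f$mean_adc, 1025)
  expect_equal(f$median_adc, 1025)
  expect_true(f$p5_adc <= f$median_adc && f$median_adc <= f$p95_adc)
})

test_that("degenerate inputs are flagged, not raised", {
  adc <- adc_from_values(1000, c(4, 1, 1))
  empty <- mask3d(array(FALSE, c(4, 1, 1)), adc$geometry)
  f0 <- compute_features(adc, empty)
  expect_identical(f0$n_voxels, 0L)
  expect_identical(f0$volume_ml, 0)
  expect_true(is.na(f0$mean_adc))

  solid <- mask3d(array(TRUE, c(4, 1, 1)), adc$geometry)
  fc <- compute_features(adc, solid)
  expect_identical(fc$std_adc, 0)
  expect_true(is.na(fc$skewness_adc))
  expect_true(is.na(fc$kurtosis_adc))
  expect_identical(fc$entropy_adc, 0)
})

test_that("histogram counts match a per-value scan, with edge clipping", {
  set.seed(55)
  bins <- bin_scheme(c(650, 1400), 16)
  vals <- c(runif(500, 400, 1700))  # includes out-of-range values
  counts <- adc_histogram(vals, bins)
  expect_identical(sum(counts), 500L)

  edges <- seq(650, 1400, length.out = 17)
  brute <- integer(16)
  for (v in vals) {
    i <- findInterval(v, edges, rightmost.closed = TRUE)
    i <- min(max(i, 1L), 16L)
    brute[i] <- brute[i] + 1L
  }
  expect_identical(counts, brute)

  one <- adc_histogram(rep(1000, 7), bins)
  expect_identical(max(one), 7L)
  expect_identical(sum(one > 0), 1L)
})

test_that("entropy matches hand computations", {
  expect_identical(shannon_entropy(c(0, 9, 0)), 0)
  expect_equal(shannon_entropy(rep(3, 64)), 6)
  expect_equal(shannon_entropy(c(1, 1, 2)), 1.5)
  expect_equal(shannon_entropy(c(2, 2)), 1)
  expect_true(is.na(shannon_entropy(c(0, 0))))
})

test_that("scaling values and bin range scales locations, leaves shape alone", {
  set.seed(77)
  x <- rgamma(4000, shape = 4, rate = 1 / 200) + 500
  d <- c(40, 10, 10)
  lesion <- mask3d(array(TRUE, d), vol_geometry(table1_spacing, d))
  b1 <- bin_scheme(c(min(x), max(x)), 32)
  f1 <- compute_features(adc_from_values(x, d), lesion, b1)
  cc <- 1.7
  b2 <- bin_scheme(cc * c(min(x), max(x)), 32)
  f2 <- compute_features(adc_from_values(cc * x, d), lesion, b2)

  for (col in c("mean_adc", "std_adc", "median_adc", "p5_adc", "p95_adc")) {
    expect_equal(f2[[col]], cc * f1[[col]], tolerance = 1e-12)
  }
  expect_equal(f2$skewness_adc, f1$skewness_adc, tolerance = 1e-12)
  expect_equal(f2$kurtosis_adc, f1$kurtosis_adc, tolerance = 1e-12)
  expect_equal(f2$entropy_adc, f1$entropy_adc, tolerance = 1e-12)
})

test_that("adding a constant shifts location statistics only", {
  set.seed(78)
  x <- rnorm(2000, 1000, 150)
  d <- c(20, 10, 10)
  lesion <- mask3d(array(TRUE, d), vol_geometry(table1_spacing, d))
  f1 <- compute_features(adc_from_values(x, d), lesion,
                         bin_scheme(c(min(x), max(x)), 32))
  f2 <- compute_features(adc_from_values(x + 300, d), lesion,
                         bin_scheme(c(min(x), max(x)) + 300, 32))
  expect_equal(f2$mean_adc, f1$mean_adc + 300)
  expect_equal(f2$median_adc, f1$median_adc + 300)
  expect_equal(f2$std_adc, f1$std_adc, tolerance = 1e-12)
  expect_equal(f2$skewness_adc, f1$skewness_adc, tolerance = 1e-10)
  expect_equal(f2$kurtosis_adc, f1$kurtosis_adc, tolerance = 1e-10)
})

test_that("entropy of uniform data approaches the bin-count bound", {
  set.seed(79)
  x <- runif(1e5, 650, 1400)
  counts <- adc_histogram(x, bin_scheme(c(650, 1400), 64))
  h <- shannon_entropy(counts)
  expect_gt(h, 6 - 0.02)
  expect_lte(h, 6)
})
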