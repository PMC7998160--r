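test_that("study write/read round trip preserves voxels and geometry", {
  ph <- generate_phantom(
    tissues = default_phantom_tissues(c(16, 16, 12)),
    dim = c(16, 16, 12), slices_per_station = 4, seed = 11)
  dir <- withr::local_tempdir()
  write_dwi_series(ph$study, dir)
  back <- read_dwi_series(dir)

  expect_length(back$stations, 3)
  for (i in 1:3) {
    orig <- ph$study$stations[[i]]
    got <- back$stations[[i]]
    expect_identical(names(got$signals), c("50", "900"))
    for (bn in names(orig$signals)) {
      expect_equal(got$signals[[bn]], orig$signals[[bn]],
                   ignore_attr = TRUE, tolerance = 0)
    }
    expect_equal(got$geometry$spacing, orig$geometry$spacing)
    expect_equal(got$geometry$origin, orig$geometry$origin, tolerance = 1e-6)
  }
})

test_that("a missing per-station volume is an incomplete study", {
  ph <- generate_phantom(
    tissues = default_phantom_tissues(c(12, 12, 6)),
    dim = c(12, 12, 6), slices_per_station = 3, seed = 2)
  dir <- withr::local_tempdir()
  write_dwi_series(ph$study, dir)
  file.remove(file.path(dir, "station2_b900.nii"))
  expect_error(read_dwi_series(dir), "incomplete study")
})

test_that("geometry mismatch across b-values of one station is rejected", {
  dir <- withr::local_tempdir()
  g1 <- vol_geometry(c(1.6, 1.6, 5), c(8, 8, 4))
  g2 <- vol_geometry(c(2.0, 2.0, 5), c(8, 8, 4))
  wbdwi:::write_nifti_volume(array(runif(256), c(8, 8, 4)), g1,
                             file.path(dir, "a.nii"))
  wbdwi:::write_nifti_volume(array(runif(256), c(8, 8, 4)), g2,
                             file.path(dir, "b.nii"))
  writeLines(c("filename\tbvalue", "a.nii\t50", "b.nii\t900"),
             file.path(dir, "bvalues.tsv"))
  expect_error(read_dwi_series(dir), "geometry conflict")
})

test_that("assemble_body_volume stacks the requested stations contiguously", {
  # 4 stations of 50 slices; keeping stations 2-4 yields 150 fused slices
  set.seed(7)
  g <- function(st) vol_geometry(c(1.6, 1.6, 5), c(8, 8, 50),
                                 origin = c(0, 0, (st - 1) * 250))
  consts <- matrix(runif(8, 10, 100), nrow = 4)  # station x b constants
  stations <- lapply(1:4, function(st) {
    dwi_station(list("50" = array(consts[st, 1], c(8, 8, 50)),
                     "900" = array(consts[st, 2], c(8, 8, 50))),
                g(st), station_index = st)
  })
  study <- dwi_study(stations)

  fused <- assemble_body_volume(study, include = 2:4)
  st <- fused$stations[[1]]
  expect_equal(st$geometry$dim[3], 150L)

  # hand bookkeeping: per-slice means must follow the station constants
  slice_means <- apply(st$signals[["50"]], 3, mean)
  expect_equal(slice_means, rep(consts[2:4, 1], each = 50))

  # voxel-count and intensity conservation (pure rearrangement)
  expect_equal(sum(st$signals[["900"]]),
               sum(vapply(stations[2:4],
                          function(s) sum(s$signals[["900"]]), numeric(1))))

  # single-station include is the identity
  one <- assemble_body_volume(study, include = 3)
  expect_equal(one$stations[[1]]$signals[["50"]],
               stations[[3]]$signals[["50"]])
})

test_that("in-plane mismatched stations are unstackable", {
  g1 <- vol_geometry(c(1.6, 1.6, 5), c(8, 8, 4))
  g2 <- vol_geometry(c(1.6, 1.6, 5), c(10, 10, 4))
  s1 <- dwi_station(list("50" = array(1, c(8, 8, 4)),
                         "900" = array(1, c(8, 8, 4))), g1, 1L)
  s2 <- dwi_station(list("50" = array(1, c(10, 10, 4)),
                         "900" = array(1, c(10, 10, 4))), g2, 2L)
  expect_error(dwi_study(list(s1, s2)), "unstackable")
})

test_that("mask round trip is voxel-exact, including counts and empty masks", {
  g <- vol_geometry(c(1.6, 1.6, 5), c(25, 25, 20))
  dir <- withr::local_tempdir()

  set.seed(42)
  idx <- sample(prod(c(25, 25, 20)), 12345)
  v <- array(FALSE, c(25, 25, 20))
  v[idx] <- TRUE
  m <- mask3d(v, g)
  p <- file.path(dir, "m.nii")
  write_mask(m, p)
  back <- read_mask(p)
  expect_identical(back$voxels, m$voxels)
  expect_identical(mask_count(back), 12345L)
  expect_equal(back$geometry$spacing, g$spacing)

  empty <- mask3d(array(FALSE, c(25, 25, 20)), g)
  write_mask(empty, file.path(dir, "e.nii"))
  expect_identical(mask_count(read_mask(file.path(dir, "e.nii"))), 0L)
})

test_that("reading a nonexistent mask file fails as unusable", {
  expect_error(read_mask(file.path(tempdir(), "no_such_mask.nii")),
               "unusable mask file")
})
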