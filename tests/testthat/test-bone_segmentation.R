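make_computed <- function(vals) {
  computed_dwi(vals, 1000, vol_geometry(c(1.6, 1.6, 5), dim(vals)))
}

test_that("threshold_mask selects exactly the voxels at or above threshold", {
  set.seed(9)
  vals <- array(runif(27, 0, 100), c(3, 3, 3))
  # place exactly 5 voxels above the working threshold of 41
  vals[vals >= 41] <- runif(sum(vals >= 41), 0, 40.9)
  vals[sample(27, 5)] <- runif(5, 41.1, 100)
  cb <- make_computed(vals)
  m <- threshold_mask(cb, 41)
  # brute-force voxel scan
  expect_identical(m$voxels, array(vals >= 41, dim(vals)))
  expect_identical(mask_count(m), 5L)

  expect_identical(mask_count(threshold_mask(cb, 0)), 27L)
  expect_identical(mask_count(threshold_mask(cb, max(vals) + 1)), 0L)
})

test_that("threshold_mask is antitone in the threshold", {
  set.seed(10)
  cb <- make_computed(array(runif(500, 0, 100), c(10, 10, 5)))
  for (t1 in c(10, 30, 60)) {
    m1 <- threshold_mask(cb, t1)
    m2 <- threshold_mask(cb, t1 + 15)
    expect_true(all(m1$voxels | !m2$voxels))  # mask(t2) subset of mask(t1)
  }
})

test_that("full-depth edits remove the ellipse through the whole depth", {
  g <- vol_geometry(c(1.6, 1.6, 5), c(9, 9, 9))
  solid <- mask3d(array(TRUE, c(9, 9, 9)), g)

  # ellipse covering the whole in-plane extent empties the mask
  wipe <- ellipsoid_edit(c(5, 5, 5), c(20, 20, 20),
                         "full_depth_axial_projection")
  expect_identical(mask_count(apply_edit(solid, wipe)), 0L)

  # axial-projection cut of radius 2: brute-force in-ellipse membership,
  # removed through every slice
  e <- ellipsoid_edit(c(5, 5, 5), c(2, 2, 2), "full_depth_axial_projection")
  out <- apply_edit(solid, e)
  removed_expect <- 0L
  for (x in 1:9) for (y in 1:9) {
    if (((x - 5) / 2)^2 + ((y - 5) / 2)^2 <= 1) removed_expect <- removed_expect + 9L
  }
  expect_identical(mask_count(solid) - mask_count(out), removed_expect)

  # coronal and sagittal cuts act along the remaining axes
  for (mode in c("full_depth_coronal_projection",
                 "full_depth_sagittal_projection")) {
    e <- ellipsoid_edit(c(5, 5, 5), c(2, 2, 2), mode)
    out <- apply_edit(solid, e)
    ax <- if (mode == "full_depth_coronal_projection") c(1, 3) else c(2, 3)
    removed_expect <- 0L
    for (u in 1:9) for (w in 1:9) {
      if (((u - 5) / 2)^2 + ((w - 5) / 2)^2 <= 1) removed_expect <- removed_expect + 9L
    }
    expect_identical(mask_count(solid) - mask_count(out), removed_expect)
  }
})

test_that("single-slice edits touch only their slice", {
  g <- vol_geometry(c(1.6, 1.6, 5), c(9, 9, 9))
  solid <- mask3d(array(TRUE, c(9, 9, 9)), g)
  e <- ellipsoid_edit(c(5, 5, 0), c(3, 3, 1), "single_slice", slice_index = 4)
  out <- apply_edit(solid, e)
  expect_true(all(out$voxels[, , -4]))
  expect_lt(sum(out$voxels[, , 4]), 81)
})

test_that("edits are purely subtractive and clip at volume bounds", {
  set.seed(3)
  m <- rand_mask(c(12, 12, 8), p = 0.5)
  e <- ellipsoid_edit(c(11, 11, 0), c(5, 5, 1), "full_depth_axial_projection")
  out <- apply_edit(m, e)
  expect_true(all(m$voxels | !out$voxels))
  expect_lte(mask_count(out), mask_count(m))
})

test_that("edit scripts fold left, are idempotent, and disjoint edits commute", {
  set.seed(21)
  m <- rand_mask(c(16, 16, 10), p = 0.6)
  script <- list(
    ellipsoid_edit(c(4, 4, 0), c(2, 2, 1), "full_depth_axial_projection"),
    ellipsoid_edit(c(12, 12, 0), c(2, 2, 1), "full_depth_axial_projection"),
    ellipsoid_edit(c(8, 8, 0), c(2, 2, 1), "single_slice", slice_index = 5)
  )

  expect_identical(apply_edit_script(m, list())$voxels, m$voxels)

  once <- apply_edit_script(m, script)
  fold <- Reduce(apply_edit, script, accumulate = FALSE, init = m)
  expect_identical(once$voxels, fold$voxels)

  twice <- apply_edit_script(once, script)
  expect_identical(twice$voxels, once$voxels)

  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_identical(apply_edit_script(m, script[perm])$voxels, once$voxels)
  }
})

test_that("edit scripts survive a JSON round trip", {
  script <- list(
    ellipsoid_edit(c(4.5, 4, 1), c(2, 2.5, 1), "full_depth_coronal_projection"),
    ellipsoid_edit(c(8, 8, 3), c(2, 2, 1), "single_slice", slice_index = 3)
  )
  p <- withr::local_tempfile(fileext = ".json")
  write_edit_script(script, p)
  back <- read_edit_script(p)
  expect_equal(back, script)

  set.seed(14)
  m <- rand_mask(c(10, 10, 6), p = 0.5)
  expect_identical(apply_edit_script(m, back)$voxels,
                   apply_edit_script(m, script)$voxels)
})
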