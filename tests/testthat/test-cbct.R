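test_that("DICOM series round-trip preserves intensities and geometry", {
  set.seed(51)
  arr <- array(sample(0:4000, 32 * 24 * 16, replace = TRUE), c(32, 24, 16))
  vol <- voxel_volume(arr, spacing = c(0.25, 0.25, 0.5),
                      origin = c(1, 2, 3))
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir, series_uid = "1.2.3.4")
  back <- read_dicom_series(dir)
  expect_equal(back$data, vol$data, ignore_attr = TRUE)
  expect_equal(back$spacing, vol$spacing)        # anisotropic preserved
  expect_equal(back$origin, vol$origin)
})

test_that("slice order on disk does not affect the reconstructed volume", {
  set.seed(52)
  arr <- array(sample(0:4000, 16^3, replace = TRUE), c(16, 16, 16))
  vol <- voxel_volume(arr, spacing = c(0.3, 0.3, 0.3))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dicom_series(vol, d1, series_uid = "1.2.3.5")
  write_dicom_series(vol, d2, series_uid = "1.2.3.5",
                     instance_order = sample(16))
  v1 <- read_dicom_series(d1)
  v2 <- read_dicom_series(d2)
  expect_equal(v1$data, v2$data)
  expect_equal(v1$origin, v2$origin)
})

test_that("mixed series and missing slices are rejected", {
  arr <- array(0, c(8, 8, 8))
  vol <- voxel_volume(arr, spacing = c(0.5, 0.5, 0.5))
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir, series_uid = "1.2.3.6")
  # drop a middle slice -> irregular spacing
  file.remove(file.path(dir, "slice_0004.dcm"))
  expect_error(read_dicom_series(dir), "missing|irregular")
  # add a slice from another series
  write_dicom_series(voxel_volume(arr[, , 1:2, drop = FALSE],
                                  c(0.5, 0.5, 0.5)),
                     dir, series_uid = "9.9.9.9")
  expect_error(read_dicom_series(dir), "mixed series")
})

test_that("threshold segmentation matches the per-voxel oracle", {
  vol <- voxel_volume(array(500, c(4, 4, 4)), c(1, 1, 1))
  m <- threshold_segment(vol, 400, 700)
  expect_true(all(m$mask))
  expect_warning(m2 <- threshold_segment(vol, 600, 700), "empty")
  expect_false(any(m2$mask))
  expect_true(attr(m2, "empty"))
  expect_error(threshold_segment(vol, 700, 400), "lower")

  set.seed(53)
  arr <- array(sample(0:1000, 6^3, replace = TRUE), c(6, 6, 6))
  rv <- voxel_volume(arr, c(1, 1, 1))
  m3 <- threshold_segment(rv, 250, 750)
  oracle <- sum(vapply(seq_along(arr), function(i)
    arr[i] >= 250 && arr[i] <= 750, logical(1)))
  expect_equal(sum(m3$mask), oracle)
})

test_that("mask subtraction is an exact per-voxel AND NOT", {
  set.seed(54)
  d <- c(5, 5, 5)
  a <- threshold_segment(voxel_volume(array(runif(125), d), c(1, 1, 1)),
                         0.25, 0.8)
  b <- threshold_segment(voxel_volume(array(runif(125), d), c(1, 1, 1)),
                         0.25, 0.8)
  s <- mask_subtract(a, b)
  expect_identical(as.vector(s$mask), as.vector(a$mask & !b$mask))
  # self-subtraction is always empty; disjoint leaves a unchanged
  expect_false(any(mask_subtract(a, a)$mask))
  nb <- b
  nb$mask <- array(FALSE, d)
  expect_identical(mask_subtract(a, nb)$mask, a$mask)
  bad <- b
  bad$mask <- array(FALSE, c(4, 5, 5))
  expect_error(mask_subtract(a, bad), "congruent")
})

test_that("htvc counts voxel centers in boxes with the stated sign", {
  # a solid 10x10x10-voxel cube removed at 0.3 mm spacing: -27 mm^3
  d <- c(20, 20, 20)
  m <- array(FALSE, d)
  m[6:15, 6:15, 6:15] <- TRUE
  change <- structure(list(mask = m, spacing = c(0.3, 0.3, 0.3),
                           origin = c(0, 0, 0), orientation = diag(3),
                           jaw = "maxilla"),
                      class = "roi_mask")
  box <- selection_box(c(-1, -1, -1), c(7, 7, 7))
  got <- htvc(change, box, sign = -1)
  expect_equal(as.numeric(got), -1000 * 0.027 / 1000)   # -0.027 ml
  expect_equal(attr(got, "voxels"), 1000)
  # empty change mask
  change$mask[] <- FALSE
  expect_equal(as.numeric(htvc(change, box)), 0)
  # box fully outside the grid: warning + zero
  far <- selection_box(c(100, 100, 100), c(110, 110, 110))
  expect_warning(z <- htvc(change, far), "outside")
  expect_equal(as.numeric(z), 0)
  # additive over disjoint boxes
  change$mask <- m
  b1 <- selection_box(c(-1, -1, -1), c(2.85, 7, 7))
  b2 <- selection_box(c(2.85001, -1, -1), c(7, 7, 7))
  expect_equal(as.numeric(htvc(change, list(b1, b2))),
               as.numeric(htvc(change, box)))
})

test_that("the removal phantom recovers minus the analytic sphere volume", {
  spec <- cbct_phantom_spec()   # r = 8 mm tooth, 0.25 mm spacing
  ser <- make_cbct_series(spec)
  m0 <- threshold_segment(ser$t0, 550, 3300)
  m2 <- threshold_segment(ser$t2, 550, 3300)
  lost <- mask_subtract(m0, m2)
  ext <- (spec$dims - 1) * spec$spacing
  box <- selection_box(c(0, 0, 0), ext + 0.25)
  got <- as.numeric(htvc(lost, box, sign = -1)) * 1000   # mm^3
  truth <- -ser$truth$removed_volume_mm3
  expect_lt(abs(got - truth) / abs(truth), 0.01)
  # the counted voxels equal the exhaustive sphere-voxel count
  expect_equal(attr(htvc(lost, box), "voxels"), ser$truth$sphere_voxels)
})

test_that("align_jaw is exact for aligned volumes and passes through manual", {
  spec <- cbct_phantom_spec(dims = c(48, 48, 48), spacing = rep(0.5, 3),
                            tooth_radius = 4, noise_sd = 0)
  ser <- make_cbct_series(spec)
  tf <- align_jaw(ser$t0, ser$t0, stride = 2L)
  expect_lt(rotation_angle_deg(tf$rotation), 0.01)
  expect_lt(sqrt(sum(tf$translation^2)), 0.01)

  manual <- rigid_transform(rotation_about_axis(c(0, 0, 1), 3), c(1, 2, 3))
  expect_identical(align_jaw(ser$t0, ser$t0, init = manual, mode = "manual"),
                   manual)
  expect_error(align_jaw(ser$t0, ser$t0, mode = "manual"), "transform")
})

test_that("align_jaw recovers a known 1.5 mm shift within 0.1 mm", {
  spec <- cbct_phantom_spec(dims = c(48, 48, 48), spacing = rep(0.5, 3),
                            tooth_radius = 4)
  ser <- make_cbct_series(spec)
  moved <- ser$t0
  moved$origin <- moved$origin + c(1.5, 0, 0)   # content shifted by +1.5 mm x
  tf <- align_jaw(moved, ser$t0, stride = 2L)
  # mapping moving -> fixed must undo the shift
  err <- apply_transform(rbind(c(10, 10, 10) + c(1.5, 0, 0)), tf) -
    rbind(c(10, 10, 10))
  expect_lt(sqrt(sum(err^2)), 0.1)
})
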