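vol1 <- function(vals, bit_depth = 16L) {
  vmi_volume(array(vals, c(1, 1, length(vals))), c(1, 1, 1),
             bit_depth = bit_depth)
}

test_that("intensity rescaling maps the global range to the full bit range", {
  expect_equal(as.vector(rescale_intensity_3d(vol1(c(10, 30)))$voxels),
               c(0, 65535))
  # midpoint rounds half up: (20-10)/20 * 65535 = 32767.5 -> 32768
  expect_equal(as.vector(rescale_intensity_3d(vol1(c(10, 20, 30)))$voxels),
               c(0, 32768, 65535))
  expect_equal(as.vector(rescale_intensity_3d(vol1(c(7, 7, 7)))$voxels),
               c(0, 0, 0))
  # applied jointly over the 3D volume, not per slice
  v <- vmi_volume(array(c(0, 100, 200, 400), c(2, 1, 2)), c(1, 1, 1))
  r <- rescale_intensity_3d(v)
  expect_equal(range(r$voxels), c(0, 65535))
  expect_equal(r$voxels[2, 1, 1], floor(100 / 400 * 65535 + 0.5))
  # idempotent once at full range
  expect_equal(rescale_intensity_3d(r)$voxels, r$voxels)
})

test_that("slice inversion is an involution with fixed endpoints", {
  v <- vol1(c(0, 12345, 65535))
  iv <- invert_slices(v)
  expect_equal(as.vector(iv$voxels), c(65535, 53190, 0))
  expect_equal(invert_slices(iv)$voxels, v$voxels)
})

test_that("rolling ball removes smooth background, preserves thin ridges", {
  # constant slice -> all zeros
  v <- vmi_volume(array(1234, c(2, 16, 16)), c(1, 1, 1))
  expect_true(all(rolling_ball_subtract(v, 5)$voxels == 0))
  # single bright pixel preserved within 1 count
  sl <- matrix(0, 64, 64)
  sl[32, 32] <- 1000
  out <- rolling_ball_subtract(vmi_volume(array(sl, c(1, 64, 64)),
                                          c(1, 1, 1)), 10)
  expect_lt(abs(out$voxels[1, 32, 32] - 1000), 1)
  # plane ramp + 3-px ridge, radius 20: ramp removed, ridge preserved
  ramp <- outer(seq(0, 2000, length.out = 64), seq(0, 1500, length.out = 64),
                `+`)
  ridge <- matrix(0, 64, 64)
  ridge[, 31:33] <- 5000
  out <- rolling_ball_subtract(vmi_volume(array(ramp + ridge, c(1, 64, 64)),
                                          c(1, 1, 1)), 20)
  # residual background < 2% of ridge height in the interior (the ball
  # cannot see past the image border, so a one-radius margin is excluded)
  expect_lt(max(out$voxels[1, 21:44, setdiff(21:44, 25:39)]), 0.02 * 5000)
  expect_gt(min(out$voxels[1, , 32]), 0.9 * 5000)
  expect_error(rolling_ball_subtract(v, -1), "radius")
})

test_that("rolling ball agrees with the brute-force opening oracle", {
  set.seed(33)
  for (i in 1:6) {
    sl <- matrix(runif(32 * 32, 0, 1000), 32, 32)
    v <- vmi_volume(array(sl, c(1, 32, 32)), c(1, 1, 1))
    r <- sample(c(5, 10, 20), 1)
    got <- sl - rolling_ball_subtract(v, r)$voxels[1, , ]  # background
    expect_lt(max(abs(got - rollball_oracle(sl, r))), 1)
    # invariants: non-negative, bounded by the slice maximum
    sub <- rolling_ball_subtract(v, r)$voxels
    expect_gte(min(sub), 0)
    expect_lte(max(sub), max(sl))
  }
})

test_that("binarize thresholds bimodal volumes and filters specks", {
  vox <- array(0, c(4, 16, 16))
  vox[2:3, 4:9, 4:9] <- 60000
  vox[1, 1, 1:5] <- 60000  # 5-voxel speck
  v <- vmi_volume(vox, c(1, 1, 1))
  p <- segmentation_params(5, min_object_voxels = 10)
  m <- binarize(v, p)
  expect_true(all(m$voxels[2:3, 4:9, 4:9]))
  expect_false(any(m$voxels[1, 1, ]))  # speck removed
  expect_equal(sum(m$voxels), 2 * 36)
  # otsu variant agrees on clean bimodal data
  p2 <- segmentation_params(5, binarization = "otsu", min_object_voxels = 10)
  expect_identical(binarize(v, p2)$voxels, m$voxels)
  # all-zero volume -> empty mask
  z <- vmi_volume(array(0, c(2, 8, 8)), c(1, 1, 1))
  expect_equal(sum(binarize(z, p)$voxels), 0)
})

test_that("cavity masks capture large dark regions only", {
  vox <- array(50000, c(6, 24, 24))
  vox[2:5, 5:14, 5:14] <- 0          # 400-voxel cavity
  vox[1, 20:21, 20:21] <- 0          # 4-voxel pore
  v <- vmi_volume(vox, c(1, 1, 1))
  m <- cavity_mask_from_foreground(v, threshold = 1000,
                                   min_object_voxels = 64)
  expect_true(all(m$voxels[2:5, 5:14, 5:14]))
  expect_false(any(m$voxels[1, , ]))
  expect_equal(sum(m$voxels), 400)
  # uniformly bright volume -> empty
  b <- vmi_volume(array(40000, c(2, 8, 8)), c(1, 1, 1))
  expect_equal(sum(cavity_mask_from_foreground(b, 1000)$voxels), 0)
  expect_error(cavity_mask_from_foreground(v, threshold = 1e7),
               "threshold outside")
})

test_that("exclusion masking removes voxels and reports the fraction", {
  m <- vmi_mask(array(rep(c(TRUE, FALSE), 50), c(4, 5, 5)), c(1, 1, 1))
  none <- vmi_mask(array(FALSE, c(4, 5, 5)), c(1, 1, 1))
  all_ <- vmi_mask(array(TRUE, c(4, 5, 5)), c(1, 1, 1))
  r0 <- apply_exclusion_mask(m, none)
  expect_identical(r0$voxels, m$voxels)
  expect_equal(attr(r0, "excluded_fraction"), 0)
  r1 <- apply_exclusion_mask(m, all_)
  expect_equal(sum(r1$voxels), 0)
  expect_equal(attr(r1, "excluded_fraction"), 1)
  # 100 true voxels, exclude 30 of them
  vox <- array(FALSE, c(4, 5, 10))
  vox[seq_len(100)] <- TRUE
  ex <- array(FALSE, c(4, 5, 10))
  ex[seq_len(30)] <- TRUE
  r <- apply_exclusion_mask(vmi_mask(vox, c(1, 1, 1)),
                            vmi_mask(ex, c(1, 1, 1)))
  expect_equal(sum(r$voxels), 70)
  expect_equal(attr(r, "excluded_fraction"), 0.30)
  expect_error(apply_exclusion_mask(m, vmi_mask(array(TRUE, c(1, 5, 5)),
                                                c(1, 1, 1))), "shape")
})

test_that("segmentation is affine-invariant and dark/bright dual", {
  ph <- make_phantom(small_spec(seed = 11))
  params <- segmentation_params(50)
  m1 <- segment_vasculature(ph$volume, params)
  # global affine intensity change: identical mask
  aff <- vmi_volume(1.5 * ph$volume$voxels + 2000, ph$volume$spacing,
                    ph$volume$channel)
  expect_identical(segment_vasculature(aff, params)$voxels, m1$voxels)
  # dark/bright duality: VMI mode == bright mode on the pre-inverted volume
  pre <- invert_slices(rescale_intensity_3d(ph$volume))
  mb <- segment_vasculature(pre, segmentation_params(50, invert = FALSE))
  expect_identical(mb$voxels, m1$voxels)
  # uniform bright volume -> empty mask
  u <- vmi_volume(array(30000, c(4, 16, 16)), c(1, 1, 1))
  expect_equal(sum(segment_vasculature(u, segmentation_params(5))$voxels), 0)
})

test_that("segment_vasculature supports exclusion and stage dumping", {
  ph <- make_phantom(small_spec(seed = 12))
  ex <- vmi_mask(array(rep(c(TRUE, FALSE), c(32, 32))[
    rep(1:64, each = 64 * 64)] > 0, c(64, 64, 64)), ph$mask$spacing)
  dir <- withr::local_tempdir()
  m <- segment_vasculature(ph$volume, segmentation_params(50), exclude = ex,
                           save_stages = dir)
  expect_false(any(m$voxels & ex$voxels))
  expect_true(length(list.files(dir, "\\.tif$")) >= 5)
  expect_true("exclude" %in% attr(m, "stages"))
})
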