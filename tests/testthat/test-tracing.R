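test_that("skeletonization thins a cylinder to its axis", {
  m <- make_cylinder(nz = 48, radius_vox = 3)
  sk <- skeletonize_mask(m)
  ci <- which(sk$voxels, arr.ind = TRUE)
  expect_gt(nrow(ci), 30)  # ~40-voxel chain, ends may retract slightly
  expect_lte(max(sqrt((ci[, 2] - 8)^2 + (ci[, 3] - 8)^2)), 1)
  # every skeleton voxel inside the mask
  expect_true(all(m$voxels[sk$voxels]))
  expect_error(skeletonize_mask(vmi_mask(array(FALSE, c(2, 2, 2)),
                                         c(1, 1, 1))), "empty")
})

test_that("skeletonization preserves isolated voxels and components", {
  vox <- array(FALSE, c(8, 8, 8))
  vox[4, 4, 4] <- TRUE
  sk <- skeletonize_mask(vmi_mask(vox, c(1, 1, 1)))
  expect_identical(sk$voxels, vox)
  # two disjoint cylinders -> two disjoint chains
  vox2 <- array(FALSE, c(30, 20, 9))
  for (y in 1:20) for (x in 1:9)
    if ((y - 5)^2 + (x - 5)^2 <= 4) vox2[3:27, y, x] <- TRUE
  for (y in 1:20) for (x in 1:9)
    if ((y - 15)^2 + (x - 5)^2 <= 4) vox2[3:27, y, x] <- TRUE
  sk2 <- skeletonize_mask(vmi_mask(vox2, c(1, 1, 1)))
  lab <- vmir:::.label3d_cpp(sk2$voxels, dim(sk2$voxels))
  expect_equal(max(lab), 2)
})

test_that("a straight cylinder traces to one depth-1 branch of known size", {
  m <- make_cylinder(nz = 48, radius_vox = 3, spacing = c(10, 10, 10))
  tr <- build_tree(m)
  bt <- branch_table(tr)
  expect_equal(nrow(bt), 1)
  expect_equal(bt$depth, 1L)
  expect_true(bt$is_terminal)
  expect_lt(abs(bt$mean_diameter_um - 60), 10)  # one voxel-width tolerance
  expect_gt(bt$length_um, 0)
  expect_error(build_tree(vmi_mask(array(FALSE, c(2, 2, 2)), c(1, 1, 1))),
               "empty")
  expect_error(build_tree(m, prune_below = -5), "prune_below")
})

test_that("a Y-shaped mask traces to a trunk and two terminal limbs", {
  spec <- phantom_spec(shape = c(64, 64, 64), spacing = c(10, 10, 10),
                       levels = 2, root_diameter = 60, tortuosity = 0,
                       noise_sd = 0, illumination_amplitude = 0, seed = 5)
  tree <- generate_tree(spec)
  ras <- rasterize_tree(tree, spec)
  tr <- build_tree(ras$mask)
  bt <- branch_table(tr)
  expect_equal(nrow(bt), 3)
  expect_equal(sort(bt$depth), c(1L, 2L, 2L))
  expect_equal(bt$is_terminal, bt$depth == 2L)
  # depth law on every parent-child pair
  for (i in which(!is.na(bt$parent_id)))
    expect_equal(bt$depth[i],
                 bt$depth[match(bt$parent_id[i], bt$id)] + 1L)
})

test_that("traced centerline points lie inside the input mask", {
  ph <- make_phantom(small_spec(seed = 13, noise_sd = 0))
  tr <- build_tree(ph$mask)
  sp <- ph$mask$spacing
  for (cl in tr$centerlines) {
    ijk <- cbind(ceiling(cl[, 1] / sp[1]), ceiling(cl[, 2] / sp[2]),
                 ceiling(cl[, 3] / sp[3]))
    expect_true(all(ph$mask$voxels[ijk]))
  }
})

test_that("increasing the prune length never increases the branch count", {
  ph <- make_phantom(small_spec(seed = 14))
  seg <- segment_vasculature(ph$volume, segmentation_params(50))
  counts <- vapply(c(0, 40, 100, 250, 600), function(p)
    nrow(branch_table(build_tree(seg, prune_below = p))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("re-tracing a rasterized phantom recovers the generating tree", {
  # branch count within +-10%, per-depth mean diameter within +-15%
  for (s in 1:5) {
    ph <- make_phantom(phantom_spec(seed = s))
    tr <- build_tree(ph$mask)
    bt <- branch_table(tr)
    gt <- branch_table(ph$tree)
    expect_lte(abs(nrow(bt) - nrow(gt)) / nrow(gt), 0.10)
    for (k in sort(unique(gt$depth))) {
      got <- mean(bt$mean_diameter_um[bt$depth == k])
      want <- mean(gt$mean_diameter_um[gt$depth == k])
      expect_lt(abs(got - want) / want, 0.15)
    }
  }
})

test_that("anisotropic masks are resampled to isotropic before thinning", {
  # same cylinder, half the z sampling: identical physical answer
  m <- make_cylinder(nz = 24, radius_vox = 3, z0 = 3, z1 = 22,
                     spacing = c(20, 10, 10))
  tr <- build_tree(m)
  bt <- branch_table(tr)
  expect_equal(nrow(bt), 1)
  expect_lt(abs(bt$mean_diameter_um - 60), 12)
})

test_that("branch tables round-trip through CSV at 6 significant digits", {
  ph <- make_phantom(small_spec(seed = 15, noise_sd = 0))
  tr <- build_tree(ph$mask)
  p <- file.path(withr::local_tempdir(), "br.csv")
  write_branch_table(tr, p)
  back <- branch_table(read_branch_table(p))
  ref <- branch_table(tr)
  expect_equal(back$id, ref$id)
  expect_equal(back$depth, ref$depth)
  expect_equal(back$mean_diameter_um, ref$mean_diameter_um,
               tolerance = 1e-6)
  expect_equal(back$length_um, ref$length_um, tolerance = 1e-6)
})

test_that("SWC export and import preserve the branch structure", {
  ph <- make_phantom(small_spec(seed = 16, noise_sd = 0))
  tr <- build_tree(ph$mask)
  p <- file.path(withr::local_tempdir(), "tree.swc")
  write_swc(tr, p)
  back <- read_swc(p, spacing = tr$spacing)
  bt <- branch_table(tr)
  bb <- branch_table(back)
  expect_equal(nrow(bb), nrow(bt))
  expect_equal(sort(bb$depth), sort(bt$depth))
  expect_equal(sort(bb$mean_diameter_um), sort(bt$mean_diameter_um),
               tolerance = 0.05)
  expect_equal(sort(bb$length_um), sort(bt$length_um), tolerance = 0.05)
  # generated trees round-trip too
  p2 <- file.path(withr::local_tempdir(), "gen.swc")
  write_swc(ph$tree, p2)
  gb <- branch_table(read_swc(p2))
  expect_equal(nrow(gb), nrow(ph$tree$branches))
  expect_equal(sort(gb$depth), sort(ph$tree$branches$depth))
})
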