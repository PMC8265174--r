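test_that("phantom specs enforce their invariants", {
  expect_error(phantom_spec(vessel_intensity = 40000,
                            foreground_intensity = 30000), "dark")
  expect_error(phantom_spec(asymmetry = 1), "asymmetry")
  expect_error(phantom_spec(levels = 0), "levels")
  expect_error(phantom_spec(illumination_amplitude = 1.2), "illumination")
  expect_error(phantom_spec(spacing = c(0, 1, 1)), "spacing")
})

test_that("tree generation follows the branching rule exactly", {
  # levels = 1: a single unbranched root
  t1 <- generate_tree(small_spec(levels = 1, seed = 2))
  expect_equal(nrow(t1$branches), 1)
  expect_true(t1$branches$is_terminal)
  # symmetric Murray split: d = D / 2^(1/3)
  t2 <- generate_tree(phantom_spec(shape = c(96, 96, 96), levels = 2,
                                   root_diameter = 40, seed = 3))
  kids <- t2$branches[!is.na(t2$branches$parent_id), ]
  expect_equal(kids$mean_diameter_um, rep(40 / 2^(1 / 3), 2))
  # generative Murray compliance at every bifurcation, any asymmetry
  sp <- phantom_spec(shape = c(192, 192, 192), levels = 4, asymmetry = 0.25,
                     murray_exponent = 3, seed = 4)
  tr <- generate_tree(sp)
  br <- tr$branches
  for (p in br$id[!br$is_terminal]) {
    D <- br$mean_diameter_um[br$id == p]
    ds <- br$mean_diameter_um[!is.na(br$parent_id) & br$parent_id == p]
    expect_lt(abs(sum(ds^3) - D^3), 1e-9 * D^3)
  }
  # the thinner daughter is (1 - asymmetry) times the thicker one
  for (p in br$id[!br$is_terminal]) {
    ds <- sort(br$mean_diameter_um[!is.na(br$parent_id) & br$parent_id == p])
    expect_equal(ds[1] / ds[2], 1 - 0.25)
  }
})

test_that("phantoms are bit-reproducible for identical spec and seed", {
  s <- small_spec(seed = 21)
  a <- make_phantom(s)
  b <- make_phantom(s)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
  expect_identical(a$tree$branches, b$tree$branches)
  # generation does not disturb the caller's RNG stream
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(make_phantom(s))
  expect_identical(runif(1), before)
})

test_that("rasterization realizes the stated imaging model", {
  clean <- small_spec(seed = 22, noise_sd = 0, illumination_amplitude = 0)
  ph <- make_phantom(clean)
  # noise- and illumination-free: exactly two intensities
  expect_setequal(unique(as.vector(ph$volume$voxels)),
                  c(clean$foreground_intensity, clean$vessel_intensity))
  # mask is true exactly where the image is darker than the foreground
  expect_identical(ph$mask$voxels,
                   array(ph$volume$voxels < clean$foreground_intensity,
                         dim(ph$volume$voxels)))
  # same tree, different seeds: intensities differ, mask identical
  s1 <- small_spec(seed = 23)
  s2 <- small_spec(seed = 24)
  tree <- generate_tree(s1)
  r1 <- rasterize_tree(tree, s1)
  r2 <- rasterize_tree(tree, s2)
  expect_false(identical(r1$volume$voxels, r2$volume$voxels))
  expect_identical(r1$mask$voxels, r2$mask$voxels)
})

test_that("rasterized single-branch volume matches the analytic capsule", {
  sp <- phantom_spec(levels = 1, seed = 25, root_diameter = 100,
                     tortuosity = 0, noise_sd = 0,
                     illumination_amplitude = 0)
  ph <- make_phantom(sp)
  L <- ph$tree$branches$length_um
  r <- ph$tree$branches$mean_diameter_um / 2
  analytic <- (pi * r^2 * L + 4 / 3 * pi * r^3) / prod(sp$spacing)
  expect_lt(abs(sum(ph$mask$voxels) - analytic) / analytic, 0.05)
})

test_that("pipeline difficulty is monotone in the noise level", {
  noise <- c(500, 2000, 5000)
  mean_dice <- vapply(noise, function(ns) {
    mean(vapply(1:5, function(s) {
      ph <- make_phantom(small_spec(seed = s, noise_sd = ns))
      seg <- segment_vasculature(ph$volume, segmentation_params(50))
      dice(seg, ph$mask)$dice
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dice) <= 0))
})

test_that("make_phantom trees satisfy the Murray identity end to end", {
  # terminals must spread over depths for the regression to be defined
  sp <- phantom_spec(levels = 5, asymmetry = 0.3, min_diameter = 20,
                     seed = 26)
  ph <- make_phantom(sp)
  f <- murray_fit(murray_depth_sums(ph$tree, TRUE), TRUE)
  expect_gte(f$slope, 0.99)
  expect_lte(f$slope, 1.01)
})
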