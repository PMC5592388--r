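test_that("vesselness thresholding is strictly greater-than", {
  g <- vol_grid(c(3, 3, 1))
  v <- vesselness_volume(array(c(0, 0.6, 0.601, 0.75, 0.7501, 0.749, 1, 0.2,
                                 0.75), c(3, 3, 1)), g)
  m75 <- threshold_vesselness(v, 0.75)
  expect_identical(sum(m75$values), 2L)            # 0.7501 and 1 only
  expect_false(m75$values[1, 2, 1])                # exactly 0.75 excluded
  m60 <- threshold_vesselness(v, 0.60)
  expect_false(m60$values[2, 1, 1])                # exactly 0.60 excluded
  expect_true(m60$values[3, 1, 1])                 # 0.601 included
  expect_identical(sum(threshold_vesselness(
    vesselness_volume(array(0, c(3, 3, 1)), g), 0.5)$values), 0L)
  expect_error(threshold_vesselness(v, 1), "\\(0, 1\\)")
})

test_that("in-plane dilation stamps a Euclidean disk and stays in-slice", {
  m <- array(FALSE, c(9, 9, 3)); m[5, 5, 2] <- TRUE
  d <- dilate_in_plane(binary_mask(m), 2)
  # exactly the 13 integer offsets with dx^2 + dy^2 <= 4
  expect_identical(sum(d$values[, , 2]), 13L)
  idx <- which(d$values[, , 2], arr.ind = TRUE) - 5L
  expect_true(all(idx[, 1]^2 + idx[, 2]^2 <= 4))
  expect_identical(sum(d$values[, , c(1, 3)]), 0L)

  # radius 0 is the identity
  expect_identical(dilate_in_plane(binary_mask(m), 0)$values, m)

  # monotone: the dilation contains the mask, counts grow with radius
  set.seed(8)
  r <- binary_mask(array(runif(9 * 9 * 3) > 0.9, c(9, 9, 3)))
  d1 <- dilate_in_plane(r, 1); d2 <- dilate_in_plane(r, 2)
  expect_true(all(d1$values[r$values]))
  expect_true(all(d2$values[d1$values]))
  # dilating a dilation contains the single larger dilation
  d12 <- dilate_in_plane(d1, 2)
  expect_true(all(d12$values[d2$values]))
})

test_that("two voxels on the clinical MRA grid measure 0.82 mm", {
  mra_inplane <- 210 / 512
  expect_equal(2 * mra_inplane, 0.82, tolerance = 0.005)
})

test_that("arterial mask localizes the artery, spares the vein, reruns identically", {
  ph <- generate_phantom(two_tube_spec(seed = 7L))
  swi_grid <- ph$swi$grid
  mask <- build_arterial_mask(ph$tof, swi_grid, ph$truth$misalignment)

  # covers nearly all true artery voxels after dilation
  am <- ph$truth$artery_mask$values
  expect_gt(sum(mask$values & am) / sum(am), 0.95)

  # true vein voxels barely touched (vein is far from the artery)
  vm <- ph$truth$vein_mask$values
  expect_lt(sum(mask$values & vm) / sum(vm), 0.02)

  # deterministic: an identical rerun is bit-identical
  again <- build_arterial_mask(ph$tof, swi_grid, ph$truth$misalignment)
  expect_identical(mask$values, again$values)

  # no arteries -> empty mask
  ph0 <- generate_phantom(phantom_spec(
    tubes = list(tube_line(c(60, 28, 28), c(62, 80, 28), 1.3, "vein")),
    swi_shape = c(44, 44, 20), swi_spacing = c(2.4, 2.4, 2.8),
    mra_shape = c(48, 48, 20), mra_spacing = c(1.9, 1.9, 1.7),
    mra_origin = c(6, 6, 4), m1_slice = 6L, seed = 9L))
  m0 <- build_arterial_mask(ph0$tof, ph0$swi$grid, rigid_transform())
  expect_identical(sum(m0$values), 0L)
})

test_that("fallback brain mask recovers the ellipsoid and rejects constants", {
  ph <- generate_phantom(two_tube_spec(seed = 17L))
  fb <- fallback_brain_mask(ph$swi)
  tb <- ph$truth$brain_mask$values
  dice <- 2 * sum(fb$values & tb) / (sum(fb$values) + sum(tb))
  expect_gt(dice, 0.95)

  # single connected component by construction
  lab <- swiven:::label_components_3d(fb$values)
  expect_identical(length(unique(lab[lab > 0])), 1L)

  expect_error(fallback_brain_mask(intensity_volume(array(3, c(6, 6, 6)))),
               "variation")
})
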