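test_that("NIfTI write/read round-trips values, affine and spacing", {
  grid <- vol_grid(c(8, 7, 6), c(0.82, 0.82, 2.0))
  set.seed(11)
  vol <- intensity_volume(array(rnorm(8 * 7 * 6, 100, 20), c(8, 7, 6)), grid)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_equal(back$values, vol$values, tolerance = 1e-6)
  expect_lt(max(abs(back$grid$affine - grid$affine)), 1e-5)
  expect_equal(back$grid$spacing[3], 2.0, tolerance = 1e-6)

  # constant volume round trip is exact
  cvol <- intensity_volume(array(7, c(6, 6, 6)))
  write_volume(cvol, f)
  expect_true(all(read_volume(f)$values == 7))

  # masks go through uint8 and come back after thresholding
  m <- binary_mask(array(runif(6^3) > 0.6, c(6, 6, 6)),
                   vol_grid(c(6, 6, 6), c(1, 1, 2)))
  write_volume(m, f)
  expect_identical(read_mask(f)$values, m$values)
})

test_that("read_volume rejects missing, non-3D and non-finite inputs", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "no such file")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img4 <- RNifti::asNifti(array(0, c(4, 4, 4, 2)))
  RNifti::writeNifti(img4, f)
  expect_error(read_volume(f), "4D")
  imgn <- RNifti::asNifti(array(c(NaN, rep(1, 63)), c(4, 4, 4)))
  RNifti::writeNifti(imgn, f)
  expect_error(read_volume(f), "non-finite")
})

test_that("domain types enforce their invariants", {
  expect_error(vol_grid(c(4, 4), c(1, 1, 1)), "3 positive integers")
  expect_error(vol_grid(c(4, 4, 4), c(1, -1, 1)), "positive")
  expect_error(vol_grid(c(4, 4, 4), affine = matrix(0, 4, 4)), "singular")
  expect_error(intensity_volume(array(c(Inf, rep(0, 7)), c(2, 2, 2))),
               "non-finite")
  expect_error(intensity_volume(matrix(0, 3, 3)), "3D")
  g <- vol_grid(c(4, 4, 4), c(0.5, 0.5, 2))
  expect_lt(max(abs(sqrt(colSums(g$affine[1:3, 1:3]^2)) - g$spacing)), 1e-6)
  expect_error(vesselness_volume(array(1.5, c(3, 3, 3))), "\\[0, 1\\]")
})

test_that("resampling: identity, exact one-voxel shift, value-set preservation", {
  grid <- vol_grid(c(10, 9, 8), c(1.5, 2, 2.5))
  set.seed(21)
  vol <- intensity_volume(array(rnorm(720), c(10, 9, 8)), grid)

  same <- resample_to_grid(vol, grid, rigid_transform(), "linear")
  expect_equal(same$values, vol$values, tolerance = 1e-12)

  # translating by exactly one voxel along axis 1 shifts the lattice
  shift <- rigid_transform(translation = c(grid$spacing[1], 0, 0))
  out <- resample_to_grid(vol, grid, shift, "linear")
  expect_equal(out$values[2:10, , ], vol$values[1:9, , ], tolerance = 1e-9)

  # nearest-neighbour keeps the input's value set under a generic motion
  m <- binary_mask(array(runif(720) > 0.7, c(10, 9, 8)), grid)
  rot <- rigid_transform(angles = c(0.03, -0.02, 0.05),
                         translation = c(0.7, -0.4, 1.1),
                         center = c(7, 8, 9))
  res <- resample_to_grid(m, grid, rot, "nearest")
  expect_true(all(res$values %in% c(0, 1)))

  # linear interpolation never leaves the source range
  res2 <- resample_to_grid(vol, grid, rot, "linear")
  expect_gte(min(res2$values), min(min(vol$values), 0))
  expect_lte(max(res2$values), max(max(vol$values), 0))
})

test_that("rigid transforms compose, invert and serialize exactly", {
  t1 <- rigid_transform(c(0.1, -0.05, 0.2), c(3, -2, 1), center = c(10, 20, 5))
  inv <- rigid_invert(t1)
  expect_lt(max(abs(rigid_matrix(rigid_compose(t1, inv)) - diag(4))), 1e-8)
  expect_lt(max(abs(rigid_matrix(rigid_compose(inv, t1)) - diag(4))), 1e-8)

  back <- rigid_from_matrix(rigid_matrix(t1), center = c(10, 20, 5))
  expect_equal(back$angles, t1$angles, tolerance = 1e-10)
  expect_equal(back$translation, t1$translation, tolerance = 1e-10)

  f <- withr::local_tempfile(fileext = ".txt")
  write_transform(t1, f)
  expect_lt(max(abs(rigid_matrix(read_transform(f)) - rigid_matrix(t1))), 1e-9)
  expect_error(rigid_from_matrix(diag(c(2, 1, 1, 1))), "rigid")
})
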