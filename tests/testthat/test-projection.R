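test_that("window length follows thickness / slice spacing", {
  expect_identical(swiven:::window_length(16, 2.0), 8L)   # the default slab
  expect_identical(swiven:::window_length(16, 2.8), 6L)
  expect_error(swiven:::window_length(1, 4), "shorter")
})

test_that("sliding mIP equals the brute-force window minimum", {
  # the single-column example: [9,7,8,3,9,9,9,9] with a 4-slice window
  col <- c(9, 7, 8, 3, 9, 9, 9, 9)
  vol <- intensity_volume(array(rep(col, each = 1), c(1, 1, 8)),
                          vol_grid(c(1, 1, 8), c(1, 1, 4)))
  mip <- sliding_mip(vol, projection_params(thickness = 16))
  expect_equal(as.numeric(mip$values), c(3, 3, 3, 3, 9, 9, 9, 9))

  # random volumes against the per-voxel oracle, exact
  set.seed(61)
  for (i in 1:5) {
    arr <- array(rnorm(8 * 8 * 16, 100, 20), c(8, 8, 16))
    w <- sample(2:8, 1)
    vol <- intensity_volume(arr, vol_grid(c(8, 8, 16), c(1, 1, 2)))
    got <- sliding_mip(vol, projection_params(thickness = 2 * w))
    want <- oracle_masked_mip(arr, array(FALSE, dim(arr)), w, NA)
    expect_identical(got$values, want)
  }

  # constant volume: projection changes nothing; w = 1 is the identity
  cv <- intensity_volume(array(4, c(5, 5, 9)))
  expect_equal(sliding_mip(cv, projection_params(thickness = 6))$values,
               cv$values)
  rv <- intensity_volume(array(rnorm(5 * 5 * 9), c(5, 5, 9)))
  expect_identical(sliding_mip(rv, projection_params(thickness = 1))$values,
                   rv$values)
  expect_error(sliding_mip(rv, projection_params(thickness = 20)), "longer")
})

test_that("masked mIP excludes arteries before projecting and fills full windows", {
  # [9,7,8,3] with the 3 masked: the window minimum becomes 7
  arr <- array(c(9, 7, 8, 3), c(1, 1, 4))
  g <- vol_grid(c(1, 1, 4), c(1, 1, 4))
  mask <- array(FALSE, c(1, 1, 4)); mask[1, 1, 4] <- TRUE
  out <- masked_sliding_mip(intensity_volume(arr, g), binary_mask(mask, g),
                            projection_params(thickness = 16))
  expect_equal(out$values[1, 1, 1], 7)

  # an empty mask reproduces the plain mIP
  set.seed(62)
  arr <- array(rnorm(6 * 6 * 12, 50, 10), c(6, 6, 12))
  g <- vol_grid(c(6, 6, 12), c(1, 1, 2))
  vol <- intensity_volume(arr, g)
  empty <- binary_mask(array(FALSE, dim(arr)), g)
  expect_identical(masked_sliding_mip(vol, empty)$values,
                   sliding_mip(vol)$values)

  # fully masked window columns take the 99th-percentile fill value
  # (floored at the raw window minimum, so exclusion never darkens)
  full <- binary_mask(array(TRUE, dim(arr)), g)
  filled <- masked_sliding_mip(vol, full)
  fill <- as.numeric(quantile(arr, 0.99, names = FALSE))
  expect_gte(min(filled$values), fill)
  expect_equal(filled$values[1, 1, 1], fill)   # a deep window uses the fill
  plain <- sliding_mip(vol)
  expect_true(all(filled$values >= plain$values))
})

test_that("masked mIP equals its oracle and dominates the unmasked mIP", {
  set.seed(63)
  for (i in 1:5) {
    arr <- array(rnorm(8 * 8 * 16, 100, 20), c(8, 8, 16))
    mask <- array(runif(length(arr)) < 0.25, dim(arr))
    g <- vol_grid(c(8, 8, 16), c(1, 1, 2))
    w <- sample(c(4L, 8L), 1)
    params <- projection_params(thickness = 2 * w)
    got <- masked_sliding_mip(intensity_volume(arr, g), binary_mask(mask, g),
                              params)
    fill <- as.numeric(quantile(arr, 0.99, names = FALSE))
    expect_identical(got$values, oracle_masked_mip(arr, mask, w, fill))
    # removing candidates from a minimum can only raise it
    plain <- sliding_mip(intensity_volume(arr, g), params)
    expect_true(all(got$values >= plain$values))
  }
})

test_that("brain-restricted projection ignores the dark surround", {
  # dark background below/around a bright slab: without the brain mask the
  # window minimum leaks the surround; with it, it cannot
  arr <- array(10, c(6, 6, 10))
  arr[, , 3:8] <- 100
  brain <- array(FALSE, c(6, 6, 10)); brain[, , 3:8] <- TRUE
  g <- vol_grid(c(6, 6, 10), c(1, 1, 2))
  mip <- sliding_mip(intensity_volume(arr, g), projection_params(16),
                     binary_mask(brain, g))
  expect_true(all(mip$values[, , 3:8] == 100))
})
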