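test_that("Hessian responses are exact on constants and quadratics", {
  h0 <- hessian_2d(matrix(5, 20, 20), 2)
  expect_equal(max(abs(h0$dxx), abs(h0$dxy), abs(h0$dyy)), 0,
               tolerance = 1e-12)

  # v(x, y) = x^2 has dxx = 2 sigma^2 (scale-normalized), dyy = dxy = 0
  img <- outer(0:40, rep(1, 41))^2
  for (sigma in c(1, 1.5, 2.5)) {
    h <- hessian_2d(img, sigma)
    expect_equal(h$dxx[21, 21], 2 * sigma^2, tolerance = 1e-9)
    expect_lt(abs(h$dyy[21, 21]), 1e-9)
    expect_lt(abs(h$dxy[21, 21]), 1e-9)
  }

  # transposing the image swaps dxx/dyy and transposes dxy
  set.seed(5)
  a <- matrix(rnorm(30 * 24), 30, 24)
  h1 <- hessian_2d(a, 1.5)
  h2 <- hessian_2d(t(a), 1.5)
  expect_equal(h1$dxx, t(h2$dyy), tolerance = 1e-12)
  expect_equal(h1$dxy, t(h2$dxy), tolerance = 1e-12)

  expect_error(hessian_2d(a, -1), "sigma")
  expect_error(hessian_2d(matrix(0, 3, 3), 1), "5 pixels")
})

test_that("frangi_slice implements the polarity rule and the dark-bar response", {
  p <- frangi_params(scales = 1.5, polarity = "dark")
  expect_true(all(frangi_slice(matrix(42, 16, 16), p) == 0))

  # bright ridge fails the dark-polarity sign test on its crest
  bright <- matrix(100, 41, 41); bright[20:22, ] <- 150
  v <- frangi_slice(bright, p)
  expect_true(all(v[21, ] == 0))
  # and is picked up once the polarity is flipped
  vb <- frangi_slice(bright, frangi_params(scales = 1.5, polarity = "bright"))
  expect_true(all(vb[21, 5:37] > 0.4))

  # dark bar: brute-force oracle agreement at 1e-10, centerline response
  bar <- matrix(100, 41, 41); bar[20:22, ] <- 50
  got <- frangi_slice(bar, p)
  want <- oracle_frangi_slice(bar, 0.5, 20, 1.5, "dark")
  expect_lt(max(abs(got - want)), 1e-10)
  expect_true(all(got[21, 5:37] > 0.5))
  expect_true(all(got[21, 5:37] == want[21, 5:37]))
})

test_that("vesselness matches the brute-force oracle on random slices", {
  set.seed(99)
  for (i in 1:4) {
    img <- matrix(rnorm(32 * 32, 100, 25), 32, 32)
    pol <- if (i %% 2 == 0) "dark" else "bright"
    scales <- list(1, c(1, 2), 1.5, c(1.5, 2.5))[[i]]
    got <- frangi_slice(img, frangi_params(scales = scales, polarity = pol))
    want <- oracle_frangi_slice(img, 0.5, 20, scales, pol)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("vesselness properties: range, scale maximum, offset invariance", {
  set.seed(12)
  img <- matrix(rnorm(40 * 40, 100, 20), 40, 40)
  p <- frangi_params(scales = c(1, 1.5, 2))
  v <- frangi_slice(img, p)
  expect_gte(min(v), 0)
  expect_lte(max(v), 1)

  # multiscale output is the pointwise maximum over single scales
  singles <- lapply(p$scales, function(s) {
    frangi_slice(img, frangi_params(scales = s))
  })
  expect_equal(v, Reduce(pmax, singles), tolerance = 1e-14)

  # adding a constant leaves the Hessian, hence the vesselness, unchanged
  expect_equal(frangi_slice(img + 500, p), v, tolerance = 1e-9)

  expect_error(frangi_params(beta = 0), "beta")
  expect_error(frangi_params(scales = numeric()), "scales")
})

test_that("vesselness_3d is slice-wise and discriminates a dark tube", {
  # stacking identical slices gives identical vesselness slices
  set.seed(3)
  sl <- matrix(rnorm(20 * 20, 100, 15), 20, 20)
  vol <- intensity_volume(array(rep(sl, 3), c(20, 20, 3)))
  v3 <- vesselness_3d(vol, frangi_params(scales = 1.5))
  expect_equal(v3$values[, , 1], v3$values[, , 3], tolerance = 1e-14)
  expect_equal(v3$values[, , 1], frangi_slice(sl, frangi_params(scales = 1.5)),
               tolerance = 1e-14)

  # constant volume stays zero
  expect_true(all(vesselness_3d(intensity_volume(array(9, c(8, 8, 4))),
                                frangi_params())$values == 0))

  # a dark in-plane bar scores higher on the bar than off it
  arr <- array(130, c(30, 30, 4))
  arr[14:16, , ] <- 40
  noisy <- arr + array(rnorm(length(arr), 0, 4), dim(arr))
  v <- vesselness_3d(intensity_volume(noisy), frangi_params(polarity = "dark"))
  on_tube <- v$values[15, , ]
  off_tube <- v$values[c(5, 25), , ]
  expect_gt(mean(on_tube), mean(off_tube) + 0.3)

  expect_error(vesselness_3d(intensity_volume(array(0, c(8, 8, 2))),
                             frangi_params(), slice_axis = 4), "axis")
})
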