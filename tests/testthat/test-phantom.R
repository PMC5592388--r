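test_that("tube rasterization matches analytic cylinder volume", {
  # straight axis-aligned cylinder: 1.5 mm radius, 40 mm long, 0.5 mm grid
  g <- vol_grid(c(100, 24, 24), c(0.5, 0.5, 0.5))
  tube <- tube_line(c(5, 6, 6), c(45, 6, 6), 1.5, "vein")
  m <- rasterize_tube(tube, g)
  vol_count <- sum(m$values) * prod(g$spacing)
  # the rasterized solid is a capsule: cylinder plus hemispherical end caps
  capsule <- pi * 1.5^2 * 40 + 4 / 3 * pi * 1.5^3
  expect_lt(abs(vol_count - capsule) / capsule, 0.05)

  # sub-voxel radius: legal, possibly empty, never an error
  tiny <- rasterize_tube(tube_line(c(5, 6.25, 6.25), c(45, 6.25, 6.25),
                                   0.2, "vein"), g)
  expect_true(sum(tiny$values) >= 0)

  # disjoint tubes: the union count is the sum of the parts
  t1 <- tube_line(c(5, 4, 4), c(45, 4, 4), 1, "vein")
  t2 <- tube_line(c(5, 9, 9), c(45, 9, 9), 1, "vein")
  m1 <- rasterize_tube(t1, g); m2 <- rasterize_tube(t2, g)
  expect_identical(sum(m1$values | m2$values), sum(m1$values) + sum(m2$values))

  expect_error(tube_line(c(0, 0, 0), c(0, 0, 0), 1), "degenerate")
  expect_error(tube_helix(c(0, 0, 0), c(0, 0, 1), 5, 10, c(1, 1), 1),
               "degenerate")
})

test_that("phantom generation is exact without noise and seeded with it", {
  spec0 <- two_tube_spec(seed = 3L)
  spec0$noise_sd <- 0
  ph <- generate_phantom(spec0)
  lv <- spec0$levels
  # piecewise-constant levels away from structure boundaries
  expect_equal(ph$swi$values[2, 2, 2], lv$swi_background)
  ctr <- round(swiven:::world_to_voxel(ph$swi$grid,
                                       matrix(c(52.5, 52.5, 40), 1))) + 1
  expect_equal(ph$swi$values[ctr[1], ctr[2], ctr[3]], lv$swi_brain)
  expect_true(all(ph$swi$values[ph$truth$vein_mask$values] < lv$swi_brain))
  expect_equal(ph$tof$values[2, 2, 2], lv$tof_background)

  # identical spec + seed regenerate bit-identically; truth ignores noise
  spec <- two_tube_spec(seed = 5L)
  a <- generate_phantom(spec); b <- generate_phantom(spec)
  expect_identical(a$swi$values, b$swi$values)
  expect_identical(a$tof$values, b$tof$values)
  spec2 <- two_tube_spec(seed = 6L)
  c2 <- generate_phantom(spec2)
  expect_false(identical(a$swi$values, c2$swi$values))
  expect_identical(a$truth$vein_mask$values, c2$truth$vein_mask$values)
  expect_identical(a$truth$nvvv_true, c2$truth$nvvv_true)

  # truth NVVV is exactly the voxel-count ratio above M1
  sl <- (spec$m1_slice + 1):spec$swi_shape[3]
  nv <- sum(a$truth$vein_mask$values[, , sl] &
              a$truth$brain_mask$values[, , sl])
  nb <- sum(a$truth$brain_mask$values[, , sl])
  expect_identical(a$truth$nvvv_true, nv / nb)
  expect_true(a$truth$contamination_true > 0)    # has one dark artery
})

test_that("phantom spec validates intensity ordering", {
  lv <- list(swi_background = 10, swi_brain = 130, swi_vein = 150,
             swi_dark_artery = 40, swi_ventricle = 170,
             tof_background = 10, tof_brain = 60, tof_artery = 220,
             tof_ventricle = 25)
  expect_error(phantom_spec(levels = lv), "darker than brain")
  lv$swi_vein <- 40; lv$tof_artery <- 5
  expect_error(phantom_spec(levels = lv), "brighter than background")
})

test_that("the preset suite spans contamination 0 to above 0.5, reproducibly", {
  ps <- preset_suite()
  expect_gte(length(ps), 4L)
  truths <- vapply(ps, function(s) generate_phantom(s)$truth$contamination_true,
                   numeric(1))
  expect_equal(unname(truths["score0"]), 0)
  expect_gte(max(truths), 0.5)
  # the mid preset sits near the one-third cohort figure
  expect_gt(truths[["score2"]], 0.25)
  expect_lt(truths[["score2"]], 0.45)
  expect_true(all(diff(truths) > 0))

  # regeneration is bit-identical
  p1 <- generate_phantom(ps$score1); p2 <- generate_phantom(ps$score1)
  expect_identical(p1$swi$values, p2$swi$values)
  expect_identical(p1$tof$values, p2$tof$values)
})

test_that("phantoms round-trip to disk with truth sidecar", {
  ph <- generate_phantom(two_tube_spec(seed = 13L))
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  expect_true(all(file.exists(file.path(dir,
    c("swi.nii.gz", "tof.nii.gz", "brain_mask.nii.gz", "vein_mask.nii.gz",
      "artery_mask.nii.gz", "misalignment.txt", "truth.json")))))
  swi <- read_volume(file.path(dir, "swi.nii.gz"))
  expect_equal(swi$values, ph$swi$values, tolerance = 1e-5)
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(truth$nvvv_true, ph$truth$nvvv_true, tolerance = 1e-12)
})
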