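#' Parametric tube specifications for phantom vasculature
#'
#' Tubes are defined by a centerline in world millimetres plus a radius.
#' Straight segments model cortical veins; helices (an arc is a helix with
#' zero pitch) emulate the tortuous course of cerebral arteries. Each tube
#' belongs to the vein or artery channel; an artery can additionally be
#' flagged `swi_dark` to model failed flow compensation, in which case it
#' appears hypointense on the SWI as well as bright on the TOF.
#'
#' @param p0,p1 segment endpoints (mm, length-3).
#' @param radius tube radius in mm (> 0).
#' @param channel `"vein"` or `"artery"`.
#' @param swi_dark logical; arteries only — does this artery contaminate
#'   the SWI?
#' @return An object of class `tube_spec`.
#' @export
tube_line <- function(p0, p1, radius, channel = c("vein", "artery"),
                      swi_dark = FALSE) {
  channel <- match.arg(channel)
  if (radius <= 0) stop("radius must be > 0")
  if (sum((p1 - p0)^2) == 0) stop("degenerate tube: zero length")
  structure(list(kind = "line", p0 = as.numeric(p0), p1 = as.numeric(p1),
                 radius = radius, channel = channel, swi_dark = swi_dark),
            class = "tube_spec")
}

#' @rdname tube_line
#' @param center helix axis point (mm).
#' @param axis helix axis direction (length-3, need not be unit).
#' @param turn_radius radius of the helical winding (mm).
#' @param pitch advance along the axis per full turn (mm; 0 gives a planar
#'   circular arc).
#' @param theta angular range in radians, length-2 `c(from, to)`.
#' @export
tube_helix <- function(center, axis, turn_radius, pitch, theta, radius,
                       channel = c("vein", "artery"), swi_dark = FALSE) {
  channel <- match.arg(channel)
  if (radius <= 0 || turn_radius <= 0) stop("radii must be > 0")
  if (diff(theta) == 0) stop("degenerate tube: zero angular extent")
  structure(list(kind = "helix", center = as.numeric(center),
                 axis = as.numeric(axis) / sqrt(sum(axis^2)),
                 turn_radius = turn_radius, pitch = pitch,
                 theta = as.numeric(theta), radius = radius,
                 channel = channel, swi_dark = swi_dark),
            class = "tube_spec")
}

# Dense centerline samples at approximately `step` mm arclength spacing.
tube_points <- function(tube, step) {
  if (tube$kind == "line") {
    len <- sqrt(sum((tube$p1 - tube$p0)^2))
    n <- max(2L, ceiling(len / step) + 1L)
    tt <- seq(0, 1, length.out = n)
    cbind(tube$p0[1] + tt * (tube$p1[1] - tube$p0[1]),
          tube$p0[2] + tt * (tube$p1[2] - tube$p0[2]),
          tube$p0[3] + tt * (tube$p1[3] - tube$p0[3]))
  } else {
    a <- tube$axis
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * a) * a
    u <- u / sqrt(sum(u^2))
    v <- c(a[2] * u[3] - a[3] * u[2],
           a[3] * u[1] - a[1] * u[3],
           a[1] * u[2] - a[2] * u[1])
    speed <- sqrt(tube$turn_radius^2 + (tube$pitch / (2 * pi))^2)
    arclen <- speed * abs(diff(tube$theta))
    n <- max(2L, ceiling(arclen / step) + 1L)
    th <- seq(tube$theta[1], tube$theta[2], length.out = n)
    r <- tube$turn_radius
    adv <- tube$pitch * th / (2 * pi)
    cbind(tube$center[1] + r * cos(th) * u[1] + r * sin(th) * v[1] + adv * a[1],
          tube$center[2] + r * cos(th) * u[2] + r * sin(th) * v[2] + adv * a[2],
          tube$center[3] + r * cos(th) * u[3] + r * sin(th) * v[3] + adv * a[3])
  }
}

# Mark voxels whose centre lies within `radius` mm of any sample point.
rasterize_points <- function(pts, radius, grid) {
  mask <- array(FALSE, dim = grid$shape)
  sp <- grid$spacing
  vox <- world_to_voxel(grid, pts)
  for (s in seq_len(nrow(pts))) {
    c0 <- vox[s, ]
    lo <- pmax(0, floor(c0 - radius / sp))
    hi <- pmin(grid$shape - 1, ceiling(c0 + radius / sp))
    if (any(lo > hi)) next
    g <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    w <- voxel_to_world(grid, g)
    d2 <- (w[, 1] - pts[s, 1])^2 + (w[, 2] - pts[s, 2])^2 +
          (w[, 3] - pts[s, 3])^2
    sel <- d2 <= radius^2
    if (any(sel)) {
      lin <- 1 + g[sel, 1] + grid$shape[1] * (g[sel, 2] + grid$shape[2] * g[sel, 3])
      mask[lin] <- TRUE
    }
  }
  binary_mask(mask, grid)
}

#' Rasterize a tube onto a grid
#'
#' Voxels whose centre lies within the tube radius of the centerline
#' (distance evaluated in world mm against a dense centerline sampling at
#' half the minimum voxel spacing).
#'
#' @param tube a [tube_spec].
#' @param grid a [vol_grid].
#' @return A [binary_mask]; may be empty if the radius is well below the
#'   voxel size.
#' @export
rasterize_tube <- function(tube, grid) {
  stopifnot(inherits(tube, "tube_spec"))
  step <- min(grid$spacing) / 2
  rasterize_points(tube_points(tube, step), tube$radius, grid)
}

#' Phantom specification
#'
#' Defines paired synthetic SWI / TOF volumes: a bright brain ellipsoid on
#' a dark surround in the SWI channel with dark (hypointense) veins and
#' optionally dark contaminating arteries; a dark background with
#' partially saturated brain tissue and bright arteries in the TOF
#' channel, rendered after a known rigid misalignment. Intensities live on
#' a 0-255-like scale so that the default Frangi `c = 20` operates in a
#' sensible regime. Grid spacings echo a clinical protocol (2.0 mm SWI
#' slices, 0.8 mm MRA slices) at a desk-scale matrix.
#'
#' @param tubes list of [tube_spec]s.
#' @param swi_shape,swi_spacing SWI grid (defaults 64 x 64 x 28 at
#'   1.64 x 1.64 x 2.0 mm).
#' @param mra_shape,mra_spacing,mra_origin MRA grid (defaults 112 x 112 x 40
#'   at 0.82 x 0.82 x 0.8 mm, offset to cover the brain centre).
#' @param brain_center,brain_semiaxes brain ellipsoid in mm. The default
#'   in-plane semiaxes are unequal, as in real head anatomy; a rotationally
#'   symmetric phantom would leave the in-plane rotation of a registration
#'   problem unidentifiable.
#' @param ventricles list of internal ellipsoids (each a list with
#'   `center` and `semiaxes`, mm) emulating the lateral ventricles: CSF is
#'   bright on T2*-weighted SWI and dark on TOF, providing interior
#'   landmarks for registration.
#' @param levels named list of intensity levels: `swi_background`,
#'   `swi_brain`, `swi_vein`, `swi_dark_artery`, `swi_ventricle`,
#'   `tof_background`, `tof_brain`, `tof_artery`, `tof_ventricle`.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param misalignment [rigid_transform] mapping MRA world into SWI world
#'   (the transform a registration should recover).
#' @param m1_slice 1-based SWI slice index of the M1 plane.
#' @param seed integer seed controlling the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(tubes = list(),
                         swi_shape = c(64, 64, 28),
                         swi_spacing = c(1.64, 1.64, 2.0),
                         mra_shape = c(112, 112, 40),
                         mra_spacing = c(0.82, 0.82, 0.8),
                         mra_origin = c(7, 7, 6),
                         brain_center = c(52.5, 52.5, 27),
                         brain_semiaxes = c(45, 38, 24),
                         ventricles = list(
                           list(center = c(44, 50, 26), semiaxes = c(6, 14, 8)),
                           list(center = c(61, 50, 26), semiaxes = c(6, 14, 8))),
                         levels = list(swi_background = 10, swi_brain = 130,
                                       swi_vein = 40, swi_dark_artery = 40,
                                       swi_ventricle = 170,
                                       tof_background = 10, tof_brain = 60,
                                       tof_artery = 220, tof_ventricle = 25),
                         noise_sd = 4, misalignment = rigid_transform(),
                         m1_slice = 8L, seed = 1L) {
  if (levels$swi_vein >= levels$swi_brain ||
      levels$swi_dark_artery >= levels$swi_brain) {
    stop("SWI vein / dark-artery levels must be darker than brain")
  }
  if (levels$tof_artery <= levels$tof_background) {
    stop("TOF artery level must be brighter than background")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(tubes = tubes, swi_shape = as.integer(swi_shape),
                 swi_spacing = as.numeric(swi_spacing),
                 mra_shape = as.integer(mra_shape),
                 mra_spacing = as.numeric(mra_spacing),
                 mra_origin = as.numeric(mra_origin),
                 brain_center = as.numeric(brain_center),
                 brain_semiaxes = as.numeric(brain_semiaxes),
                 ventricles = ventricles,
                 levels = levels, noise_sd = noise_sd,
                 misalignment = misalignment,
                 m1_slice = as.integer(m1_slice), seed = as.integer(seed)),
            class = "phantom_spec")
}

swi_grid_of <- function(spec) vol_grid(spec$swi_shape, spec$swi_spacing)

mra_grid_of <- function(spec) {
  aff <- diag(c(spec$mra_spacing, 1))
  aff[1:3, 4] <- spec$mra_origin
  vol_grid(spec$mra_shape, affine = aff)
}

# 2x supersampled companion grid: fine voxel centres subdivide each coarse
# voxel into 2x2x2 octants.
supersample_grid <- function(grid) {
  aff <- grid$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] / 2
  aff[1:3, 4] <- aff[1:3, 4] - as.numeric(grid$affine[1:3, 1:3] %*% rep(0.25, 3))
  vol_grid(grid$shape * 2L, affine = aff)
}

# Box-average 2x2x2 blocks (inverse of supersample_grid), giving fractional
# occupancy / partial-volume softened intensities.
downsample2 <- function(v) {
  d <- dim(v)
  v <- (v[seq(1, d[1], 2), , , drop = FALSE] +
        v[seq(2, d[1], 2), , , drop = FALSE]) / 2
  v <- (v[, seq(1, d[2], 2), , drop = FALSE] +
        v[, seq(2, d[2], 2), , drop = FALSE]) / 2
  (v[, , seq(1, d[3], 2), drop = FALSE] +
   v[, , seq(2, d[3], 2), drop = FALSE]) / 2
}

# combined occupancy of the ventricle ellipsoids at given fine-grid points
ventricle_occupancy <- function(ventricles, world, fine_shape) {
  acc <- rep(FALSE, nrow(world))
  for (v in ventricles) {
    acc <- acc | ellipsoid_inside(world, v$center, v$semiaxes)
  }
  downsample2(array(as.double(acc), dim = fine_shape))
}

ellipsoid_inside <- function(world, center, semiaxes) {
  ((world[, 1] - center[1]) / semiaxes[1])^2 +
  ((world[, 2] - center[2]) / semiaxes[2])^2 +
  ((world[, 3] - center[3]) / semiaxes[3])^2 <= 1
}

# union occupancy of a set of tubes on the 2x supersampled grid, box-downsampled
tube_occupancy <- function(tubes, grid, transform_pts = NULL) {
  fine <- supersample_grid(grid)
  acc <- array(FALSE, dim = fine$shape)
  step <- min(fine$spacing) / 2
  for (tube in tubes) {
    pts <- tube_points(tube, step)
    if (!is.null(transform_pts)) pts <- transform_pts(pts)
    acc <- acc | rasterize_points(pts, tube$radius, fine)$values
  }
  downsample2(array(as.double(acc), dim = fine$shape))
}

run_seeded <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a paired SWI / TOF phantom with exact ground truth
#'
#' Renders the SWI on its own grid and the TOF on the (differently spaced)
#' MRA grid after applying the specified rigid misalignment. Tube
#' boundaries are rendered with partial volume via 2x supersampled
#' rasterization and box-downsampling, so vessels have soft edges like
#' real data; Gaussian noise of the stated SD is then added (seeded, so
#' identical specs regenerate bit-identically). Truth masks are noise-free
#' voxel-centre rasterizations on the SWI grid in perfectly aligned space.
#'
#' @param spec a [phantom_spec].
#' @return A list with `swi`, `tof` ([intensity_volume]s) and `truth`, a
#'   list holding `brain_mask`, `vein_mask`, `artery_mask` (all arteries),
#'   `dark_artery_mask`, the exact `nvvv_true` (veins only, the ideal
#'   corrected value), `unvvv_true` (veins plus dark arteries),
#'   `contamination_true`, `misalignment` and `m1_slice`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lv <- spec$levels
  sg <- swi_grid_of(spec)
  mg <- mra_grid_of(spec)
  veins <- Filter(function(t) t$channel == "vein", spec$tubes)
  arteries <- Filter(function(t) t$channel == "artery", spec$tubes)
  dark_arteries <- Filter(function(t) isTRUE(t$swi_dark), arteries)

  # ---- SWI channel (aligned world) ----
  fine_s <- supersample_grid(sg)
  wf <- voxel_to_world(fine_s, all_voxels(fine_s))
  occ_brain <- downsample2(array(
    as.double(ellipsoid_inside(wf, spec$brain_center, spec$brain_semiaxes)),
    dim = fine_s$shape))
  occ_vent <- ventricle_occupancy(spec$ventricles, wf, fine_s$shape)
  occ_vein <- tube_occupancy(veins, sg)
  occ_dark <- tube_occupancy(dark_arteries, sg)
  swi <- lv$swi_background + (lv$swi_brain - lv$swi_background) * occ_brain
  swi <- swi * (1 - occ_vent) + lv$swi_ventricle * occ_vent
  swi <- swi * (1 - occ_vein) + lv$swi_vein * occ_vein
  swi <- swi * (1 - occ_dark) + lv$swi_dark_artery * occ_dark

  # ---- TOF channel (rendered through the misalignment) ----
  mis <- rigid_matrix(spec$misalignment)
  mis_inv <- solve(mis)
  fine_m <- supersample_grid(mg)
  wm <- voxel_to_world(fine_m, all_voxels(fine_m))
  # voxel at MRA world y shows the scene at A(y)
  scene <- sweep(wm %*% t(mis[1:3, 1:3]), 2L, mis[1:3, 4], "+")
  occ_brain_t <- downsample2(array(
    as.double(ellipsoid_inside(scene, spec$brain_center, spec$brain_semiaxes)),
    dim = fine_m$shape))
  pull_back <- function(pts) {
    sweep(pts %*% t(mis_inv[1:3, 1:3]), 2L, mis_inv[1:3, 4], "+")
  }
  occ_vent_t <- ventricle_occupancy(spec$ventricles, scene, fine_m$shape)
  occ_art_t <- tube_occupancy(arteries, mg, transform_pts = pull_back)
  tof <- lv$tof_background + (lv$tof_brain - lv$tof_background) * occ_brain_t
  tof <- tof * (1 - occ_vent_t) + lv$tof_ventricle * occ_vent_t
  tof <- tof * (1 - occ_art_t) + lv$tof_artery * occ_art_t

  if (spec$noise_sd > 0) {
    swi <- swi + run_seeded(spec$seed,
                            array(stats::rnorm(length(swi), 0, spec$noise_sd),
                                  dim = dim(swi)))
    tof <- tof + run_seeded(spec$seed + 1L,
                            array(stats::rnorm(length(tof), 0, spec$noise_sd),
                                  dim = dim(tof)))
  }

  # ---- exact truth on the SWI grid ----
  union_mask <- function(tubes) {
    m <- array(FALSE, dim = sg$shape)
    for (tube in tubes) m <- m | rasterize_tube(tube, sg)$values
    binary_mask(m, sg)
  }
  wc <- voxel_to_world(sg, all_voxels(sg))
  brain_mask <- binary_mask(
    array(ellipsoid_inside(wc, spec$brain_center, spec$brain_semiaxes),
          dim = sg$shape), sg)
  vein_mask <- union_mask(veins)
  artery_mask <- union_mask(arteries)
  dark_mask <- union_mask(dark_arteries)

  sl <- (spec$m1_slice + 1L):sg$shape[3]
  nb <- sum(brain_mask$values[, , sl])
  nv <- sum(vein_mask$values[, , sl] & brain_mask$values[, , sl])
  nu <- sum((vein_mask$values[, , sl] | dark_mask$values[, , sl]) &
              brain_mask$values[, , sl])
  nvvv_true <- nv / nb
  unvvv_true <- nu / nb
  contamination_true <- if (nu > 0) (nu - nv) / nu else 0

  list(swi = intensity_volume(swi, sg),
       tof = intensity_volume(tof, mg),
       truth = list(brain_mask = brain_mask, vein_mask = vein_mask,
                    artery_mask = artery_mask, dark_artery_mask = dark_mask,
                    nvvv_true = nvvv_true, unvvv_true = unvvv_true,
                    contamination_true = contamination_true,
                    misalignment = spec$misalignment,
                    m1_slice = spec$m1_slice))
}

# Shared vasculature of the preset suite: six parasagittal cortical-style
# veins above the M1 plane (running anteroposteriorly, as veins draining
# toward the midline do) and two large basal arteries below it
# (TOF-bright only). Veins and the lateral contaminating arteries occupy
# disjoint in-plane territories so projected structures rarely cross —
# mirroring real anatomy, where Sylvian arteries are lateral to the
# pericallosal venous territory.
preset_base_tubes <- function() {
  list(
    tube_line(c(37, 26, 20), c(39, 78, 20), 1.2, "vein"),
    tube_line(c(44, 24, 24), c(42, 80, 24), 1.2, "vein"),
    tube_line(c(51, 22, 28), c(53, 84, 28), 1.3, "vein"),
    tube_line(c(58, 24, 32), c(56, 80, 32), 1.2, "vein"),
    tube_line(c(65, 26, 36), c(67, 78, 36), 1.2, "vein"),
    tube_line(c(70, 32, 40), c(68, 74, 40), 1.1, "vein"),
    tube_line(c(30, 52, 8), c(76, 52, 8), 1.6, "artery"),
    tube_line(c(52, 32, 10), c(52, 74, 10), 1.5, "artery")
  )
}

# Tortuous SWI-dark arteries (helices winding about an anteroposterior
# axis) used to dose the contamination. They run in the lateral
# (Sylvian-level) bands left and right of the venous territory, at
# mid-superior height: their clearance above the M1 plane exceeds the
# 16 mm slab, so the sliding projection does not smear their replicas
# below the quantification cut.
contaminating_arteries <- function() {
  list(
    tube_helix(c(29, 52, 30), c(0, 1, 0), turn_radius = 4.5, pitch = 40,
               theta = c(-1.4, 1.4) * pi, radius = 1.5, channel = "artery",
               swi_dark = TRUE),
    tube_helix(c(76, 52, 30), c(0, 1, 0), turn_radius = 4.5, pitch = 38,
               theta = c(-1.4, 1.4) * pi, radius = 1.5,
               channel = "artery", swi_dark = TRUE),
    tube_helix(c(30, 50, 33), c(0.15, 1, 0), turn_radius = 4, pitch = 34,
               theta = c(-1.2, 1.2) * pi, radius = 1.7, channel = "artery",
               swi_dark = TRUE),
    tube_helix(c(75, 54, 27), c(-0.15, 1, 0), turn_radius = 4, pitch = 36,
               theta = c(-1.2, 1.2) * pi, radius = 1.7, channel = "artery",
               swi_dark = TRUE)
  )
}


#' Reproducible phantom presets of increasing arterial contamination
#'
#' Four presets mirroring a qualitative 0-III contamination grading: no
#' SWI-dark arteries ("score0"), then one to four tortuous dark arteries
#' above the M1 plane ("score1"-"score3"), spanning true contamination
#' fractions from 0 to above 0.5. Each preset carries a fixed seed and
#' regenerates bit-identically.
#'
#' @return Named list of [phantom_spec]s.
#' @export
preset_suite <- function() {
  base <- preset_base_tubes()
  cont <- contaminating_arteries()
  mis <- rigid_transform(angles = c(0, 0, 2 * pi / 180),
                         translation = c(3, -2, 1),
                         center = c(52.5, 52.5, 27))
  list(
    score0 = phantom_spec(tubes = base, misalignment = mis, seed = 101L),
    score1 = phantom_spec(tubes = c(base, cont[1]), misalignment = mis,
                          seed = 102L),
    score2 = phantom_spec(tubes = c(base, cont[1:2]), misalignment = mis,
                          seed = 103L),
    score3 = phantom_spec(tubes = c(base, cont), misalignment = mis,
                          seed = 104L)
  )
}

#' Write a phantom to disk (volumes as NIfTI, truth as JSON + masks)
#'
#' @param ph result of [generate_phantom].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(ph$swi, file.path(dir, "swi.nii.gz"))
  write_volume(ph$tof, file.path(dir, "tof.nii.gz"))
  write_volume(ph$truth$brain_mask, file.path(dir, "brain_mask.nii.gz"))
  write_volume(ph$truth$vein_mask, file.path(dir, "vein_mask.nii.gz"))
  write_volume(ph$truth$artery_mask, file.path(dir, "artery_mask.nii.gz"))
  write_transform(ph$truth$misalignment, file.path(dir, "misalignment.txt"))
  truth <- ph$truth[c("nvvv_true", "unvvv_true", "contamination_true",
                      "m1_slice")]
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "truth.json"))
  invisible(dir)
}
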