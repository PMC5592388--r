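#' Arterial masking parameters
#'
#' @param artery_threshold vesselness probability above which (strictly) an
#'   MRA voxel counts as artery; default 0.75.
#' @param dilation_radius in-plane dilation radius in voxels on the MRA
#'   grid (non-negative integer; default 2, i.e. 0.82 mm at a 210/512 mm
#'   in-plane spacing). Dilation absorbs partial-volume rims and small
#'   residual misregistration.
#' @param vein_threshold vesselness probability above which (strictly) an
#'   mIP SWI voxel counts as vein; default 0.60.
#' @return An object of class `masking_params`.
#' @export
masking_params <- function(artery_threshold = 0.75, dilation_radius = 2L,
                           vein_threshold = 0.60) {
  if (artery_threshold <= 0 || artery_threshold >= 1 ||
      vein_threshold <= 0 || vein_threshold >= 1) {
    stop("thresholds must lie in (0, 1)")
  }
  dilation_radius <- as.integer(dilation_radius)
  if (dilation_radius < 0L) stop("dilation_radius must be >= 0")
  structure(list(artery_threshold = artery_threshold,
                 dilation_radius = dilation_radius,
                 vein_threshold = vein_threshold),
            class = "masking_params")
}

#' Threshold a vesselness volume into a binary mask
#'
#' Voxels are kept where vesselness strictly exceeds the threshold (a voxel
#' at exactly the threshold is excluded).
#'
#' @param v a [vesselness_volume] (or [intensity_volume]).
#' @param threshold probability threshold in (0, 1).
#' @return A [binary_mask] on `v`'s grid.
#' @export
threshold_vesselness <- function(v, threshold) {
  stopifnot(inherits(v, "intensity_volume"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  binary_mask(v$values > threshold, v$grid)
}

# Integer in-plane offsets of a Euclidean disk of the given radius.
disk_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

#' In-plane (slice-wise) binary dilation
#'
#' Morphological dilation with a Euclidean disk structuring element
#' (`dx^2 + dy^2 <= r^2`), applied independently to every axial slice;
#' the mask never grows across slices.
#'
#' @param mask a [binary_mask].
#' @param radius disk radius in voxels (non-negative integer).
#' @return The dilated [binary_mask].
#' @export
dilate_in_plane <- function(mask, radius) {
  stopifnot(inherits(mask, "binary_mask"))
  radius <- as.integer(radius)
  if (radius < 0L) stop("radius must be >= 0")
  if (radius == 0L || !any(mask$values)) return(mask)
  d <- dim(mask$values)
  out <- mask$values
  off <- disk_offsets(radius)
  for (i in seq_len(nrow(off))) {
    dx <- off$dx[i]; dy <- off$dy[i]
    if (dx == 0L && dy == 0L) next
    xs <- max(1, 1 - dx):min(d[1], d[1] - dx)
    ys <- max(1, 1 - dy):min(d[2], d[2] - dy)
    out[xs + dx, ys + dy, ] <- out[xs + dx, ys + dy, , drop = FALSE] |
      mask$values[xs, ys, , drop = FALSE]
  }
  binary_mask(out, mask$grid)
}

#' Build the dilated arterial mask on the SWI grid
#'
#' The full arterial localization chain: bright-polarity Frangi vesselness
#' of the MRA, strict thresholding (default > 0.75), in-plane dilation on
#' the native MRA grid (where "2 voxels" has its stated physical size),
#' then nearest-neighbour resampling through the rigid transform onto the
#' SWI grid and re-binarization. Deterministic given its inputs.
#'
#' @param mra the TOF MRA [intensity_volume].
#' @param swi_grid the target [vol_grid] (the SWI grid).
#' @param transform [rigid_transform] mapping MRA world into SWI world.
#' @param params a [masking_params].
#' @param frangi a [frangi_params]; its polarity is forced to `"bright"`.
#' @return A [binary_mask] on `swi_grid`.
#' @export
build_arterial_mask <- function(mra, swi_grid, transform = rigid_transform(),
                                params = masking_params(),
                                frangi = frangi_params(polarity = "bright")) {
  frangi$polarity <- "bright"
  v <- vesselness_3d(mra, frangi)
  m <- threshold_vesselness(v, params$artery_threshold)
  m <- dilate_in_plane(m, params$dilation_radius)
  res <- resample_to_grid(m, swi_grid, transform, "nearest")
  binary_mask(res$values > 0.5, swi_grid)
}

# Global Otsu threshold (maximizes between-class variance of a histogram).
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) <= 0) stop("image has no intensity variation")
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  centers <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins)
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  centers[which.max(bcv)]
}

# 6-connected components by vectorized label propagation (min over
# neighbours until fixed point); labels are linear indices of seeds.
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0, dim = d)
  lab[mask] <- which(mask)
  shift_min <- function(l) {
    m <- l
    for (ax in 1:3) {
      if (d[ax] < 2L) next
      lo <- slice_shift(l, ax, 1L)
      hi <- slice_shift(l, ax, -1L)
      m <- pmin_pos(m, lo)
      m <- pmin_pos(m, hi)
    }
    m[!mask] <- 0
    m
  }
  repeat {
    new <- shift_min(lab)
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# shift array along axis by s (propagating neighbour values), pad with 0
slice_shift <- function(a, ax, s) {
  d <- dim(a)
  out <- array(0, dim = d)
  n <- d[ax]
  if (abs(s) >= n) return(out)
  src <- if (s > 0) 1:(n - s) else (1 - s):n
  dst <- src + s
  si <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  di <- si
  si[[ax]] <- src; di[[ax]] <- dst
  out[di[[1]], di[[2]], di[[3]]] <- a[si[[1]], si[[2]], si[[3]]]
  out
}

# elementwise min ignoring zeros in either argument
pmin_pos <- function(a, b) {
  r <- a
  take <- b > 0 & (a == 0 | b < a)
  r[take] <- b[take]
  r
}

# spacing-aware 3D ball dilation (radius in mm)
dilate_ball_3d <- function(values, radius_mm, spacing) {
  r <- floor(radius_mm / spacing)
  off <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  keep <- (off$dx * spacing[1])^2 + (off$dy * spacing[2])^2 +
          (off$dz * spacing[3])^2 <= radius_mm^2
  off <- off[keep, , drop = FALSE]
  out <- values
  for (i in seq_len(nrow(off))) {
    if (off$dx[i] == 0 && off$dy[i] == 0 && off$dz[i] == 0) next
    s <- values
    for (ax in 1:3) {
      d <- c(off$dx[i], off$dy[i], off$dz[i])[ax]
      if (d != 0) s <- slice_shift(s, ax, d) > 0
    }
    out <- out | s
  }
  out
}

close_ball_3d <- function(values, radius_mm, spacing) {
  !dilate_ball_3d(!dilate_ball_3d(values, radius_mm, spacing),
                  radius_mm, spacing)
}

#' Fallback brain mask for phantom-grade data
#'
#' Global Otsu threshold on intensity, followed by extraction of the
#' largest 6-connected foreground component, morphological closing (3 mm
#' ball) to seal dark vessels reaching the surface, and filling of
#' interior holes (background not reachable from the volume border). This
#' is a simple intensity-based extraction adequate for the
#' bright-brain-on-dark phantoms generated by this package; it is NOT a
#' substitute for a proper skull-stripping tool (e.g. BET) on clinical
#' data — supply an external brain mask there.
#'
#' @param vol an [intensity_volume].
#' @param close_mm closing ball radius in mm (default 3).
#' @return A [binary_mask] covering the brain.
#' @export
fallback_brain_mask <- function(vol, close_mm = 3) {
  stopifnot(inherits(vol, "intensity_volume"))
  thr <- otsu_threshold(as.numeric(vol$values))
  fg <- vol$values > thr
  if (!any(fg)) stop("no foreground voxels above the Otsu threshold")
  lab <- label_components_3d(fg)
  labs <- lab[lab > 0]
  keep <- as.integer(names(which.max(table(labs))))
  comp <- lab == keep
  if (close_mm > 0) comp <- close_ball_3d(comp, close_mm, vol$grid$spacing)
  # fill holes: background connected to the border stays background
  bg <- !comp
  border_seed <- array(FALSE, dim = dim(bg))
  border_seed[1, , ] <- TRUE; border_seed[dim(bg)[1], , ] <- TRUE
  border_seed[, 1, ] <- TRUE; border_seed[, dim(bg)[2], ] <- TRUE
  border_seed[, , 1] <- TRUE; border_seed[, , dim(bg)[3]] <- TRUE
  reach <- flood_from(bg, border_seed & bg)
  filled <- comp | (bg & !reach)
  binary_mask(filled, vol$grid)
}

# 6-connected flood fill: grow seeds within region until fixed point
flood_from <- function(region, seeds) {
  cur <- seeds
  repeat {
    grown <- cur
    for (ax in 1:3) {
      if (dim(region)[ax] < 2L) next
      grown <- grown | slice_shift(cur, ax, 1L) > 0
      grown <- grown | slice_shift(cur, ax, -1L) > 0
    }
    grown <- grown & region
    if (identical(grown, cur)) break
    cur <- grown
  }
  cur
}
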