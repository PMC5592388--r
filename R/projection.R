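#' Sliding projection parameters
#'
#' @param thickness slab thickness in mm (default 16). The window length in
#'   slices is `round(thickness / slice_spacing)` (so 8 slices at a 2.0 mm
#'   slice spacing) and must be >= 1.
#' @param axis projection axis (default 3, the slice axis).
#' @param fill_quantile quantile of in-brain intensities used as the
#'   hyperintense fill value when a projection column is entirely
#'   artery-masked (default 0.99).
#' @return An object of class `projection_params`.
#' @export
projection_params <- function(thickness = 16, axis = 3L, fill_quantile = 0.99) {
  if (thickness <= 0) stop("thickness must be > 0")
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  if (fill_quantile <= 0 || fill_quantile > 1) {
    stop("fill_quantile must lie in (0, 1]")
  }
  structure(list(thickness = thickness, axis = as.integer(axis),
                 fill_quantile = fill_quantile),
            class = "projection_params")
}

window_length <- function(thickness, spacing) {
  w <- as.integer(round(thickness / spacing))
  if (w < 1L) stop("projection window shorter than one slice")
  w
}

# minimum over sliding leading-anchored windows along axis 3;
# trailing windows are truncated at the volume edge.
sliding_min_axis3 <- function(v, w) {
  d <- dim(v)
  out <- v
  if (w <= 1L) return(out)
  for (j in seq_len(w - 1L)) {
    n <- d[3] - j
    if (n < 1L) break
    out[, , 1:n] <- pmin(out[, , 1:n, drop = FALSE],
                         v[, , (1 + j):d[3], drop = FALSE])
  }
  out
}

# shared worker: sliding window minimum with voxel exclusion and
# hyperintense fill for windows left empty
project_excluding <- function(vol, exclude, params, brain) {
  ax <- params$axis
  w <- window_length(params$thickness, vol$grid$spacing[ax])
  if (w > vol$grid$shape[ax]) {
    stop(sprintf("projection window (%d slices) longer than volume (%d slices)",
                 w, vol$grid$shape[ax]))
  }
  inside <- if (is.null(brain)) rep(TRUE, length(vol$values)) else brain$values
  fill <- as.numeric(stats::quantile(vol$values[inside], params$fill_quantile,
                                     names = FALSE))
  v <- vol$values
  v[exclude] <- Inf  # excluded from every window minimum
  if (ax != 3L) v <- aperm(v, c(setdiff(1:3, ax), ax))
  out <- sliding_min_axis3(v, w)
  filled <- is.infinite(out)
  if (any(filled)) {
    # windows with every voxel excluded take the hyperintense fill value,
    # floored at the raw window minimum so that exclusion can never darken
    # a voxel below its unmasked projection
    raw <- vol$values
    if (ax != 3L) raw <- aperm(raw, c(setdiff(1:3, ax), ax))
    base <- sliding_min_axis3(raw, w)
    out[filled] <- pmax(fill, base[filled])
  }
  if (ax != 3L) out <- aperm(out, order(c(setdiff(1:3, ax), ax)))
  intensity_volume(out, vol$grid)
}

#' Sliding minimum intensity projection (mIP)
#'
#' Output slice `k` is the voxelwise minimum over input slices
#' `k .. k+w-1`, where `w = round(thickness / slice spacing)`; the window
#' is anchored at its leading slice and truncated at the superior edge, so
#' the output has as many slices as the input. When a brain mask is given
#' (brain extraction precedes the venographic analysis), only in-brain
#' voxels enter the minimum — otherwise the dark surround leaks into
#' windows that cross the brain edge and reads as spurious vessels.
#'
#' @param vol the SWI [intensity_volume].
#' @param params a [projection_params].
#' @param brain optional [binary_mask] on `vol`'s grid.
#' @return The mIP [intensity_volume] on `vol`'s grid.
#' @export
sliding_mip <- function(vol, params = projection_params(), brain = NULL) {
  stopifnot(inherits(vol, "intensity_volume"))
  exclude <- if (is.null(brain)) {
    array(FALSE, dim = vol$grid$shape)
  } else {
    if (!grids_equal(vol$grid, brain$grid)) {
      stop("brain mask must live on the SWI grid")
    }
    !brain$values
  }
  project_excluding(vol, exclude, params, brain)
}

#' Arterial-masked sliding mIP
#'
#' Identical to [sliding_mip] except that artery-masked voxels are excluded
#' from each window's minimum *in the original SWI space, before
#' projection* (masking the projected image instead would also erase veins
#' hidden behind arteries in the slab). Where a window is entirely masked —
#' an artery running parallel to the slab — the output is set to a
#' hyperintense fill value: the `fill_quantile` quantile (default 99th) of
#' in-brain SWI intensities, bright enough never to re-read as a dark
#' vessel.
#'
#' @param vol the SWI [intensity_volume].
#' @param artery a [binary_mask] of arterial voxels on `vol`'s grid.
#' @param params a [projection_params].
#' @param brain optional [binary_mask] defining "in-brain" for the fill
#'   value; defaults to all voxels.
#' @return The corrected mIP [intensity_volume].
#' @export
masked_sliding_mip <- function(vol, artery, params = projection_params(),
                               brain = NULL) {
  stopifnot(inherits(vol, "intensity_volume"), inherits(artery, "binary_mask"))
  if (!grids_equal(vol$grid, artery$grid)) {
    stop("artery mask must live on the SWI grid")
  }
  exclude <- artery$values
  if (!is.null(brain)) {
    if (!grids_equal(vol$grid, brain$grid)) {
      stop("brain mask must live on the SWI grid")
    }
    exclude <- exclude | !brain$values
  }
  project_excluding(vol, exclude, params, brain)
}
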