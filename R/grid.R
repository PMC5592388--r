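#' Volume grid geometry
#'
#' A `vol_grid` describes the sampling lattice of a 3D image: the number of
#' voxels per axis, the voxel spacing in millimetres, and the 4x4
#' voxel-to-world affine in the NIfTI convention (0-based voxel indices;
#' world coordinates in mm). All geometric computation in this package is
#' done in world millimetres so that grids with different spacings (e.g. an
#' SWI grid and a finer MRA grid) interoperate.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing numeric vector of length 3, mm per voxel. Ignored if
#'   `affine` is given (then derived from the affine's column norms).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to
#'   `diag(spacing)` with the world origin at voxel (0,0,0).
#' @return An object of class `vol_grid` with fields `shape`, `spacing`,
#'   `affine`.
#' @export
vol_grid <- function(shape, spacing = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("shape must be 3 positive integers")
  }
  if (is.null(affine)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
      stop("spacing must be 3 strictly positive reals")
    }
    affine <- diag(c(spacing, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
    if (abs(det(affine)) < 1e-12) stop("affine is singular")
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
    if (any(spacing <= 0)) stop("affine has a zero-length column")
  }
  structure(list(shape = shape, spacing = spacing, affine = affine),
            class = "vol_grid")
}

#' @export
format.vol_grid <- function(x, ...) {
  sprintf("<vol_grid %s, spacing %s mm>",
          paste(x$shape, collapse = "x"),
          paste(signif(x$spacing, 4), collapse = "x"))
}

#' @export
print.vol_grid <- function(x, ...) cat(format(x), "\n")

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) < tol
}

#' World coordinates of voxel centres
#'
#' @param grid a [vol_grid].
#' @param vox n x 3 matrix of 0-based voxel coordinates (may be fractional).
#' @return n x 3 matrix of world coordinates in mm.
#' @keywords internal
voxel_to_world <- function(grid, vox) {
  vox <- matrix(as.numeric(vox), ncol = 3L)
  sweep(vox %*% t(grid$affine[1:3, 1:3]), 2L, grid$affine[1:3, 4], "+")
}

#' @rdname voxel_to_world
#' @param world n x 3 matrix of world coordinates (mm).
#' @keywords internal
world_to_voxel <- function(grid, world) {
  world <- matrix(as.numeric(world), ncol = 3L)
  inv <- solve(grid$affine)
  sweep(world %*% t(inv[1:3, 1:3]), 2L, inv[1:3, 4], "+")
}

#' World centre of a grid's field of view
#' @keywords internal
grid_center <- function(grid) {
  as.numeric(voxel_to_world(grid, matrix((grid$shape - 1) / 2, ncol = 3)))
}

#' Intensity volume
#'
#' A 3D scalar image together with its grid geometry. Values are stored as
#' doubles and must be finite.
#'
#' @param values 3D numeric array.
#' @param grid a [vol_grid] whose shape matches `dim(values)`; if missing, a
#'   unit-spacing grid is created.
#' @return An object of class `intensity_volume` with fields `grid`, `values`.
#' @export
intensity_volume <- function(values, grid = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop(sprintf("values must be a 3D array, got %dD", length(dim(values))))
  }
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) stop("values contain non-finite voxels")
  if (is.null(grid)) grid <- vol_grid(dim(values))
  if (!identical(as.integer(dim(values)), grid$shape)) {
    stop("values shape does not match grid shape")
  }
  structure(list(grid = grid, values = values), class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("<intensity_volume %s, range [%.4g, %.4g]>\n",
              format(x$grid), min(x$values), max(x$values)))
}

#' Binary mask on a grid
#'
#' @param values 3D logical (or 0/1 numeric) array.
#' @param grid a [vol_grid]; defaults to unit spacing.
#' @return An object of class `binary_mask` with fields `grid`, `values`
#'   (logical array).
#' @export
binary_mask <- function(values, grid = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("mask values must be a 3D array")
  if (!is.logical(values)) {
    values <- array(values != 0, dim = dim(values))
  }
  if (is.null(grid)) grid <- vol_grid(dim(values))
  if (!identical(as.integer(dim(values)), grid$shape)) {
    stop("mask shape does not match grid shape")
  }
  structure(list(grid = grid, values = values), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %s, %d true voxels>\n",
              format(x$grid), sum(x$values)))
}

#' Vesselness volume (per-voxel vessel probability in [0, 1])
#'
#' @param values 3D numeric array with all entries in `[0, 1]`.
#' @param grid a [vol_grid].
#' @return An object of class `vesselness_volume`.
#' @export
vesselness_volume <- function(values, grid = NULL) {
  values <- as.array(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values)) || min(values) < 0 || max(values) > 1) {
    stop("vesselness values must be finite and within [0, 1]")
  }
  if (is.null(grid)) grid <- vol_grid(dim(values))
  if (!identical(as.integer(dim(values)), grid$shape)) {
    stop("values shape does not match grid shape")
  }
  structure(list(grid = grid, values = values),
            class = c("vesselness_volume", "intensity_volume"))
}
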