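#' Read a 3D NIfTI volume
#'
#' Reads a `.nii` / `.nii.gz` file, promotes voxel data to double and
#' attaches the file's affine (sform preferred, per RNifti's `xform`) and
#' spacing as a [vol_grid].
#'
#' @param path path to a NIfTI-1 file holding a 3D scalar image.
#' @return An [intensity_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop(sprintf("expected a 3D image, got %dD (%s)", length(d), path))
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  vals <- array(as.double(img), dim = d)
  if (any(!is.finite(vals))) stop(sprintf("non-finite voxels in %s", path))
  intensity_volume(vals, vol_grid(d, affine = aff))
}

#' Write a 3D volume as NIfTI
#'
#' The grid's affine is stored as both sform and qform (code 2, aligned);
#' intensities are written as 32-bit float, masks as unsigned 8-bit.
#'
#' @param vol an [intensity_volume] or [binary_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "binary_mask")) {
    dat <- array(as.integer(vol$values), dim = vol$grid$shape)
    datatype <- "uint8"
  } else {
    stopifnot(inherits(vol, "intensity_volume"))
    dat <- vol$values
    datatype <- "float"
  }
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$grid$spacing
  aff <- structure(vol$grid$affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI mask (0/1 volume thresholded at 0.5)
#' @param path path to a NIfTI file.
#' @return A [binary_mask].
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  binary_mask(vol$values > 0.5, vol$grid)
}

#' Sample a volume at fractional 0-based voxel coordinates
#'
#' @param values 3D array.
#' @param vox n x 3 matrix of 0-based (possibly fractional) voxel coords.
#' @param mode `"linear"` (trilinear) or `"nearest"`.
#' @return numeric vector of length n; `NA` where the point falls outside
#'   the array.
#' @keywords internal
sample_volume <- function(values, vox, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(values)
  n <- nrow(vox)
  out <- rep(NA_real_, n)
  if (mode == "nearest") {
    i <- round(vox)
    ok <- i[, 1] >= 0 & i[, 1] <= d[1] - 1 &
          i[, 2] >= 0 & i[, 2] <= d[2] - 1 &
          i[, 3] >= 0 & i[, 3] <= d[3] - 1
    ii <- i[ok, , drop = FALSE]
    out[ok] <- values[1 + ii[, 1] + d[1] * (ii[, 2] + d[2] * ii[, 3])]
    return(out)
  }
  ok <- vox[, 1] >= 0 & vox[, 1] <= d[1] - 1 &
        vox[, 2] >= 0 & vox[, 2] <= d[2] - 1 &
        vox[, 3] >= 0 & vox[, 3] <= d[3] - 1
  v <- vox[ok, , drop = FALSE]
  if (nrow(v) == 0L) return(out)
  i0 <- floor(v)
  f <- v - i0
  # clamp so that points exactly on the far face use the last cell
  i0 <- pmin(i0, matrix(rep(d - 2, each = nrow(v)), ncol = 3))
  i0 <- pmax(i0, 0)
  f <- v - i0
  at <- function(dx, dy, dz) {
    values[1 + (i0[, 1] + dx) + d[1] * ((i0[, 2] + dy) + d[2] * (i0[, 3] + dz))]
  }
  w000 <- (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3])
  w100 <- f[, 1] * (1 - f[, 2]) * (1 - f[, 3])
  w010 <- (1 - f[, 1]) * f[, 2] * (1 - f[, 3])
  w110 <- f[, 1] * f[, 2] * (1 - f[, 3])
  w001 <- (1 - f[, 1]) * (1 - f[, 2]) * f[, 3]
  w101 <- f[, 1] * (1 - f[, 2]) * f[, 3]
  w011 <- (1 - f[, 1]) * f[, 2] * f[, 3]
  w111 <- f[, 1] * f[, 2] * f[, 3]
  out[ok] <- w000 * at(0, 0, 0) + w100 * at(1, 0, 0) +
             w010 * at(0, 1, 0) + w110 * at(1, 1, 0) +
             w001 * at(0, 0, 1) + w101 * at(1, 0, 1) +
             w011 * at(0, 1, 1) + w111 * at(1, 1, 1)
  out
}

# 0-based voxel coordinates of every voxel of a grid (n x 3, column-major)
all_voxels <- function(grid) {
  s <- grid$shape
  cbind(rep.int(0:(s[1] - 1), s[2] * s[3]),
        rep.int(rep(0:(s[2] - 1), each = s[1]), s[3]),
        rep(0:(s[3] - 1), each = s[1] * s[2]))
}

#' Resample a volume onto a target grid under a rigid transform
#'
#' The transform maps source world coordinates into target world
#' coordinates; each target voxel centre is pulled back through the inverse
#' transform and the source is interpolated there. Voxels mapping outside
#' the source field of view receive the fill value 0 (a dark background).
#'
#' @param src an [intensity_volume] (or [binary_mask], resampled as 0/1).
#' @param target a [vol_grid].
#' @param transform a [rigid_transform] mapping src world to target world
#'   (default identity).
#' @param mode `"linear"` or `"nearest"`. Nearest preserves the source's
#'   value set and is the right choice for label/mask images.
#' @return An [intensity_volume] on `target`.
#' @export
resample_to_grid <- function(src, target, transform = rigid_transform(),
                             mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  vals <- if (inherits(src, "binary_mask")) {
    array(as.double(src$values), dim = src$grid$shape)
  } else src$values
  world_t <- voxel_to_world(target, all_voxels(target))
  inv <- solve(rigid_matrix(transform))
  world_s <- sweep(world_t %*% t(inv[1:3, 1:3]), 2L, inv[1:3, 4], "+")
  vox_s <- world_to_voxel(src$grid, world_s)
  out <- sample_volume(vals, vox_s, mode)
  out[is.na(out)] <- 0
  intensity_volume(array(out, dim = target$shape), target)
}
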