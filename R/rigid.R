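#' Rigid 6-DOF transform in world space
#'
#' Maps moving-volume world coordinates (mm) into fixed-volume world
#' coordinates: `x' = R (x - center) + center + translation`, where `R` is
#' the rotation `Rz %*% Ry %*% Rx` built from the three Euler angles
#' (radians, fixed axis order x-then-y-then-z). `center` is the rotation
#' centre in mm; it is folded into the homogeneous matrix, so transforms
#' with different centres compose correctly.
#'
#' @param angles numeric length 3, Euler angles in radians (x, y, z).
#' @param translation numeric length 3, mm.
#' @param center numeric length 3, rotation centre in mm (default origin).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  angles <- as.numeric(angles); translation <- as.numeric(translation)
  center <- as.numeric(center)
  stopifnot(length(angles) == 3L, length(translation) == 3L,
            length(center) == 3L)
  structure(list(angles = angles, translation = translation, center = center),
            class = "rigid_transform")
}

euler_rotation <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param t a [rigid_transform] (or a 4x4 matrix, returned unchanged).
#' @return 4x4 matrix mapping homogeneous world coordinates.
#' @export
rigid_matrix <- function(t) {
  if (is.matrix(t)) return(t)
  stopifnot(inherits(t, "rigid_transform"))
  r <- euler_rotation(t$angles)
  offset <- t$center + t$translation - as.numeric(r %*% t$center)
  rbind(cbind(r, offset), c(0, 0, 0, 1))
}

#' Recover a rigid transform from a 4x4 matrix
#'
#' Euler angles are extracted for the `Rz Ry Rx` convention; the rotational
#' part must be orthonormal with determinant +1.
#'
#' @param m 4x4 rigid homogeneous matrix.
#' @param center rotation centre to express the transform about (mm).
#' @return A [rigid_transform] with `rigid_matrix()` equal to `m`.
#' @export
rigid_from_matrix <- function(m, center = c(0, 0, 0)) {
  r <- m[1:3, 1:3]
  if (max(abs(t(r) %*% r - diag(3))) > 1e-6 || det(r) < 0) {
    stop("matrix is not a proper rigid rotation")
  }
  ry <- asin(max(-1, min(1, -r[3, 1])))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(r[3, 2], r[3, 3])
    rz <- atan2(r[2, 1], r[1, 1])
  } else {  # gimbal lock: fold x into z
    rx <- atan2(-r[2, 3], r[2, 2])
    rz <- 0
  }
  angles <- c(rx, ry, rz)
  translation <- m[1:3, 4] - center + as.numeric(r %*% center)
  rigid_transform(angles, translation, center)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform rot (deg) %s, trans (mm) %s>\n",
              paste(signif(x$angles * 180 / pi, 4), collapse = ", "),
              paste(signif(x$translation, 4), collapse = ", ")))
}

#' Invert a rigid transform
#' @param t a [rigid_transform].
#' @return The inverse [rigid_transform] (expressed about the same centre).
#' @export
rigid_invert <- function(t) {
  rigid_from_matrix(solve(rigid_matrix(t)), center = t$center)
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b [rigid_transform]s.
#' @return The composition as a [rigid_transform].
#' @export
rigid_compose <- function(a, b) {
  rigid_from_matrix(rigid_matrix(a) %*% rigid_matrix(b), center = a$center)
}

#' Read / write a rigid transform as a plain-text 4x4 matrix
#'
#' The file holds the 4x4 world-mm homogeneous matrix, one row per line,
#' whitespace separated — a format that is easy to produce from any external
#' registration tool.
#'
#' @param path file path.
#' @return `read_transform` returns a [rigid_transform].
#' @export
read_transform <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (!all(dim(m) == c(4L, 4L))) stop("transform file must hold a 4x4 matrix")
  dimnames(m) <- NULL
  rigid_from_matrix(m)
}

#' @rdname read_transform
#' @param t a [rigid_transform].
#' @export
write_transform <- function(t, path) {
  m <- rigid_matrix(t)
  lines <- apply(m, 1L, function(r) paste(sprintf("%.12g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
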