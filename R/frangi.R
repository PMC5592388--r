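#' Frangi filter parameters
#'
#' @param beta blobness sensitivity (dimensionless, > 0). Controls how
#'   strongly blob-like structures (|lambda1| ~ |lambda2|) are penalized.
#' @param c structureness sensitivity in raw intensity units (> 0). Sets
#'   the Hessian magnitude at which a structure counts as "signal" rather
#'   than noise; it is meaningful only relative to the image's intensity
#'   scale, so images should live on a 0-255-like range with the default.
#' @param scales Gaussian sigmas in voxels (in-plane), strictly positive.
#'   The default spans venule-to-artery radii at typical SWI/MRA
#'   resolutions.
#' @param polarity `"dark"` to enhance hypointense tubes (veins on SWI,
#'   larger Hessian eigenvalue positive) or `"bright"` for hyperintense
#'   tubes (arteries on TOF, eigenvalue negative).
#' @return An object of class `frangi_params`.
#' @export
frangi_params <- function(beta = 0.5, c = 20,
                          scales = c(1, 1.5, 2, 2.5, 3),
                          polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0")
  if (!is.numeric(c) || c <= 0) stop("c must be > 0")
  if (length(scales) == 0L || any(scales <= 0)) {
    stop("scales must be non-empty and strictly positive")
  }
  structure(list(beta = beta, c = c, scales = as.numeric(scales),
                 polarity = polarity),
            class = "frangi_params")
}

# Sampled Gaussian-derivative kernels with discrete moment correction:
# the smoothing kernel sums to 1; the derivative kernels are the sampled
# analytic derivatives renormalized so that their discrete moments are
# exact (zero DC response, and first/second-moment responses matching the
# continuum). A constant image then has an exactly zero Hessian and a
# quadratic image an exact one, instead of merely approximate.
gaussian_deriv_kernel <- function(sigma, order = 0L) {
  if (sigma <= 0) stop("sigma must be > 0")
  r <- max(3L, ceiling(4 * sigma))
  x <- seq.int(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- -x / sigma^2 * g          # antisymmetric: sum is exactly 0
    return(k / abs(sum(x * k)))    # unit (negated) first moment
  }
  if (order == 2L) {
    k <- (x^2 - sigma^2) / sigma^4 * g
    k <- k - sum(k) * g            # exact zero DC
    return(k * 2 / sum(x^2 * k))   # response 2 on x^2
  }
  stop("order must be 0, 1 or 2")
}

# Half-sample symmetric ("reflect") index mapping for arbitrary overhang.
reflect_index <- function(p, n) {
  q <- (p - 1) %% (2 * n)
  ifelse(q < n, q + 1, 2 * n - q)
}

# Correlate a matrix with a 1D kernel along rows (first axis), reflective
# boundary. Derivative kernels are antisymmetric, so correlation with the
# sign convention of gaussian_deriv_kernel(order = 1) realizes +d/dx.
conv1d_axis1 <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  idx <- reflect_index(seq.int(1L - r, n + r), n)
  pm <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (t in seq_along(k)) {
    # correlation: out(i) = sum_u k(u) f(i + u), u = t - r - 1
    out <- out + k[t] * pm[t:(t + n - 1L), , drop = FALSE]
  }
  out
}

conv_sep2d <- function(img, kx, ky) {
  t(conv1d_axis1(t(conv1d_axis1(img, kx)), ky))
}

#' Scale-normalized 2D Hessian of an image slice
#'
#' Second-order Gaussian-derivative responses at scale `sigma` (in pixels),
#' multiplied by `sigma^2` (gamma = 2 scale normalization) so that
#' responses at different scales are comparable. Boundaries are handled by
#' reflective extension.
#'
#' @param slice_image 2D numeric matrix, at least 5 pixels per axis.
#' @param sigma Gaussian scale in pixels, > 0.
#' @return A list with matrices `dxx`, `dxy`, `dyy` (axis 1 is "x").
#' @export
hessian_2d <- function(slice_image, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  slice_image <- as.matrix(slice_image)
  if (nrow(slice_image) < 5L || ncol(slice_image) < 5L) {
    stop("slice must have at least 5 pixels per axis")
  }
  g0 <- gaussian_deriv_kernel(sigma, 0L)
  g1 <- gaussian_deriv_kernel(sigma, 1L)
  g2 <- gaussian_deriv_kernel(sigma, 2L)
  s2 <- sigma^2
  list(dxx = s2 * conv_sep2d(slice_image, g2, g0),
       dxy = s2 * conv_sep2d(slice_image, g1, g1),
       dyy = s2 * conv_sep2d(slice_image, g0, g2))
}

# Vesselness from Hessian fields at one scale (vectorized 2x2 eigen).
frangi_response <- function(h, beta, c, polarity) {
  half_tr <- (h$dxx + h$dyy) / 2
  disc <- sqrt(((h$dxx - h$dyy) / 2)^2 + h$dxy^2)
  ea <- half_tr + disc
  eb <- half_tr - disc
  # order by magnitude: |lam1| <= |lam2|
  swap <- abs(ea) >= abs(eb)
  lam2 <- ifelse(swap, ea, eb)
  lam1 <- ifelse(swap, eb, ea)
  keep <- if (polarity == "dark") lam2 > 0 else lam2 < 0
  rb2 <- ifelse(lam2 != 0, (lam1 / lam2)^2, 0)
  s2 <- lam1^2 + lam2^2
  v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * c^2)))
  v[!keep] <- 0
  matrix(v, nrow = nrow(h$dxx))
}

#' Multiscale 2D Frangi vesselness of a slice
#'
#' For each pixel the Hessian eigenvalues `|lambda1| <= |lambda2|` are
#' computed at every scale; pixels failing the polarity sign test on
#' `lambda2` (dark tubes need `lambda2 > 0`, bright tubes `lambda2 < 0`)
#' get vesselness 0, otherwise
#' `exp(-R_B^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))`
#' with `R_B = lambda1 / lambda2` and `S = sqrt(lambda1^2 + lambda2^2)`.
#' The result is the pointwise maximum over scales and lies in `[0, 1]`;
#' it is read as a per-pixel vessel probability.
#'
#' @param slice_image 2D numeric matrix.
#' @param params a [frangi_params].
#' @return 2D matrix of vesselness values in `[0, 1]`.
#' @export
frangi_slice <- function(slice_image, params) {
  stopifnot(inherits(params, "frangi_params"))
  out <- matrix(0, nrow(slice_image), ncol(slice_image))
  for (sigma in params$scales) {
    h <- hessian_2d(slice_image, sigma)
    out <- pmax(out, frangi_response(h, params$beta, params$c, params$polarity))
  }
  out
}

#' Slice-wise Frangi vesselness of a 3D volume
#'
#' Applies [frangi_slice] independently to every slice perpendicular to
#' `slice_axis` (default 3, the acquisition/axial axis). Scales are in
#' in-plane voxels of the volume's own grid.
#'
#' @param vol an [intensity_volume].
#' @param params a [frangi_params].
#' @param slice_axis axis index (1, 2 or 3) perpendicular to the filtered
#'   slices.
#' @return A [vesselness_volume] on `vol`'s grid.
#' @export
vesselness_3d <- function(vol, params, slice_axis = 3L) {
  stopifnot(inherits(vol, "intensity_volume"))
  if (!slice_axis %in% 1:3) stop("slice_axis must be 1, 2 or 3")
  perm <- switch(slice_axis, `1` = c(2, 3, 1), `2` = c(1, 3, 2), `3` = c(1, 2, 3))
  v <- if (slice_axis == 3L) vol$values else aperm(vol$values, perm)
  out <- array(0, dim = dim(v))
  for (k in seq_len(dim(v)[3])) {
    out[, , k] <- frangi_slice(v[, , k], params)
  }
  if (slice_axis != 3L) out <- aperm(out, order(perm))
  vesselness_volume(out, vol$grid)
}
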