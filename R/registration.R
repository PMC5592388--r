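#' Registration configuration
#'
#' @param bins number of intensity bins per axis of the joint histogram
#'   (>= 8; default 64).
#' @param levels pyramid levels (>= 1; default 3). Level `l` subsamples the
#'   fixed grid by `2^(levels - l)` and smooths both volumes accordingly,
#'   coarse to fine.
#' @param tol relative convergence tolerance of the simplex optimizer.
#' @param max_iter maximum optimizer iterations per pyramid level.
#' @param clip_quantiles intensity quantiles used to clip each volume before
#'   binning; stabilizes the histogram against a few very hot vessel voxels.
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(bins = 64L, levels = 3L, tol = 1e-6,
                                max_iter = 400L,
                                clip_quantiles = c(0.005, 0.995)) {
  bins <- as.integer(bins); levels <- as.integer(levels)
  if (bins < 8L) stop("bins must be >= 8")
  if (levels < 1L) stop("levels must be >= 1")
  structure(list(bins = bins, levels = levels, tol = tol,
                 max_iter = as.integer(max_iter),
                 clip_quantiles = clip_quantiles),
            class = "registration_config")
}

# Clip to quantile range and bin into 1..bins.
bin_intensities <- function(x, bins, clip = c(0.005, 0.995), range = NULL) {
  if (is.null(range)) range <- stats::quantile(x, clip, names = FALSE)
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) hi <- lo + 1e-12
  x <- pmin(pmax(x, lo), hi)
  pmin(bins, 1L + floor((x - lo) / (hi - lo) * bins))
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information of two volumes on a shared grid
#'
#' `NMI = (H(A) + H(B)) / H(A, B)` from a joint intensity histogram;
#' equals 1 for independent images and 2 for identical ones (up to
#' discretization). Intensities are clipped at the 0.5-99.5 percentile
#' range before binning.
#'
#' @param a,b [intensity_volume]s on the same grid (resample first if not),
#'   or plain numeric vectors of paired samples.
#' @param bins histogram bins per axis (default 64).
#' @return The NMI value (>= 1 up to sampling noise).
#' @export
normalized_mutual_information <- function(a, b, bins = 64L) {
  av <- if (inherits(a, "intensity_volume")) as.numeric(a$values) else as.numeric(a)
  bv <- if (inherits(b, "intensity_volume")) as.numeric(b$values) else as.numeric(b)
  if (length(av) != length(bv)) {
    stop("volumes must be sampled on the same grid")
  }
  ok <- is.finite(av) & is.finite(bv)
  if (!any(ok)) stop("no overlapping voxels with defined intensities")
  nmi_binned(bin_intensities(av[ok], bins), bin_intensities(bv[ok], bins), bins)
}

nmi_binned <- function(ia, ib, bins, smooth = FALSE) {
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  jm <- matrix(joint / sum(joint), bins, bins)
  if (smooth) {
    # light Parzen-style smoothing of the joint histogram (1-2-1 kernel
    # along both axes); regularizes the entropy estimate so the NMI
    # objective is smooth enough for optimization, as in SPM's approach
    blur <- function(m) {
      n <- nrow(m)
      m2 <- m
      m2[2:(n - 1), ] <- 0.25 * m[1:(n - 2), ] + 0.5 * m[2:(n - 1), ] +
        0.25 * m[3:n, ]
      m2
    }
    jm <- t(blur(t(blur(jm))))
    jm <- jm / sum(jm)
  }
  ha <- entropy_nats(rowSums(jm))
  hb <- entropy_nats(colSums(jm))
  hab <- entropy_nats(as.numeric(jm))
  if (hab == 0) return(2)  # both images constant: degenerate, maximal by convention
  (ha + hb) / hab
}

# Separable Gaussian smoothing of a 3D array (sigma in voxels per axis).
smooth_gaussian_3d <- function(v, sigma) {
  sigma <- rep(sigma, length.out = 3L)
  d <- dim(v)
  for (ax in 1:3) {
    if (sigma[ax] <= 0.05 || d[ax] < 2L) next
    k <- gaussian_deriv_kernel(sigma[ax], 0L)
    m <- apply(v, setdiff(1:3, ax), identity)      # ax becomes first dim
    m <- conv1d_axis1(matrix(m, nrow = d[ax]), k)
    v <- aperm(array(m, dim = c(d[ax], d[-ax])),
               order(c(ax, setdiff(1:3, ax))))
  }
  v
}

# Subsample a volume by an integer stride (taking every stride-th voxel),
# after matched Gaussian smoothing; affine is rescaled so world positions
# of the kept voxels are unchanged.
pyramid_level <- function(vol, stride) {
  if (stride <= 1L) return(vol)
  v <- smooth_gaussian_3d(vol$values, stride / 2)
  idx <- lapply(vol$grid$shape, function(n) seq.int(1L, n, by = stride))
  v <- v[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  aff <- vol$grid$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * stride
  intensity_volume(v, vol_grid(dim(v), affine = aff))
}

# NMI of moving resampled onto fixed's grid under t, over voxels where the
# pulled-back point lands inside the moving volume.
nmi_at <- function(moving_vals, moving_grid, fixed, trans, bins,
                   fixed_bins, moving_range,
                   world_t = voxel_to_world(fixed$grid,
                                            all_voxels(fixed$grid))) {
  inv <- solve(rigid_matrix(trans))
  world_s <- sweep(world_t %*% t(inv[1:3, 1:3]), 2L, inv[1:3, 4], "+")
  vox_s <- world_to_voxel(moving_grid, world_s)
  mv <- sample_volume(moving_vals, vox_s, "linear")
  ok <- !is.na(mv)
  if (sum(ok) < 100) return(NA_real_)
  ib <- bin_intensities(mv[ok], bins, range = moving_range)
  nmi_binned(fixed_bins[ok], ib, bins, smooth = TRUE)
}

#' Estimate the rigid transform aligning a moving to a fixed volume
#'
#' Maximizes normalized mutual information over the 6 rigid parameters with
#' a derivative-free Nelder-Mead simplex, run coarse-to-fine over a
#' Gaussian pyramid (NMI built from hard-binned histograms is not smooth
#' enough for gradient methods). The search is initialized at the identity
#' in world space, i.e. at the relative pose implied by the two image
#' headers; rotation is parameterized about the fixed volume's centre.
#'
#' @param moving the volume to be aligned (e.g. the TOF MRA).
#' @param fixed the reference volume (e.g. the SWI).
#' @param config a [registration_config].
#' @param init optional initial [rigid_transform] (moving world to fixed
#'   world).
#' @return A [rigid_transform] mapping moving world coordinates into fixed
#'   world coordinates, with attributes `nmi` (final value) and `converged`.
#' @export
estimate_rigid <- function(moving, fixed, config = registration_config(),
                           init = NULL) {
  stopifnot(inherits(moving, "intensity_volume"),
            inherits(fixed, "intensity_volume"))
  center <- grid_center(fixed$grid)
  par <- c(0, 0, 0, 0, 0, 0)
  if (!is.null(init)) {
    t0 <- rigid_from_matrix(rigid_matrix(init), center = center)
    par <- c(t0$angles, t0$translation)
  }
  bins <- config$bins
  converged <- TRUE
  value <- NA_real_
  for (lev in seq_len(config$levels)) {
    stride <- 2L^(config$levels - lev)
    fx <- pyramid_level(fixed, stride)
    mv_vals <- if (stride > 1L) {
      smooth_gaussian_3d(moving$values, stride / 2 * fixed$grid$spacing /
                           moving$grid$spacing)
    } else moving$values
    fixed_bins <- bin_intensities(as.numeric(fx$values), bins,
                                  config$clip_quantiles)
    moving_range <- stats::quantile(mv_vals, config$clip_quantiles,
                                    names = FALSE)
    world_fx <- voxel_to_world(fx$grid, all_voxels(fx$grid))
    objective <- function(p) {
      tr <- rigid_transform(p[1:3], p[4:6], center)
      v <- nmi_at(mv_vals, moving$grid, fx, tr, bins, fixed_bins,
                  moving_range, world_fx)
      if (is.na(v)) return(1e6)
      -v
    }
    if (lev == 1L) {
      # coarse rotation sweep (+-3 deg per axis) to pick the right basin:
      # hard-binned NMI has rotation-local optima a few degrees apart and
      # the simplex alone can commit to the wrong one
      sweep_step <- 3 * pi / 180
      cand <- as.matrix(expand.grid(a1 = -1:1, a2 = -1:1, a3 = -1:1)) *
        sweep_step
      best_v <- objective(par)
      best_par <- par
      for (ci in seq_len(nrow(cand))) {
        pc <- par + c(cand[ci, ], 0, 0, 0)
        vc <- objective(pc)
        if (vc < best_v) { best_v <- vc; best_par <- pc }
      }
      par <- best_par
    }
    # two simplex passes: a wide one (initial steps ~0.6 deg / ~0.8 mm via
    # parscale) to escape the binning-noise plateau around the start, then
    # a narrow one for sub-voxel refinement
    for (scale in c(1, 0.15)) {
      fit <- stats::optim(par, objective, method = "Nelder-Mead",
                          control = list(reltol = config$tol,
                                         maxit = config$max_iter,
                                         parscale = scale * c(rep(0.1, 3),
                                                              rep(8, 3))))
      # guard against a degenerate level: never accept a worse point
      if (fit$value <= objective(par) + 1e-12) par <- fit$par
      value <- -fit$value
      if (fit$convergence != 0) converged <- FALSE
    }
  }
  out <- rigid_transform(par[1:3], par[4:6], center)
  attr(out, "nmi") <- value
  attr(out, "converged") <- converged
  if (!converged) {
    warning(sprintf("optimizer did not fully converge; final NMI = %.4f", value))
  }
  out
}

#' Registration quality control
#'
#' Compares NMI of the moving volume resampled onto the fixed grid before
#' (identity / header alignment) and after applying a transform; a
#' registration passes if it did not reduce NMI.
#'
#' @param moving,fixed [intensity_volume]s.
#' @param t the [rigid_transform] under review.
#' @param bins histogram bins (default 64).
#' @return A list with `nmi_before`, `nmi_after`, `pass`.
#' @export
registration_qc <- function(moving, fixed, t, bins = 64L) {
  nmi_of <- function(tr) {
    res <- resample_to_grid(moving, fixed$grid, tr, "linear")
    normalized_mutual_information(res, fixed, bins)
  }
  before <- nmi_of(rigid_transform())
  after <- nmi_of(t)
  list(nmi_before = before, nmi_after = after,
       pass = after >= before - 1e-9)
}
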