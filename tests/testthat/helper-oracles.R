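# Independent brute-force oracles and shared phantom fixtures.
# Oracles deliberately avoid the package's computational path: direct 2D
# kernel convolution instead of separable 1D passes, eigen() instead of
# the closed-form 2x2 eigenvalues, explicit per-voxel window loops instead
# of vectorized shifts, and cut()/table() histograms for NMI.

# full 2D correlation with an explicit kernel matrix, reflective padding
oracle_conv2d <- function(img, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  n1 <- nrow(img); n2 <- ncol(img)
  ref <- function(p, n) {
    q <- (p - 1) %% (2 * n)
    ifelse(q < n, q + 1, 2 * n - q)
  }
  pad <- img[ref(seq(1 - r, n1 + r), n1), ref(seq(1 - r, n2 + r), n2)]
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      out[i, j] <- sum(pad[i:(i + 2 * r), j:(j + 2 * r)] * kernel)
    }
  }
  out
}

oracle_gauss_kernels <- function(sigma) {
  r <- max(3L, ceiling(4 * sigma))
  x <- seq.int(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  g1 <- -x / sigma^2 * g
  g1 <- g1 / abs(sum(x * g1))
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  g2 <- g2 - sum(g2) * g
  g2 <- g2 * 2 / sum(x^2 * g2)
  list(g = g, g1 = g1, g2 = g2)
}

# per-pixel Frangi vesselness: 2D convolution + eigen() + formula
oracle_frangi_slice <- function(img, beta, c, sigmas, polarity) {
  best <- matrix(0, nrow(img), ncol(img))
  for (sigma in sigmas) {
    k <- oracle_gauss_kernels(sigma)
    dxx <- sigma^2 * oracle_conv2d(img, outer(k$g2, k$g))
    dxy <- sigma^2 * oracle_conv2d(img, outer(k$g1, k$g1))
    dyy <- sigma^2 * oracle_conv2d(img, outer(k$g, k$g2))
    for (i in seq_len(nrow(img))) {
      for (j in seq_len(ncol(img))) {
        ev <- eigen(matrix(c(dxx[i, j], dxy[i, j], dxy[i, j], dyy[i, j]), 2L),
                    symmetric = TRUE, only.values = TRUE)$values
        l2 <- if (abs(ev[1]) >= abs(ev[2])) ev[1] else ev[2]
        l1 <- if (abs(ev[1]) >= abs(ev[2])) ev[2] else ev[1]
        ok <- if (polarity == "dark") l2 > 0 else l2 < 0
        v <- if (!ok || l2 == 0) 0 else {
          exp(-(l1 / l2)^2 / (2 * beta^2)) *
            (1 - exp(-(l1^2 + l2^2) / (2 * c^2)))
        }
        if (v > best[i, j]) best[i, j] <- v
      }
    }
  }
  best
}

# per-voxel sliding-window minimum over unmasked voxels, leading-anchored;
# a window with every voxel masked takes the hyperintense fill value,
# floored at the raw window minimum
oracle_masked_mip <- function(v, mask, w, fill) {
  d <- dim(v)
  out <- array(NA_real_, d)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        sl <- k:min(d[3], k + w - 1L)
        vals <- v[i, j, sl][!mask[i, j, sl]]
        out[i, j, k] <- if (length(vals)) min(vals) else {
          max(fill, min(v[i, j, sl]))
        }
      }
    }
  }
  out
}

# NMI via cut()/table() under the package's binning rule
oracle_nmi <- function(a, b, bins = 64L, clip = c(0.005, 0.995)) {
  binit <- function(x) {
    r <- stats::quantile(x, clip, names = FALSE)
    if (r[2] <= r[1]) r[2] <- r[1] + 1e-12
    x <- pmin(pmax(x, r[1]), r[2])
    cut(pmin(bins, 1 + floor((x - r[1]) / (r[2] - r[1]) * bins)),
        breaks = 0:bins + 0.5, labels = FALSE)
  }
  joint <- table(binit(a), binit(b))
  p <- joint / sum(joint)
  h <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  (h(rowSums(p)) + h(colSums(p))) / h(as.numeric(p))
}

# --- shared phantom fixtures (world geometry of the default phantom at
# --- reduced matrix sizes, so tests stay fast) ---

# for registration recovery: full vasculature, mid-resolution grids
reg_phantom_spec <- function(misalignment = rigid_transform(), seed = 1L) {
  phantom_spec(tubes = preset_suite()$score2$tubes,
               swi_shape = c(56, 56, 26), swi_spacing = c(1.875, 1.875, 2.2),
               mra_shape = c(80, 80, 32), mra_spacing = c(1.2, 1.2, 1.1),
               mra_origin = c(5, 5, 5),
               misalignment = misalignment, seed = seed)
}

# a minimal phantom with one artery and one well-separated vein; the MRA
# grid keeps a clinical-like sub-millimetre in-plane spacing so arterial
# segmentation operates in its intended regime
two_tube_spec <- function(seed = 7L, misalignment = rigid_transform()) {
  phantom_spec(tubes = list(
    tube_line(c(60, 28, 28), c(62, 80, 28), 1.3, "vein"),
    tube_helix(c(30, 52, 28), c(0, 1, 0), turn_radius = 4.5, pitch = 40,
               theta = c(-1.2, 1.2) * pi, radius = 1.7, channel = "artery",
               swi_dark = TRUE)),
    swi_shape = c(44, 44, 20), swi_spacing = c(2.4, 2.4, 2.8),
    mra_shape = c(112, 112, 36), mra_spacing = c(0.82, 0.82, 0.95),
    mra_origin = c(6, 6, 4), m1_slice = 6L,
    misalignment = misalignment, seed = seed)
}

rotation_error_deg <- function(a, b) {
  r <- rigid_matrix(a)[1:3, 1:3] %*% t(rigid_matrix(b)[1:3, 1:3])
  acos(min(1, max(-1, (sum(diag(r)) - 1) / 2))) * 180 / pi
}

translation_error_mm <- function(a, b, at = c(52.5, 52.5, 27)) {
  d <- rigid_matrix(a) %*% c(at, 1) - rigid_matrix(b) %*% c(at, 1)
  sqrt(sum(d[1:3]^2))
}
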