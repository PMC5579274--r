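#' First-order intensity features
#'
#' The ten intensity features of the battery: variance, skewness, kurtosis,
#' SUVmax, SUVpeak, SUVmean, the area under the cumulative intensity-volume
#' histogram (AUC-CSH), total lesion glycolysis (TLG), the percentage of
#' inactive volume, and the generalized effective total uptake (gETU). The
#' same formulas apply to CT volumes, operating on Hounsfield units.
#'
#' Moments are population moments over ROI voxels (variance `m2`, skewness
#' `m3/m2^1.5`, kurtosis `m4/m2^2`), 0 for degenerate (constant or single
#' voxel) ROIs. SUVpeak averages the in-ROI voxels whose centers lie within a
#' 1 cm-cubed sphere centred on the hottest voxel. AUC-CSH integrates, over
#' `n_bins` equal threshold steps spanning the ROI intensity range, the
#' fractional volume at or above each threshold (midpoint rule). TLG is
#' SUVmean times the ROI volume in cm-cubed; gETU generalizes it to
#' `V * mean(x^a)^(1/a)` and reduces to TLG at `a = 1`. The inactive volume
#' is the ROI percentage below `inactive_frac` of the ROI maximum.
#'
#' @param vol an [image_volume()].
#' @param mask the aligned [roi_mask()].
#' @param n_bins histogram bins for AUC-CSH.
#' @param inactive_frac threshold fraction of the ROI maximum defining
#'   "inactive" voxels.
#' @param getu_a gETU exponent.
#' @return named numeric vector of length 10.
#' @export
intensity_features <- function(vol, mask, n_bins = 100L, inactive_frac = 0.5,
                               getu_a = 1) {
  check_aligned(vol, mask)
  x <- vol$data[mask$data]
  n <- length(x)
  vox_cm3 <- prod(vol$spacing) / 1000
  v_cm3 <- n * vox_cm3
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  skew <- if (m2 > 1e-12) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 1e-12) mean((x - mu)^4) / m2^2 else 0

  # SUVpeak: 1 cm^3 sphere around the hottest voxel
  r_mm <- (3 * 1000 / (4 * pi))^(1 / 3)
  idx <- which(mask$data, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, vol$spacing, `*`)
  imax <- which.max(x)
  d2 <- rowSums(sweep(pts, 2, pts[imax, ], `-`)^2)
  peak <- mean(x[d2 <= r_mm^2])

  rng <- max(x) - min(x)
  if (rng > 0) {
    xs <- (x - min(x)) / rng
    th <- (seq_len(n_bins) - 0.5) / n_bins
    auc_csh <- mean(vapply(th, function(t) mean(xs >= t), numeric(1)))
  } else {
    auc_csh <- 1  # constant ROI: whole volume at the maximum
  }

  inactive <- if (max(x) > 0) 100 * mean(x < inactive_frac * max(x)) else 0
  getu <- if (getu_a == 1 || any(x < 0)) v_cm3 * mu else
    v_cm3 * mean(x^getu_a)^(1 / getu_a)

  c(variance = m2, skewness = skew, kurtosis = kurt,
    SUVmax = max(x), SUVpeak = peak, SUVmean = mu,
    aucCSH = auc_csh, TLG = mu * v_cm3, pctInactive = inactive, gETU = getu)
}

# Extreme in-ROI voxels along grid lines: a cheap superset of the convex
# hull vertices, used for hull construction and the maximum-diameter search.
roi_extreme_points <- function(mask, spacing) {
  idx <- which(mask$data, arr.ind = TRUE)
  keep <- rep(FALSE, nrow(idx))
  for (a in 1:3) {
    others <- setdiff(1:3, a)
    key <- paste(idx[, others[1]], idx[, others[2]])
    rng <- tapply(idx[, a], key, range)
    lim <- do.call(rbind, rng[key])
    keep <- keep | idx[, a] == lim[, 1] | idx[, a] == lim[, 2]
  }
  sweep(idx[keep, , drop = FALSE] - 1, 2, spacing, `*`)
}

# Surface area (mm^2) as the integral of the gradient magnitude of the
# Gaussian-smoothed indicator function; converges to the smooth-boundary
# area, unlike the staircase voxel-face count.
surface_area <- function(mask, spacing, sigma_vox = 1.5) {
  pad <- ceiling(3 * sigma_vox) + 1
  d <- dim(mask$data)
  arr <- array(0, d + 2 * pad)
  arr[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask$data)
  k <- seq(-ceiling(3 * sigma_vox), ceiling(3 * sigma_vox))
  kern <- exp(-k^2 / (2 * sigma_vox^2))
  kern <- kern / sum(kern)
  arr <- conv_axis(arr, kern, 1)
  arr <- conv_axis(arr, kern, 2)
  arr <- conv_axis(arr, kern, 3)
  gx <- grad_axis(arr, 1) / spacing[1]
  gy <- grad_axis(arr, 2) / spacing[2]
  gz <- grad_axis(arr, 3) / spacing[3]
  sum(sqrt(gx^2 + gy^2 + gz^2)) * prod(spacing)
}

conv_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  f <- stats::filter(m, kern, sides = 2)
  f[is.na(f)] <- 0
  aperm(array(as.numeric(f), d[perm]), order(perm))
}

grad_axis <- function(arr, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  g <- (rbind(m[-1, , drop = FALSE], 0) - rbind(0, m[-nrow(m), , drop = FALSE])) / 2
  aperm(array(as.numeric(g), d[perm]), order(perm))
}

#' Morphological shape features
#'
#' The five shape features of the battery: ROI volume (cm^3), size (maximum
#' tumour diameter in mm, the largest distance between any two ROI voxel
#' centers), solidity (ROI voxel count over the voxel count of the rasterized
#' convex hull), eccentricity (`sqrt(1 - lambda_min/lambda_max)` of the
#' principal-axis second moments) and compactness
#' (`V / (sqrt(pi) * A^1.5)`, dimensionless, maximal at `1/(6*pi)` for a
#' sphere). Degenerate ROIs: a single voxel has size 0, eccentricity 0 and
#' solidity 1; planar or collinear ROIs have solidity 1 by convention.
#'
#' @param mask an [roi_mask()].
#' @param spacing voxel spacing in mm (defaults to the mask's).
#' @return named numeric vector of length 5.
#' @export
shape_features <- function(mask, spacing = mask$spacing) {
  d <- dim(mask$data)
  n <- sum(mask$data)
  v_mm3 <- n * prod(spacing)
  ext <- roi_extreme_points(mask, spacing)
  size <- if (nrow(ext) > 1) cpp_max_pairwise_dist(ext) else 0

  # solidity: rasterized convex hull of ROI voxel centers
  if (n >= 4) {
    bb <- apply(which(mask$data, arr.ind = TRUE), 2, range)
    grid <- as.matrix(expand.grid(x = bb[1, 1]:bb[2, 1], y = bb[1, 2]:bb[2, 2],
                                  z = bb[1, 3]:bb[2, 3]))
    query <- sweep(grid - 1, 2, spacing, `*`)
    inside <- cpp_hull_count_inside(ext, query, 1e-7 * max(1, max(abs(ext))))
    solidity <- if (inside > 0) min(1, n / inside) else 1
  } else {
    solidity <- 1
  }

  idx <- which(mask$data, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, spacing, `*`)
  # second moments include the voxel self-moment (spacing^2/12): voxels are
  # cubes, not points, so a single voxel is isotropic (eccentricity 0) and a
  # one-voxel-thick rod stays strictly below 1
  mom <- if (n > 1) stats::cov(pts) * (n - 1) / n else matrix(0, 3, 3)
  mom <- mom + diag(spacing^2 / 12)
  ev <- eigen(mom, symmetric = TRUE, only.values = TRUE)$values
  ecc <- sqrt(max(0, 1 - max(0, ev[3]) / ev[1]))

  a_mm2 <- surface_area(mask, spacing)
  compact <- v_mm3 / (sqrt(pi) * a_mm2^1.5)

  c(volume = v_mm3 / 1000, size = size, solidity = solidity,
    eccentricity = ecc, compactness = compact)
}
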