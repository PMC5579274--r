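#' 3D image volume with voxel spacing
#'
#' Container for a 3D scalar image: SUV-valued for PET, Hounsfield-valued for
#' CT. Spacing is the physical voxel size in mm along each array axis, so
#' anisotropic acquisitions are represented exactly.
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, voxel size (dx, dy, dz) in mm; all > 0.
#' @param modality `"PET"` or `"CT"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, modality = c("PET", "CT")) {
  modality <- match.arg(modality)
  stopifnot(is.array(data), length(dim(data)) == 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive voxel sizes in mm")
  structure(list(data = data, spacing = spacing, modality = modality),
            class = "image_volume")
}

#' Binary region-of-interest mask
#'
#' A binary grid aligned voxel-for-voxel with its [image_volume()]. Multiple
#' connected components are allowed (e.g. a primary tumour plus involved
#' lymph nodes analysed as a single gross tumour volume).
#'
#' @param data logical/0-1 3D array, same shape as the paired volume.
#' @param spacing voxel spacing in mm, same as the paired volume.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data, spacing) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  data <- array(as.logical(data), dim = dim(data))
  if (!any(data)) stop("ROI mask is empty: at least one voxel must be set")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive voxel sizes in mm")
  structure(list(data = data, spacing = spacing), class = "roi_mask")
}

check_aligned <- function(vol, mask) {
  if (!identical(dim(vol$data), dim(mask$data)))
    stop("volume and mask shapes differ")
  if (max(abs(vol$spacing - mask$spacing)) > 1e-9)
    stop("volume and mask spacings differ")
  if (any(!is.finite(vol$data[mask$data])))
    stop("volume contains non-finite values inside the ROI")
  invisible(TRUE)
}

#' Texture extraction parameter grid
#'
#' Enumerates the full grid of texture extraction settings: isotropic voxel
#' sizes of 1--5 mm, the two within-ROI quantization algorithms, and 8, 16,
#' 32 or 64 gray levels — 40 combinations in total.
#'
#' @param voxel_sizes isotropic voxel sizes in mm.
#' @param quant_algos quantization algorithms.
#' @param n_grays numbers of gray levels.
#' @return data.frame with columns `voxel_size_mm`, `quant_algo`, `n_gray`.
#' @export
texture_params_grid <- function(voxel_sizes = 1:5,
                                quant_algos = c("EqualProbability", "Uniform"),
                                n_grays = c(8L, 16L, 32L, 64L)) {
  g <- expand.grid(n_gray = as.integer(n_grays), quant_algo = quant_algos,
                   voxel_size_mm = voxel_sizes,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[, c("voxel_size_mm", "quant_algo", "n_gray")]
}

#' Resample a volume and its ROI to an isotropic voxel size
#'
#' The output grid is anchored at the input volume's origin (voxel centers at
#' integer multiples of `s` from the first input voxel center) and covers the
#' ROI bounding box padded by one voxel, so texture neighbourhoods at the ROI
#' border are preserved. Image intensities are interpolated with a tricubic
#' (Keys) kernel by default; the mask is interpolated linearly and
#' re-binarized at 0.5.
#'
#' @param vol an [image_volume()].
#' @param mask the aligned [roi_mask()].
#' @param s target isotropic voxel size in mm.
#' @param interp `"cubic"` (default) or `"linear"` image interpolation.
#' @return list with elements `vol` and `mask` on the new isotropic grid.
#' @export
resample_isotropic <- function(vol, mask, s, interp = c("cubic", "linear")) {
  interp <- match.arg(interp)
  check_aligned(vol, mask)
  stopifnot(is.numeric(s), length(s) == 1L, s > 0)

  idx <- which(mask$data, arr.ind = TRUE)
  # physical coordinates of ROI bounding box (voxel-1 center = 0 per axis)
  lo <- (apply(idx, 2, min) - 1) * vol$spacing
  hi <- (apply(idx, 2, max) - 1) * vol$spacing
  coords <- lapply(1:3, function(a) {
    k <- seq(floor((lo[a] - s) / s), ceiling((hi[a] + s) / s))
    k * s
  })
  # fractional input voxel indices (0-based) of the output sample points
  u <- lapply(1:3, function(a) coords[[a]] / vol$spacing[a])

  method <- if (interp == "cubic") 1L else 0L
  newdat <- cpp_interp3(vol$data, dim(vol$data), u[[1]], u[[2]], u[[3]], method)
  newmask <- cpp_interp3(array(as.numeric(mask$data), dim(mask$data)),
                         dim(mask$data), u[[1]], u[[2]], u[[3]], 0L) >= 0.5
  newmask <- array(newmask, dim = dim(newdat))
  if (!any(newmask))
    stop(sprintf("ROI is empty after resampling to %g mm isotropic voxels", s))
  list(vol = image_volume(newdat, rep(s, 3), vol$modality),
       mask = roi_mask(newmask, rep(s, 3)))
}

new_quantized_roi <- function(levels, n_gray, spacing) {
  structure(list(levels = levels, n_gray = as.integer(n_gray),
                 spacing = spacing), class = "quantized_roi")
}

#' Uniform gray-level quantization of a ROI
#'
#' Divides the within-ROI intensity range into `n_gray` equal-width bins:
#' `level = min(n_gray, floor(n_gray * (x - min) / (max - min)) + 1)`, so the
#' ROI minimum maps to level 1 and the maximum to `n_gray`. A constant ROI
#' maps entirely to level 1. Voxels outside the ROI carry level 0.
#'
#' @param vol an [image_volume()].
#' @param mask the aligned [roi_mask()].
#' @param n_gray number of gray levels (>= 2).
#' @return A `quantized_roi`: integer level grid plus `n_gray`.
#' @export
quantize_uniform <- function(vol, mask, n_gray) {
  check_aligned(vol, mask)
  n_gray <- as.integer(n_gray)
  stopifnot(n_gray >= 2L)
  x <- vol$data[mask$data]
  lo <- min(x); hi <- max(x)
  lev <- array(0L, dim = dim(vol$data))
  if (hi - lo <= 0) {
    lev[mask$data] <- 1L
  } else {
    lev[mask$data] <- pmin(n_gray, floor(n_gray * (x - lo) / (hi - lo)) + 1L)
  }
  new_quantized_roi(lev, n_gray, vol$spacing)
}

#' Equal-probability gray-level quantization of a ROI
#'
#' Histogram-equalizing quantization: bin edges are the within-ROI empirical
#' quantiles at k/n_gray, so with distinct intensities the per-level voxel
#' counts are flat to within one count. Heavy ties may leave some levels
#' empty; level counts always sum to the ROI size.
#'
#' @inheritParams quantize_uniform
#' @return A `quantized_roi`.
#' @export
quantize_equalprob <- function(vol, mask, n_gray) {
  check_aligned(vol, mask)
  n_gray <- as.integer(n_gray)
  stopifnot(n_gray >= 2L)
  x <- vol$data[mask$data]
  edges <- quantile(x, probs = seq_len(n_gray - 1L) / n_gray,
                    names = FALSE, type = 7)
  lev <- array(0L, dim = dim(vol$data))
  lev[mask$data] <- 1L + vapply(x, function(v) sum(v > edges), integer(1))
  new_quantized_roi(lev, n_gray, vol$spacing)
}

quantize_roi <- function(vol, mask, algo, n_gray) {
  switch(algo,
         Uniform = quantize_uniform(vol, mask, n_gray),
         EqualProbability = quantize_equalprob(vol, mask, n_gray),
         stop("unknown quantization algorithm: ", algo))
}

#' Read a volume/mask pair from NIfTI files
#'
#' Volume and mask must share grid shape and voxel spacing; the mask is
#' binarized at > 0.
#'
#' @param vol_path,mask_path paths to `.nii`/`.nii.gz` files.
#' @param modality `"PET"` or `"CT"`.
#' @return list with `vol` ([image_volume()]) and `mask` ([roi_mask()]).
#' @export
read_nifti_pair <- function(vol_path, mask_path, modality = c("PET", "CT")) {
  modality <- match.arg(modality)
  v <- RNifti::readNifti(vol_path)
  m <- RNifti::readNifti(mask_path)
  sp <- RNifti::pixdim(v)[1:3]
  if (!identical(dim(v)[1:3], dim(m)[1:3]))
    stop("volume and mask NIfTI grids differ in shape")
  if (max(abs(sp - RNifti::pixdim(m)[1:3])) > 1e-6)
    stop("volume and mask NIfTI voxel spacings differ")
  vol <- image_volume(array(as.numeric(v), dim = dim(v)[1:3]), sp, modality)
  mask <- roi_mask(array(as.numeric(m) > 0, dim = dim(m)[1:3]), sp)
  check_aligned(vol, mask)
  list(vol = vol, mask = mask)
}

#' Write a volume (or mask) to NIfTI
#'
#' @param x an [image_volume()] or [roi_mask()].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  dat <- if (inherits(x, "roi_mask")) array(as.numeric(x$data), dim(x$data)) else x$data
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
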