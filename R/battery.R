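#' Full radiomic feature battery
#'
#' Computes the complete per-modality battery of 1615 named features:
#' 10 intensity and 5 shape features at native resolution, plus the 40
#' texture features at each of the 40 extraction-parameter combinations
#' (isotropic voxel sizes 1--5 mm, Uniform / EqualProbability quantization,
#' 8/16/32/64 gray levels). Texture feature names are formed as
#' `<family>_<feature>__vx<s>mm_<algo>_Ng<k>` and listed in stable
#' lexicographic order after the intensity and shape blocks.
#'
#' @param vol an [image_volume()].
#' @param mask the aligned [roi_mask()].
#' @param grid parameter grid, defaults to [texture_params_grid()].
#' @param config extraction options, see [extraction_config()].
#' @return named numeric vector of length 1615 with attribute `modality`.
#' @export
extract_battery <- function(vol, mask, grid = texture_params_grid(),
                            config = extraction_config()) {
  check_aligned(vol, mask)
  out <- c(intensity_features(vol, mask, n_bins = config$n_bins,
                              inactive_frac = config$inactive_frac,
                              getu_a = config$getu_a),
           shape_features(mask))

  tex <- vector("list", nrow(grid))
  cache <- list()
  for (r in seq_len(nrow(grid))) {
    s <- grid$voxel_size_mm[r]
    key <- as.character(s)
    if (is.null(cache[[key]])) {
      cache[[key]] <- tryCatch(
        resample_isotropic(vol, mask, s, interp = config$interp),
        error = function(e) stop("battery extraction failed at voxel size ",
                                 s, " mm: ", conditionMessage(e), call. = FALSE))
    }
    rs <- cache[[key]]
    q <- quantize_roi(rs$vol, rs$mask, grid$quant_algo[r], grid$n_gray[r])
    f <- texture_features(q, distance_weight = config$distance_weight)
    names(f) <- paste0(names(f), "__vx", s, "mm_", grid$quant_algo[r],
                       "_Ng", grid$n_gray[r])
    tex[[r]] <- f
  }
  tex <- unlist(tex)
  tex <- tex[order(names(tex), method = "radix")]
  out <- c(out, tex)
  stopifnot(!anyDuplicated(names(out)), all(is.finite(out)))
  attr(out, "modality") <- vol$modality
  out
}

#' Extraction configuration
#'
#' Bundles the tunable extraction conventions: interpolation kernel for
#' resampling, the diagonal distance correction for texture matrices, the
#' AUC-CSH histogram resolution, the inactive-volume threshold fraction and
#' the gETU exponent.
#'
#' @param interp image interpolation, `"cubic"` or `"linear"`.
#' @param distance_weight inverse-distance diagonal correction flag.
#' @param n_bins histogram bins for AUC-CSH.
#' @param inactive_frac inactive-volume threshold as a fraction of the ROI
#'   maximum.
#' @param getu_a gETU exponent.
#' @return named list of class `extraction_config`.
#' @export
extraction_config <- function(interp = "cubic", distance_weight = TRUE,
                              n_bins = 100L, inactive_frac = 0.5, getu_a = 1) {
  structure(list(interp = interp, distance_weight = distance_weight,
                 n_bins = n_bins, inactive_frac = inactive_frac,
                 getu_a = getu_a, schema_version = "1.0"),
            class = "extraction_config")
}

#' Names of the 1615-feature battery
#'
#' @param grid parameter grid, defaults to [texture_params_grid()].
#' @return character vector of length 1615.
#' @export
battery_feature_names <- function(grid = texture_params_grid()) {
  tex <- unlist(lapply(seq_len(nrow(grid)), function(r)
    paste0(texture_feature_names(), "__vx", grid$voxel_size_mm[r], "mm_",
           grid$quant_algo[r], "_Ng", grid$n_gray[r])))
  c(c("variance", "skewness", "kurtosis", "SUVmax", "SUVpeak", "SUVmean",
      "aucCSH", "TLG", "pctInactive", "gETU"),
    c("volume", "size", "solidity", "eccentricity", "compactness"),
    sort(tex, method = "radix"))
}

#' Write / read a feature table as CSV with a JSON config side-car
#'
#' The side-car records the extraction configuration and a schema version so
#' a table can be audited and reproduced.
#'
#' @param table data.frame of patients by features (plus outcome columns).
#' @param path CSV output path; the side-car is written at `<path>.json`.
#' @param config the [extraction_config()] used.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, config = extraction_config()) {
  write.csv(table, path, row.names = FALSE)
  jsonlite::write_json(unclass(config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(tab, "config") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tab
}
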