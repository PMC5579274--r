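#' 3D texture matrices
#'
#' The four classical texture matrices are built once per scan from the
#' quantized ROI, merging all 13 unique directions of 3D space
#' (26-connectivity) into a single matrix. Because diagonal neighbours sit at
#' physical distances of sqrt(2) and sqrt(3) voxels rather than 1, diagonal
#' contributions are distance-corrected: co-occurrence pairs (GLCM) and
#' neighbourhood averages (NGTDM) are weighted by inverse Euclidean distance,
#' and run lengths (GLRLM) accumulate the geometric step length before being
#' rounded to an integer run-length column. The unweighted variant is
#' selectable via `distance_weight = FALSE`.
#'
#' @param q a `quantized_roi` from [quantize_uniform()] or
#'   [quantize_equalprob()].
#' @param distance_weight apply the inverse-distance diagonal correction
#'   (default `TRUE`).
#' @return `build_glcm`: list with `m` (symmetric matrix normalized to sum 1)
#'   and `degenerate` (single-voxel ROI flag). `build_glrlm`/`build_glszm`:
#'   list with the count matrix `m` (gray level by run length / zone size).
#'   `build_ngtdm`: list with `s` (summed absolute gray-tone differences),
#'   `p` (occurrence probabilities) and `n_valid` (contributing voxel count).
#' @name texture_matrices
NULL

dist_weights <- function(distance_weight) {
  if (distance_weight) c(1, 1 / sqrt(2), 1 / sqrt(3)) else c(1, 1, 1)
}

#' @rdname texture_matrices
#' @export
build_glcm <- function(q, distance_weight = TRUE) {
  w <- dist_weights(distance_weight)
  m <- cpp_glcm(q$levels, dim(q$levels), q$n_gray, w[1], w[2], w[3])
  tot <- sum(m)
  degenerate <- tot <= 0
  if (!degenerate) m <- m / tot
  list(m = m, degenerate = degenerate)
}

#' @rdname texture_matrices
#' @export
build_glrlm <- function(q, distance_weight = TRUE) {
  m <- cpp_glrlm(q$levels, dim(q$levels), q$n_gray, distance_weight)
  # trim empty trailing run-length columns (keep at least one)
  last <- max(1L, max(which(colSums(m) > 0), 1L))
  list(m = m[, seq_len(last), drop = FALSE])
}

#' @rdname texture_matrices
#' @export
build_glszm <- function(q) {
  list(m = cpp_glszm(q$levels, dim(q$levels), q$n_gray))
}

#' @rdname texture_matrices
#' @export
build_ngtdm <- function(q, distance_weight = TRUE) {
  w <- dist_weights(distance_weight)
  r <- cpp_ngtdm(q$levels, dim(q$levels), q$n_gray, w[1], w[2], w[3])
  n_valid <- sum(r$n)
  p <- if (n_valid > 0) r$n / n_valid else r$n
  list(s = as.numeric(r$s), p = as.numeric(p), n_valid = n_valid)
}

#' Dump texture matrices of a quantized ROI to CSV files for inspection
#'
#' @param q a `quantized_roi`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
dump_texture_matrices <- function(q, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  mats <- list(GLCM = build_glcm(q)$m, GLRLM = build_glrlm(q)$m,
               GLSZM = build_glszm(q)$m)
  for (nm in names(mats)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(mats[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  ng <- build_ngtdm(q)
  p <- file.path(dir, "NGTDM.csv")
  write.csv(data.frame(level = seq_along(ng$s), s = ng$s, p = ng$p), p,
            row.names = FALSE)
  invisible(c(paths, p))
}
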