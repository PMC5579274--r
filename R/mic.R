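#' Maximal information coefficient (MIC)
#'
#' Grid-search MIC: over every grid resolution `i x j` with
#' `i * j <= B(n) = n^alpha` (`i, j >= 2`), one axis is equipartitioned into
#' `i` rows and the partition of the other axis into at most `j` columns is
#' optimized by dynamic programming (candidate boundaries restricted to
#' `clump_factor * j` equal-frequency superclumps, the standard heuristic);
#' both axis orientations are searched. The maximal mutual information is
#' normalized by `log2(min(i, j))` and the maximum over resolutions is the
#' MIC.
#'
#' @param x,y numeric vectors (n >= 10).
#' @param alpha grid-size exponent, `B(n) = n^alpha`.
#' @param clump_factor superclump multiplier bounding the dynamic-programming
#'   candidate boundaries.
#' @return MIC in \[0, 1\]; symmetric in `(x, y)`; 0 for constant input.
#' @export
mic <- function(x, y, alpha = 0.6, clump_factor = 5L) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 10)
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cpp_mic(as.numeric(x), as.numeric(y), alpha, as.integer(clump_factor))
}
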