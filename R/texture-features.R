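#' Texture features from the four matrix families
#'
#' Computes the 40 texture features used throughout the package: 9 from the
#' GLCM, 13 from the GLRLM, 13 from the GLSZM and 5 from the NGTDM. Feature
#' names carry their family prefix (e.g. `GLSZM_GLN`). Degenerate ROIs
#' (single level, single voxel) follow fixed rules: entropy 0, correlation 0
#' when a marginal variance vanishes, and an epsilon guard (1e-9) in the
#' NGTDM coarseness/strength denominators.
#'
#' @param q a `quantized_roi`.
#' @param distance_weight inverse-distance diagonal correction, see
#'   [build_glcm()].
#' @return named numeric vector of length 40, all values finite.
#' @export
texture_features <- function(q, distance_weight = TRUE) {
  c(glcm_features(build_glcm(q, distance_weight), q),
    glrlm_features(build_glrlm(q, distance_weight)),
    glszm_features(build_glszm(q)),
    ngtdm_features(build_ngtdm(q, distance_weight)))
}

#' @export
#' @rdname texture_features
#' @format NULL
texture_feature_names <- function() {
  c(paste0("GLCM_", c("energy", "contrast", "entropy", "homogeneity",
                      "correlation", "sum_average", "variance",
                      "dissimilarity", "autocorrelation")),
    paste0("GLRLM_", c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
                       "SRLGE", "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV")),
    paste0("GLSZM_", c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE",
                       "SZLGE", "SZHGE", "LZLGE", "LZHGE", "GLV", "ZSV")),
    paste0("NGTDM_", c("coarseness", "busyness", "contrast", "complexity",
                       "strength")))
}

glcm_features <- function(glcm, q) {
  p <- glcm$m
  if (glcm$degenerate) {
    # single-voxel ROI: point mass at its own level
    g <- q$levels[q$levels > 0][1]
    p <- matrix(0, q$n_gray, q$n_gray)
    p[g, g] <- 1
  }
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mu <- sum(seq_len(ng) * px)
  s2 <- sum((seq_len(ng) - mu)^2 * px)
  corr <- if (s2 > 1e-12) (sum(i * j * p) - mu * mu) / s2 else 0
  ent <- -sum(p[p > 0] * log2(p[p > 0]))
  c(GLCM_energy = sum(p^2),
    GLCM_contrast = sum((i - j)^2 * p),
    GLCM_entropy = ent,
    GLCM_homogeneity = sum(p / (1 + abs(i - j))),
    GLCM_correlation = corr,
    GLCM_sum_average = sum((i + j) * p),
    GLCM_variance = sum((i - mu)^2 * p),
    GLCM_dissimilarity = sum(abs(i - j) * p),
    GLCM_autocorrelation = sum(i * j * p))
}

# Shared form of the 13 run-length / zone-size statistics: `m` counts by
# gray level (rows) and run length or zone size (columns). Order: short
# emphasis, long emphasis, gray-level non-uniformity, length/size
# non-uniformity, percentage, low/high gray-level emphasis, the four
# short/long x low/high crosses, gray-level variance, length/size variance.
rl_stats <- function(m) {
  nr <- sum(m)
  g <- row(m); j <- col(m)
  p <- m / nr
  pg <- rowSums(p); pj <- colSums(p)
  mug <- sum(seq_len(nrow(m)) * pg)
  muj <- sum(seq_len(ncol(m)) * pj)
  c(sum(p / j^2),
    sum(p * j^2),
    sum(rowSums(m)^2) / nr,
    sum(colSums(m)^2) / nr,
    nr / sum(j * m),
    sum(p / g^2),
    sum(p * g^2),
    sum(p / (g^2 * j^2)),
    sum(p * g^2 / j^2),
    sum(p * j^2 / g^2),
    sum(p * g^2 * j^2),
    sum((seq_len(nrow(m)) - mug)^2 * pg),
    sum((seq_len(ncol(m)) - muj)^2 * pj))
}

glrlm_features <- function(glrlm) {
  setNames(rl_stats(glrlm$m),
           paste0("GLRLM_", c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE",
                              "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE",
                              "GLV", "RLV")))
}

glszm_features <- function(glszm) {
  setNames(rl_stats(glszm$m),
           paste0("GLSZM_", c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE",
                              "HGZE", "SZLGE", "SZHGE", "LZLGE", "LZHGE",
                              "GLV", "ZSV")))
}

ngtdm_features <- function(ngtdm) {
  eps <- 1e-9
  s <- ngtdm$s
  p <- ngtdm$p
  n <- ngtdm$n_valid
  occ <- which(p > 0)
  lev <- seq_along(p)
  coarseness <- 1 / (eps + sum(p * s))
  if (length(occ) > 1 && n > 0) {
    io <- lev[occ]; po <- p[occ]; so <- s[occ]
    dif2 <- outer(io, io, function(a, b) (a - b)^2)
    ppij <- outer(po, po)
    contrast <- sum(ppij * dif2) / (length(occ) * (length(occ) - 1)) * sum(s) / n
    denom_busy <- sum(abs(outer(io * po, io * po, "-")))
    busyness <- if (denom_busy > 0) sum(po * so) / denom_busy else 0
    psi <- outer(po * so, po * so, "+")
    psum <- outer(po, po, "+")
    complexity <- sum(abs(outer(io, io, "-")) * psi / psum) / n
    strength <- sum(outer(po, po, "+") * dif2) / (eps + sum(s))
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(NGTDM_coarseness = coarseness, NGTDM_busyness = busyness,
    NGTDM_contrast = contrast, NGTDM_complexity = complexity,
    NGTDM_strength = strength)
}
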