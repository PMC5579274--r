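test_that("intensity features on a constant ROI follow the closed forms", {
  vol <- vol_from(2.5, c(3, 3, 3), spacing = c(2, 2, 2))
  mask <- mask_from(TRUE, c(3, 3, 3), spacing = c(2, 2, 2))
  f <- intensity_features(vol, mask)
  v_cm3 <- 27 * 8 / 1000
  expect_equal(unname(f["SUVmax"]), 2.5)
  expect_equal(unname(f["SUVmean"]), 2.5)
  expect_equal(unname(f["SUVpeak"]), 2.5)
  expect_equal(unname(f["variance"]), 0)
  expect_equal(unname(f["TLG"]), 2.5 * v_cm3)
  expect_equal(unname(f["gETU"]), 2.5 * v_cm3)  # a = 1 reduces to TLG
})

test_that("moments match hand-computed values and degenerate rules", {
  dims <- c(2, 2, 2)
  m <- mask_from(c(rep(TRUE, 4), rep(FALSE, 4)), dims)
  f <- intensity_features(vol_from(c(1, 1, 3, 3, 0, 0, 0, 0), dims), m)
  expect_equal(unname(f["variance"]), 1)   # mean 2, m2 = 1
  expect_equal(unname(f["skewness"]), 0)
  expect_equal(unname(f["kurtosis"]), 1)   # m4/m2^2 = 1 for a two-point mass

  sv <- array(FALSE, c(3, 3, 3)); sv[2, 2, 2] <- TRUE
  fs <- intensity_features(vol_from(rnorm(27), c(3, 3, 3)),
                           roi_mask(sv, c(1, 1, 1)))
  expect_equal(unname(fs[c("variance", "skewness", "kurtosis")]), c(0, 0, 0))
})

test_that("AUC-CSH of a linear ramp matches the analytic area", {
  # uniformly ramped intensities: fractional volume above threshold t is
  # 1 - t, so the area under the cumulative curve is 1/2
  vals <- seq(0, 10, length.out = 64)
  f <- intensity_features(vol_from(vals, c(4, 4, 4)), mask_from(TRUE, c(4, 4, 4)))
  expect_equal(unname(f["aucCSH"]), 0.5, tolerance = 0.02)
})

test_that("shape features recover the analytic sphere at r = 10 voxels", {
  n <- 25; ctr <- 13
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  ball <- array((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= 100, c(n, n, n))
  f <- shape_features(roi_mask(ball, c(1, 1, 1)))
  expect_equal(unname(f["volume"]), 4 / 3 * pi, tolerance = 0.05)
  expect_gte(unname(f["solidity"]), 0.97)
  expect_lte(unname(f["solidity"]), 1)
  expect_equal(unname(f["compactness"]), 1 / (6 * pi), tolerance = 0.10)
  expect_lt(unname(f["eccentricity"]), 0.2)
})

test_that("shape features handle degenerate ROIs", {
  sv <- array(FALSE, c(3, 3, 3)); sv[2, 2, 2] <- TRUE
  f <- shape_features(roi_mask(sv, c(1, 1, 1)))
  expect_equal(unname(f["volume"]), 0.001)   # one 1 mm^3 voxel
  expect_equal(unname(f["size"]), 0)
  expect_equal(unname(f["eccentricity"]), 0)
  expect_equal(unname(f["solidity"]), 1)

  rod <- array(FALSE, c(3, 3, 12)); rod[2, 2, 2:11] <- TRUE
  fr <- shape_features(roi_mask(rod, c(1, 1, 1)))
  expect_equal(unname(fr["size"]), 9)  # extreme voxel centers
  expect_lt(unname(fr["eccentricity"]), 1)
  expect_gt(unname(fr["eccentricity"]), 0.9)
})

test_that("texture features on simple ROIs follow the degenerate rules", {
  f <- texture_features(make_q(array(2L, c(2, 2, 2)), 4))
  expect_equal(unname(f["GLCM_energy"]), 1)
  expect_equal(unname(f["GLCM_entropy"]), 0)
  expect_equal(unname(f["GLSZM_ZSN"]), 1)  # single zone
  expect_true(all(is.finite(f)))
  expect_length(f, 40L)
  expect_identical(names(f), texture_feature_names())
})

test_that("run-length emphases match the hand-enumerated 1 x 4 x 1 matrix", {
  # levels (1,1,2,2): one axis run per level of length 2, plus 4 singleton
  # runs per remaining direction -> m[.,1] = 24 per level, m[.,2] = 1
  q <- make_q(array(c(1L, 1L, 2L, 2L), c(1, 4, 1)), 2)
  f <- texture_features(q)
  nr <- 50
  expect_equal(unname(f["GLRLM_SRE"]), (48 + 2 / 4) / nr)
  expect_equal(unname(f["GLRLM_LRE"]), (48 + 2 * 4) / nr)
  expect_equal(unname(f["GLRLM_GLN"]), (25^2 + 25^2) / nr)
})

test_that("texture features equal a naive recomputation from oracle matrices on random ROIs", {
  set.seed(99)
  for (rep in 1:5) {
    q <- random_quantized_roi(max_dim = 4)
    f <- texture_features(q)
    expect_true(all(is.finite(f)))
    # independent recomputation of two representative features per family
    lev <- q$levels; ng <- q$n_gray
    glcm <- oracle_glcm(lev, ng)
    if (sum(glcm) > 0) {
      expect_equal(unname(f["GLCM_energy"]), sum(glcm^2), tolerance = 1e-10)
      i <- row(glcm); j <- col(glcm)
      expect_equal(unname(f["GLCM_contrast"]), sum((i - j)^2 * glcm),
                   tolerance = 1e-10)
    }
    orl <- oracle_glrlm(lev, ng)
    cnt <- unlist(orl)
    lens <- as.numeric(vapply(strsplit(names(orl), " "), `[`, "", 2))
    expect_equal(unname(f["GLRLM_SRE"]),
                 sum(cnt / lens^2) / sum(cnt), tolerance = 1e-10)
    zones <- oracle_glszm(lev)
    sizes <- vapply(zones, `[`, 0, 2)
    expect_equal(unname(f["GLSZM_SZE"]),
                 mean(1 / sizes^2), tolerance = 1e-10)
    o <- oracle_ngtdm(lev, ng)
    pn <- if (sum(o$n) > 0) o$n / sum(o$n) else o$n
    expect_equal(unname(f["NGTDM_coarseness"]),
                 1 / (1e-9 + sum(pn * o$s)), tolerance = 1e-6)
  }
})

test_that("the battery enumerates exactly 1615 deterministic named features", {
  ph <- make_phantom(shape = c(16, 16, 16), roi_semiaxes_mm = c(6, 6.5, 7),
                     rng_seed = 1)
  fv <- extract_battery(ph$vol, ph$mask)
  expect_length(fv, 1615L)
  expect_equal(anyDuplicated(names(fv)), 0L)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), battery_feature_names())
  expect_equal(attr(fv, "modality"), "PET")

  ph2 <- make_phantom(shape = c(16, 16, 16), roi_semiaxes_mm = c(6, 6.5, 7),
                      rng_seed = 1)
  expect_identical(fv, extract_battery(ph2$vol, ph2$mask))
})

test_that("intensity features (except SUVpeak) are invariant to in-mask voxel shuffles, textures are not", {
  ph <- make_phantom(shape = c(14, 14, 14), roi_semiaxes_mm = c(5, 5, 5),
                     corr_len_mm = 2, rng_seed = 8)
  set.seed(2)
  shuffled <- ph$vol$data
  inmask <- which(ph$mask$data)
  shuffled[inmask] <- shuffled[sample(inmask)]
  vol2 <- image_volume(shuffled, ph$vol$spacing, ph$vol$modality)

  f1 <- intensity_features(ph$vol, ph$mask)
  f2 <- intensity_features(vol2, ph$mask)
  keep <- setdiff(names(f1), "SUVpeak")
  expect_equal(f1[keep], f2[keep], tolerance = 1e-12)

  q1 <- quantize_uniform(ph$vol, ph$mask, 16)
  q2 <- quantize_uniform(vol2, ph$mask, 16)
  t1 <- texture_features(q1); t2 <- texture_features(q2)
  expect_gt(max(abs(t1 - t2) / pmax(abs(t1), 1e-9)), 0.01)
})

test_that("a battery grid point with an empty resampled ROI reports the offending voxel size", {
  m <- array(FALSE, c(12, 12, 12)); m[6, 6, 6] <- TRUE
  vol <- vol_from(rnorm(12^3, 5), c(12, 12, 12))
  expect_error(extract_battery(vol, roi_mask(m, c(1, 1, 1))), "mm")
})

test_that("feature tables round-trip through CSV with their config side-car", {
  tab <- data.frame(patient_id = c("P1", "P2"), f1 = c(0.5, 1.5),
                    event = c(0L, 1L))
  path <- tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back$f1, tab$f1)
  expect_equal(attr(back, "config")$n_bins, 100L)
  unlink(c(path, paste0(path, ".json")))
})
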