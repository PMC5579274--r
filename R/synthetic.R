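#' Synthetic textured tumour phantom
#'
#' Generates a 3D scalar volume with an ellipsoidal ROI and spatially
#' correlated texture: white Gaussian noise smoothed with a Gaussian kernel
#' whose standard deviation is the correlation length, then rescaled to the
#' requested mean and variance. A correlation length of 0 gives voxel-wise
#' independent noise; variance 0 gives a constant ROI. The default settings
#' emulate an FDG-PET tumour: SUV-like mean around 5 with visible
#' intratumoural heterogeneity in a 16--32 voxel ROI at 1 mm spacing.
#'
#' @param shape grid dimensions (voxels).
#' @param spacing voxel spacing in mm.
#' @param roi_semiaxes_mm ellipsoid semi-axes in mm (ROI centred in the
#'   grid); must fit inside the grid.
#' @param mean,variance target intensity moments of the field.
#' @param corr_len_mm texture correlation length in mm (>= 0).
#' @param modality `"PET"` or `"CT"`.
#' @param preset `"smooth"` (default Gaussian texture), `"checkerboard"`
#'   (alternating blocks, for feature sanity tests) or `"necrotic_core"`
#'   (cold center, hot rim).
#' @param rng_seed integer seed; identical seeds give identical phantoms.
#' @return list with `vol` ([image_volume()]) and `mask` ([roi_mask()]).
#' @export
make_phantom <- function(shape = c(24L, 24L, 24L), spacing = c(1, 1, 1),
                         roi_semiaxes_mm = c(8, 9, 10), mean = 5,
                         variance = 2, corr_len_mm = 2,
                         modality = c("PET", "CT"),
                         preset = c("smooth", "checkerboard", "necrotic_core"),
                         rng_seed = 1L) {
  modality <- match.arg(modality)
  preset <- match.arg(preset)
  stopifnot(corr_len_mm >= 0, variance >= 0)
  half_extent <- (shape - 1) * spacing / 2
  if (any(roi_semiaxes_mm > half_extent))
    stop("ROI ellipsoid is larger than the grid")
  set.seed(rng_seed)

  cx <- lapply(1:3, function(a) ((seq_len(shape[a]) - 1) -
                                   (shape[a] - 1) / 2) * spacing[a])
  u2 <- outer(outer((cx[[1]] / roi_semiaxes_mm[1])^2,
                    (cx[[2]] / roi_semiaxes_mm[2])^2, `+`),
              (cx[[3]] / roi_semiaxes_mm[3])^2, `+`)
  mask <- u2 <= 1

  field <- array(rnorm(prod(shape)), dim = shape)
  if (preset == "smooth") {
    if (corr_len_mm > 0) {
      for (a in 1:3) {
        sig <- corr_len_mm / spacing[a]
        k <- seq(-ceiling(3 * sig), ceiling(3 * sig))
        kern <- exp(-k^2 / (2 * sig^2)); kern <- kern / sum(kern)
        field <- conv_axis(field, kern, a)
      }
    }
    field <- (field - base::mean(field)) / stats::sd(field)
    field <- mean + sqrt(variance) * field
    if (variance == 0) field <- array(mean, dim = shape)
  } else if (preset == "checkerboard") {
    blk <- pmax(1L, round(corr_len_mm / spacing))
    par <- outer(outer((seq_len(shape[1]) - 1) %/% blk[1],
                       (seq_len(shape[2]) - 1) %/% blk[2], `+`),
                 (seq_len(shape[3]) - 1) %/% blk[3], `+`) %% 2
    field <- mean + sqrt(variance) * (2 * par - 1)
  } else {  # necrotic core: cold center, hot rim, mild noise
    rim <- sqrt(pmax(u2, 0))
    field <- mean * (0.3 + 0.7 * pmin(rim, 1)) +
      sqrt(variance) * 0.2 * field
  }
  list(vol = image_volume(field, spacing, modality),
       mask = roi_mask(mask, spacing))
}

#' Synthetic imbalanced cohort with censored time-to-event outcomes
#'
#' Builds a feature table with a known generative model: standard-normal
#' radiomic-like features (informative features named in `beta`, plus
#' `n_noise` pure-noise features), a binary event drawn from
#' `Bernoulli(logistic(b0 + beta' x))` with the intercept calibrated so the
#' expected event proportion equals `event_rate`, event times drawn from an
#' exponential whose hazard scales with the linear risk, and early censoring
#' of non-events by an independent exponential. The defaults emulate the
#' kind of training cohort the methods target: ~190 subjects with ~15%
#' events and follow-up on the order of five years.
#'
#' @param n number of subjects.
#' @param event_rate expected event proportion in (0, 1).
#' @param beta named coefficients of the informative features (per standard
#'   deviation of the feature).
#' @param n_noise number of additional independent noise features
#'   (`noise01`, `noise02`, ...).
#' @param base_hazard baseline event hazard per month at risk 0.
#' @param log_hr log hazard ratio per unit of the (standardized) linear
#'   risk.
#' @param censor_rate probability that a non-event subject is censored
#'   before the follow-up horizon.
#' @param horizon_months administrative follow-up horizon.
#' @param clinical add clinical columns (`age`, `hn_type`, `t_stage`,
#'   `n_stage`, `tnm_stage`).
#' @param rng_seed integer seed.
#' @return data.frame with `patient_id`, feature columns, and outcome
#'   columns `event`, `time_months`, `censored` (event = 1 implies
#'   censored = 0).
#' @export
make_cohort <- function(n = 194L, event_rate = 0.15,
                        beta = c(sig1 = 1.5, sig2 = 1.2, sig3 = 1.0),
                        n_noise = 27L, base_hazard = 0.03, log_hr = 1,
                        censor_rate = 0.1, horizon_months = 60,
                        clinical = FALSE, rng_seed = 1L) {
  stopifnot(event_rate > 0, event_rate < 1, censor_rate >= 0, censor_rate < 1)
  set.seed(rng_seed)
  feats <- list()
  for (nm in names(beta)) feats[[nm]] <- rnorm(n)
  if (n_noise > 0)
    for (k in seq_len(n_noise))
      feats[[sprintf("noise%02d", k)]] <- rnorm(n)
  tab <- as.data.frame(feats)

  if (clinical) {
    tab$age <- round(rnorm(n, 62, 10), 1)
    tab$hn_type <- sample(c("oropharynx", "hypopharynx", "nasopharynx",
                            "larynx"), n, replace = TRUE,
                          prob = c(0.55, 0.1, 0.1, 0.25))
    tab$t_stage <- sample(1:4, n, replace = TRUE, prob = c(0.2, 0.3, 0.3, 0.2))
    tab$n_stage <- sample(0:3, n, replace = TRUE, prob = c(0.25, 0.2, 0.45, 0.1))
    tab$tnm_stage <- pmin(4L, pmax(tab$t_stage, tab$n_stage + 1L))
  }

  eta <- rep(0, n)
  for (nm in names(beta)) {
    x <- as.numeric(tab[[nm]])
    eta <- eta + beta[[nm]] * (x - base::mean(x)) / stats::sd(x)
  }
  b0 <- uniroot(function(b) base::mean(plogis(b + eta)) - event_rate,
                c(-30, 30))$root
  event <- rbinom(n, 1, plogis(b0 + eta))
  if (sum(event) == 0) {  # resample once, then give up
    event <- rbinom(n, 1, plogis(b0 + eta))
    if (sum(event) == 0) stop("no events realized in the synthetic cohort")
  }

  time <- numeric(n)
  censored <- integer(n)
  ev <- event == 1
  time[ev] <- rexp(sum(ev), rate = base_hazard * exp(log_hr * eta[ev]))
  early <- !ev & runif(n) < censor_rate
  time[early] <- pmin(rexp(sum(early), rate = 1 / (horizon_months / 2)),
                      horizon_months * 0.99)
  censored[early] <- 1L
  time[!ev & !early] <- horizon_months
  time <- pmax(time, 0.1)

  cbind(data.frame(patient_id = sprintf("P%03d", seq_len(n))), tab,
        data.frame(event = event, time_months = time, censored = censored))
}
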