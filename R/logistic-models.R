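#' @title Imbalance-adjusted logistic model construction
#' @description Internal helpers plus the exported pipeline operations:
#'   Gain-based reduction of a feature table to 25 candidates, 0.632+
#'   bootstrap forward selection over model orders 1--10, automatic order
#'   choice, and the final bootstrap-averaged logistic model.
#' @name logistic_models
NULL

# Ridge-penalized logistic log-likelihood fit (Newton/BFGS); used both as
# the separation fallback and wherever glm.fit fails to converge.
ridge_logistic <- function(X, y, lambda = 1e-4) {
  Xi <- cbind(1, X)
  p <- ncol(Xi)
  nll <- function(b) {
    eta <- drop(Xi %*% b)
    -sum(y * eta - log1p(exp(eta))) + lambda * sum(b[-1]^2) / 2
  }
  grad <- function(b) {
    mu <- plogis(drop(Xi %*% b))
    -drop(crossprod(Xi, y - mu)) + lambda * c(0, b[-1])
  }
  fit <- stats::optim(rep(0, p), nll, grad, method = "BFGS",
                      control = list(maxit = 500))
  fit$par
}

# One logistic fit; returns c(intercept, coefs). Columns with zero variance
# get coefficient 0. Separation / non-convergence falls back to a tiny-ridge
# fit (recorded via attribute "ridged").
logistic_fit <- function(X, y) {
  const <- apply(X, 2, function(col) var(col) == 0)
  Xf <- X[, !const, drop = FALSE]
  ridged <- FALSE
  co <- rep(0, ncol(Xf) + 1)
  if (ncol(Xf) == 0) {
    co <- c(stats::qlogis(max(1e-6, min(1 - 1e-6, mean(y)))))
  } else {
    fit <- suppressWarnings(glm.fit(cbind(1, Xf), y, family = binomial()))
    co <- fit$coefficients
    if (!fit$converged || anyNA(co) || max(abs(co[-1])) > 50) {
      co <- ridge_logistic(Xf, y)
      ridged <- TRUE
    }
  }
  out <- rep(0, ncol(X) + 1)
  out[1] <- co[1]
  out[c(FALSE, !const)] <- co[-1]
  attr(out, "ridged") <- ridged
  attr(out, "dropped") <- colnames(X)[const]
  out
}

# Partition-ensemble logistic fit: coefficients averaged over the balanced
# partitions of one (bootstrap) sample.
ensemble_logistic <- function(X, y, idx, rng_seed = NULL, w = 1) {
  pos <- idx[y[idx] == 1]
  neg <- idx[y[idx] == 0]
  plan <- plan_partitions(neg, pos, rng_seed)
  coefs <- vapply(seq_along(plan$partitions), function(k) {
    part <- plan$partitions[[k]]
    if (w != 1)
      part <- apply_class_weight(part, plan$minority_idx, w,
                                 rng_seed = if (is.null(rng_seed)) NULL
                                            else rng_seed + 7919L * k)
    as.numeric(logistic_fit(X[part, , drop = FALSE], y[part]))
  }, numeric(ncol(X) + 1))
  rowMeans(coefs)
}

# class-stratified bootstrap indices (both classes always represented)
stratified_bootstrap <- function(y) {
  pos <- which(y == 1); neg <- which(y == 0)
  c(sample(pos, length(pos), replace = TRUE),
    sample(neg, length(neg), replace = TRUE))
}

#' Gain-based reduction of a feature set
#'
#' Greedy forward pass balancing univariate predictive power against
#' redundancy: the first feature maximizes `|r_s(f, y)|` (Spearman); each
#' subsequent feature maximizes
#' `Gain(f | S) = w_g * |r_s(f, y)| + (1 - w_g) * (1 - redundancy(f, S))`
#' where the redundancy is the maximum (default) or mean MIC between the
#' candidate and the already-selected features. Max aggregation guarantees
#' that an exact duplicate of a selected feature (MIC 1) is maximally
#' penalized no matter how many features are already selected; the mean
#' variant dilutes that penalty as the set grows.
#'
#' @param table data.frame of candidate features plus the outcome column.
#' @param outcome name of the binary outcome column.
#' @param features candidate feature names (default: all numeric non-outcome
#'   columns).
#' @param target_size number of features to retain (25 in the standard
#'   pipeline). If fewer candidates are available, all are returned with a
#'   warning.
#' @param w_g mixing weight between predictive power and non-redundancy.
#' @param redundancy `"max"` or `"mean"` MIC aggregation.
#' @return data.frame (`feature`, `gain`) of class `reduced_feature_set`, in
#'   selection order.
#' @export
reduce_feature_set <- function(table, outcome = "event", features = NULL,
                               target_size = 25L, w_g = 0.5,
                               redundancy = c("max", "mean")) {
  redundancy <- match.arg(redundancy)
  y <- table[[outcome]]
  stopifnot(all(y %in% 0:1))
  if (is.null(features))
    features <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                        c(outcome, "time_months", "censored", "event"))
  if (length(features) < target_size) {
    warning("fewer candidate features (", length(features),
            ") than target_size; returning all")
    target_size <- length(features)
  }
  rs <- vapply(features, function(f) abs(spearman_assoc(table[[f]], y)$r_s),
               numeric(1))
  sel <- character(0)
  gains <- numeric(0)
  mic_cache <- new.env(parent = emptyenv())
  pair_mic <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "\r")
    if (is.null(mic_cache[[key]]))
      mic_cache[[key]] <- mic(table[[a]], table[[b]])
    mic_cache[[key]]
  }
  remaining <- features
  for (step in seq_len(target_size)) {
    if (step == 1) {
      g <- rs[remaining]
    } else {
      g <- vapply(remaining, function(f) {
        red <- vapply(sel, function(s) pair_mic(f, s), numeric(1))
        agg <- if (redundancy == "mean") mean(red) else max(red)
        w_g * rs[[f]] + (1 - w_g) * (1 - agg)
      }, numeric(1))
    }
    pick <- remaining[which.max(g)]
    sel <- c(sel, pick)
    gains <- c(gains, max(g))
    remaining <- setdiff(remaining, pick)
  }
  structure(data.frame(feature = sel, gain = gains),
            class = c("reduced_feature_set", "data.frame"))
}

#' 0.632+ bootstrap AUC of an imbalance-adjusted logistic model
#'
#' Estimates prediction performance of the logistic model on `features` as
#' `(1 - w) * AUC_app + w * AUC_oob` with overfitting rate
#' `R = (AUC_app - AUC'_oob) / (AUC_app - 0.5)` (clipped to \[0, 1\],
#' `AUC'_oob = max(AUC_oob, 0.5)`) and weight `w = 0.632 / (1 - 0.368 R)`;
#' 0.5 is the no-information AUC. Every fit — apparent and per-bootstrap —
#' is a balanced partition-ensemble logistic regression, and bootstrap
#' samples are drawn stratified by class so both classes are always present.
#'
#' @param table feature table with the outcome column.
#' @param features model feature names.
#' @param outcome binary outcome column name.
#' @param n_boot number of bootstrap samples.
#' @param rng_seed integer seed.
#' @return list with `estimate`, `auc_app`, `auc_oob`, `w`, `R`, `se` (the
#'   standard error of the mean out-of-bag AUC).
#' @export
auc_632plus <- function(table, features, outcome = "event", n_boot = 100L,
                        rng_seed = 1L) {
  X <- as.matrix(table[, features, drop = FALSE])
  y <- table[[outcome]]
  stopifnot(sum(y == 1) >= 2, sum(y == 0) >= 2)
  set.seed(rng_seed)
  co_app <- ensemble_logistic(X, y, seq_along(y))
  scores_app <- plogis(drop(cbind(1, X) %*% co_app))
  auc_app <- roc_metrics(scores_app, y)$auc

  oob_aucs <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    for (try in 1:10) {
      idx <- stratified_bootstrap(y)
      oob <- setdiff(seq_along(y), unique(idx))
      if (length(unique(y[oob])) == 2) break
      if (try == 10) stop("could not draw a bootstrap with a two-class out-of-bag set")
    }
    co <- ensemble_logistic(X, y, idx)
    sc <- plogis(drop(cbind(1, X[oob, , drop = FALSE]) %*% co))
    oob_aucs[b] <- roc_metrics(sc, y[oob])$auc
  }
  auc_oob <- mean(oob_aucs)
  combine_632plus(auc_app, auc_oob,
                  se = sd(oob_aucs) / sqrt(sum(!is.na(oob_aucs))))
}

#' The 0.632+ combination rule
#'
#' Pure closed-form combination of an apparent and an out-of-bag AUC; used
#' by [auc_632plus()] and directly testable against hand-evaluated cases.
#'
#' @param auc_app apparent (resubstitution) AUC.
#' @param auc_oob out-of-bag AUC.
#' @param se optional standard error carried through.
#' @return list with `estimate`, `auc_app`, `auc_oob`, `w`, `R`, `se`.
#' @export
combine_632plus <- function(auc_app, auc_oob, se = NA_real_) {
  oob_prime <- max(auc_oob, 0.5)
  R <- if (auc_app - 0.5 > 0) (auc_app - oob_prime) / (auc_app - 0.5) else 0
  R <- min(1, max(0, R))
  w <- 0.632 / (1 - 0.368 * R)
  list(estimate = (1 - w) * auc_app + w * oob_prime,
       auc_app = auc_app, auc_oob = auc_oob, w = w, R = R, se = se)
}

#' Forward feature selection maximizing the 0.632+ bootstrap AUC
#'
#' Builds nested models of orders 1..`max_order`: the order-k model is the
#' best order-(k-1) model plus the candidate from the reduced set that
#' maximizes [auc_632plus()]; ties keep the candidate ranked earlier in the
#' reduced set.
#'
#' @param reduced a [reduce_feature_set()] result (or character vector of
#'   candidate names in rank order).
#' @param table feature table with the outcome column.
#' @param outcome binary outcome column name.
#' @param max_order largest model order (truncated with a warning when the
#'   reduced set is smaller).
#' @param n_boot bootstrap samples per candidate evaluation.
#' @param rng_seed integer seed.
#' @return list of class `forward_selection`: per-order `features`,
#'   `estimate`, `se`.
#' @export
forward_select <- function(reduced, table, outcome = "event", max_order = 10L,
                           n_boot = 100L, rng_seed = 1L) {
  cand <- if (is.character(reduced)) reduced else reduced$feature
  if (max_order > length(cand)) {
    warning("max_order exceeds the reduced set size; truncating to ",
            length(cand))
    max_order <- length(cand)
  }
  sel <- character(0)
  orders <- vector("list", max_order)
  for (k in seq_len(max_order)) {
    remaining <- setdiff(cand, sel)
    best <- NULL
    for (f in remaining) {  # reduced-set order => earlier rank wins ties
      est <- auc_632plus(table, c(sel, f), outcome, n_boot,
                         rng_seed = rng_seed + 131L * k)
      if (is.null(best) || est$estimate > best$est$estimate)
        best <- list(f = f, est = est)
    }
    sel <- c(sel, best$f)
    orders[[k]] <- list(features = sel, estimate = best$est$estimate,
                        se = best$est$se, auc_app = best$est$auc_app,
                        auc_oob = best$est$auc_oob)
  }
  structure(orders, class = "forward_selection")
}

#' Choose the model order with the best parsimony
#'
#' Automatic one-standard-error rule: the smallest order whose 0.632+
#' estimate is at least the maximum estimate minus one standard error of the
#' maximum. A manual `override` order is honoured when given.
#'
#' @param selection a [forward_select()] result.
#' @param override optional manually chosen order.
#' @return the chosen order (integer).
#' @export
choose_order <- function(selection, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  est <- vapply(selection, `[[`, numeric(1), "estimate")
  se <- vapply(selection, `[[`, numeric(1), "se")
  kmax <- which.max(est)
  thr <- est[kmax] - ifelse(is.finite(se[kmax]), se[kmax], 0)
  min(which(est >= thr))
}

#' Final bootstrap-averaged logistic model
#'
#' Fits the chosen feature combination on `n_boot` stratified bootstrap
#' samples, each with the balanced partition-ensemble adjustment
#' (coefficients averaged across partitions), and averages the coefficients
#' across bootstraps. Zero-variance features get coefficient 0 with a
#' warning; separation-induced divergence falls back to a tiny-ridge fit.
#'
#' @param table feature table with the outcome column.
#' @param features chosen feature names.
#' @param outcome binary outcome column name.
#' @param n_boot bootstrap samples.
#' @param rng_seed integer seed.
#' @return object of class `logistic_model` with `features`, `intercept`,
#'   `coefficients`, `n_boot`, `rng_seed`. Supports `predict(model, table)`
#'   returning event probabilities.
#' @export
finalize_logistic <- function(table, features, outcome = "event",
                              n_boot = 100L, rng_seed = 1L) {
  X <- as.matrix(table[, features, drop = FALSE])
  y <- table[[outcome]]
  if (any(apply(X, 2, var) == 0))
    warning("zero-variance feature(s): ",
            paste(features[apply(X, 2, var) == 0], collapse = ", "),
            "; coefficients set to 0")
  set.seed(rng_seed)
  coefs <- vapply(seq_len(n_boot), function(b) {
    idx <- if (n_boot == 1) seq_along(y) else stratified_bootstrap(y)
    ensemble_logistic(X, y, idx)
  }, numeric(ncol(X) + 1))
  co <- rowMeans(coefs)
  structure(list(features = features, intercept = co[1],
                 coefficients = setNames(co[-1], features),
                 outcome = outcome, n_boot = n_boot, rng_seed = rng_seed),
            class = "logistic_model")
}

#' @export
predict.logistic_model <- function(object, newdata, type = c("prob", "link"),
                                   ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  eta <- drop(object$intercept + X %*% object$coefficients)
  if (type == "link") eta else plogis(eta)
}

#' Serialize / reload a logistic model as JSON
#'
#' @param model a `logistic_model`.
#' @param path JSON path.
#' @return `path` invisibly; `read_logistic_model` returns the model.
#' @export
write_logistic_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_logistic_model
#' @export
read_logistic_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$coefficients <- setNames(as.numeric(m$coefficients), m$features)
  structure(m, class = "logistic_model")
}
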