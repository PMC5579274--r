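#' Spearman rank correlation with a binary or continuous response
#'
#' Midranks handle ties; p-values are two-sided, computed exactly for small
#' untied samples and by the t approximation otherwise (the `cor.test`
#' convention). Constant inputs have no defined rank correlation and return
#' `r_s = 0`, `p = 1` with `degenerate = TRUE`.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with `r_s`, `p` and `degenerate`.
#' @export
spearman_assoc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r_s = 0, p = 1, degenerate = TRUE))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(r_s = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up significance flags
#'
#' Flags every hypothesis whose BH-adjusted p-value is at most the false
#' discovery rate `q` — equivalently the step-up rule over ordered p-values.
#'
#' @param p vector of p-values.
#' @param q false discovery rate.
#' @return logical vector of the same length as `p`.
#' @export
benjamini_hochberg <- function(p, q = 0.10) {
  if (length(p) == 0) return(logical(0))
  p.adjust(p, method = "BH") <= q
}

#' ROC metrics at a probability threshold
#'
#' AUC is the Mann-Whitney statistic scaled to \[0, 1\] (ties count 1/2);
#' sensitivity, specificity and accuracy are computed by thresholding the
#' scores (predicted event when score > threshold).
#'
#' @param scores numeric risk scores or probabilities.
#' @param labels binary outcomes (0/1).
#' @param threshold classification threshold on `scores`.
#' @return list with `auc`, `sensitivity`, `specificity`, `accuracy`.
#' @export
roc_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both outcome classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores > threshold)
  list(auc = auc,
       sensitivity = sum(pred == 1 & labels == 1) / n1,
       specificity = sum(pred == 0 & labels == 0) / n0,
       accuracy = mean(pred == labels))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors evaluated on the same subjects,
#' using the DeLong covariance of the paired ROC curves (via
#' [pROC::roc.test()]). A zero-variance difference (e.g. identical
#' predictors) returns p = 1.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared binary outcomes.
#' @return two-sided p-value.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  if (isTRUE(all.equal(as.numeric(scores_a), as.numeric(scores_b))))
    return(1)
  ra <- pROC::roc(labels, scores_a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(labels, scores_b, quiet = TRUE, direction = "<")
  p <- tryCatch(pROC::roc.test(ra, rb, method = "delong", paired = TRUE)$p.value,
                error = function(e) NaN)
  if (!is.finite(p)) 1 else p
}

#' Harrell's concordance index for risk scores
#'
#' The probability that, of a permissible subject pair (the earlier time is
#' an observed event), the subject failing earlier carries the higher risk
#' score; score ties count 1/2. Computed with [survival::concordance()]
#' (`reverse = TRUE`, so larger scores mean higher risk).
#'
#' @param risk_scores numeric risk scores (higher = riskier).
#' @param time_months follow-up times.
#' @param event binary event flags.
#' @return concordance index in \[0, 1\].
#' @export
concordance_index <- function(risk_scores, time_months, event) {
  stopifnot(length(risk_scores) == length(time_months),
            length(time_months) == length(event))
  cfit <- survival::concordance(
    survival::Surv(time_months, event) ~ risk_scores, reverse = TRUE)
  n_pairs <- sum(cfit$count[c("concordant", "discordant", "tied.x")])
  if (n_pairs == 0) stop("no permissible pairs for the concordance index")
  unname(cfit$concordance)
}

#' Kaplan-Meier curves and log-rank comparison of risk groups
#'
#' Fits product-limit curves per group and tests their difference with the
#' log-rank statistic (chi-square with G - 1 df). With three or more groups,
#' unadjusted pairwise log-rank p-values are also reported.
#'
#' @param groups group labels (factor or character), all groups non-empty.
#' @param time_months follow-up times.
#' @param event binary event flags (at least one event overall).
#' @return list with `fit` (a [survival::survfit()] object), `chisq`, `p`,
#'   and `pairwise` (data.frame of group pairs and p-values, or NULL).
#' @export
km_logrank <- function(groups, time_months, event) {
  groups <- factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2)
    stop("at least two non-empty groups are required")
  if (sum(event) < 1) stop("at least one event is required for the log-rank test")
  df <- data.frame(time = time_months, event = event, group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- pchisq(sd0$chisq, df = nlevels(groups) - 1, lower.tail = FALSE)
  pairwise <- NULL
  if (nlevels(groups) > 2) {
    combs <- utils::combn(levels(groups), 2)
    pairwise <- data.frame(group1 = combs[1, ], group2 = combs[2, ], p = NA_real_)
    for (k in seq_len(ncol(combs))) {
      sub <- df[df$group %in% combs[, k], ]
      if (sum(sub$event) == 0) next
      sdk <- survival::survdiff(survival::Surv(time, event) ~ group, data = sub)
      pairwise$p[k] <- pchisq(sdk$chisq, df = 1, lower.tail = FALSE)
    }
  }
  list(fit = fit, chisq = unname(sd0$chisq), p = p, pairwise = pairwise)
}
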