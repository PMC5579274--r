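#' Run configuration for the canonical pipelines
#'
#' Bundles every tunable setting of the end-to-end workflow with defaults
#' matching the standard methodology: 25-feature reduced sets, model orders
#' 1--10, 100 bootstrap samples, the 16-value minority weight grid, 10
#' stratified sub-sampling splits at a 2:1 ratio, and an FDR of 10% for the
#' univariate screen. A single master seed fans out deterministically to
#' per-stage seeds.
#'
#' @param master_seed integer master seed.
#' @param target_size reduced feature-set size.
#' @param max_order largest logistic model order.
#' @param n_boot bootstrap samples for selection and final fits.
#' @param tune_n_boot bootstrap samples per forest during weight/staging
#'   tuning.
#' @param splits stratified sub-sampling repetitions.
#' @param ratio sub-train:sub-test ratio.
#' @param q_fdr false discovery rate of the univariate screen.
#' @param interp,distance_weight extraction conventions, see
#'   [extraction_config()].
#' @return named list of class `radrisk_config`.
#' @export
radrisk_config <- function(master_seed = 1L, target_size = 25L,
                           max_order = 10L, n_boot = 100L, tune_n_boot = 10L,
                           splits = 10L, ratio = 2, q_fdr = 0.10,
                           interp = "cubic", distance_weight = TRUE) {
  structure(list(master_seed = as.integer(master_seed),
                 target_size = target_size, max_order = max_order,
                 n_boot = n_boot, tune_n_boot = tune_n_boot, splits = splits,
                 ratio = ratio, q_fdr = q_fdr, interp = interp,
                 distance_weight = distance_weight,
                 weight_grid = weight_grid()),
            class = "radrisk_config")
}

# Deterministic master-seed fan-out: each named stage gets its own seed so
# stages are individually reproducible. Kept below 2^31 - 1.
stage_seed <- function(config, stage) {
  stages <- c(simulate = 1L, extract = 2L, univariate = 3L, reduce = 4L,
              select = 5L, finalize = 6L, forest = 7L, tune = 8L,
              evaluate = 9L)
  k <- stages[[stage]]
  as.integer((as.double(config$master_seed) * 1009 + 97 * k) %% 2147483629)
}

#' Read / write a run configuration as YAML
#'
#' @param config a [radrisk_config()].
#' @param path YAML file path.
#' @return `write_config_yaml` returns `path` invisibly; `read_config_yaml`
#'   returns the validated `radrisk_config`.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(radrisk_config))
  do.call(radrisk_config, raw[intersect(names(raw), known)])
}

#' Extract the feature battery for a set of cases
#'
#' Runs [extract_battery()] on every case; a failing case (e.g. shape or
#' spacing mismatch between its volume and mask) is reported and skipped
#' while the run continues, with a summary warning at the end.
#'
#' @param cases named list; each element a list with `vol` and `mask`.
#' @param config a [radrisk_config()].
#' @return data.frame: `patient_id` plus 1615 feature columns, with
#'   attribute `failures` (named character vector of per-case errors).
#' @export
run_extract <- function(cases, config = radrisk_config()) {
  if (length(cases) == 0) stop("empty case list")
  ids <- names(cases)
  if (is.null(ids)) ids <- sprintf("case%03d", seq_along(cases))
  excfg <- extraction_config(interp = config$interp,
                             distance_weight = config$distance_weight)
  rows <- list()
  failures <- character(0)
  for (i in seq_along(cases)) {
    fv <- tryCatch(extract_battery(cases[[i]]$vol, cases[[i]]$mask,
                                   config = excfg),
                   error = function(e) conditionMessage(e))
    if (is.character(fv)) failures[ids[i]] <- fv else rows[[ids[i]]] <- fv
  }
  if (length(failures))
    warning(length(failures), "/", length(cases), " case(s) failed: ",
            paste(names(failures), collapse = ", "))
  if (length(rows) == 0) stop("no case could be extracted")
  out <- cbind(data.frame(patient_id = names(rows)),
               as.data.frame(do.call(rbind, rows), check.names = FALSE))
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

#' Univariate association screen with FDR control
#'
#' Joins a feature table to an outcomes table by `patient_id`, computes the
#' Spearman association of every feature with the binary outcome, and flags
#' significance with the Benjamini-Hochberg procedure.
#'
#' @param features data.frame with `patient_id` and feature columns.
#' @param outcomes data.frame with `patient_id` and the outcome column.
#' @param outcome binary outcome column name.
#' @param q false discovery rate.
#' @return data.frame (`feature`, `r_s`, `p`, `significant`) of class
#'   `univariate_report`, with a `family_summary` attribute giving the
#'   significant fraction per texture family / feature group.
#' @export
run_univariate <- function(features, outcomes, outcome = "event", q = 0.10) {
  unmatched <- setdiff(features$patient_id, outcomes$patient_id)
  if (length(unmatched))
    stop("patients without outcomes: ", paste(unmatched, collapse = ", "))
  tab <- merge(features, outcomes[, c("patient_id", outcome)],
               by = "patient_id")
  if (nrow(tab) == 0) stop("no patients after joining features and outcomes")
  feat_names <- setdiff(names(features), "patient_id")
  y <- tab[[outcome]]
  res <- lapply(feat_names, function(f) spearman_assoc(tab[[f]], y))
  rep <- data.frame(feature = feat_names,
                    r_s = vapply(res, `[[`, numeric(1), "r_s"),
                    p = vapply(res, `[[`, numeric(1), "p"))
  rep$significant <- benjamini_hochberg(rep$p, q)
  fam <- sub("_.*$", "", rep$feature)
  fam[!fam %in% c("GLCM", "GLRLM", "GLSZM", "NGTDM")] <- "other"
  summary <- aggregate(significant ~ family,
                       data = data.frame(family = fam,
                                         significant = rep$significant),
                       FUN = base::mean)
  attr(rep, "family_summary") <- summary
  class(rep) <- c("univariate_report", "data.frame")
  rep
}

#' Train the canonical outcome model bundle
#'
#' The radiomic pipeline on a designated training table: Gain-based
#' reduction, 0.632+ forward selection over model orders, the one-SE order
#' choice, and the final bootstrap-averaged logistic model. When clinical
#' variables are supplied, a partition-ensemble random forest combining the
#' selected radiomic features with the clinical variables is also trained,
#' optionally after minority-weight tuning.
#'
#' @param table training feature table with outcome columns.
#' @param outcome binary outcome column name.
#' @param features candidate radiomic feature names (default: all numeric
#'   non-outcome columns).
#' @param clinical clinical variable names for the combined forest, or NULL.
#' @param tune_w tune the minority weight over the grid (slow); otherwise
#'   `w = 1`.
#' @param config a [radrisk_config()].
#' @return list of class `risk_model_bundle`: `logistic`, `forest` (or
#'   NULL), `selection`, `order`, `reduced`, `train_ids`, `config`, `w`.
#' @export
run_train <- function(table, outcome = "event", features = NULL,
                      clinical = NULL, tune_w = FALSE,
                      config = radrisk_config()) {
  reduced <- reduce_feature_set(table, outcome, features,
                                target_size = config$target_size)
  selection <- forward_select(reduced, table, outcome,
                              max_order = min(config$max_order,
                                              nrow(reduced)),
                              n_boot = config$n_boot,
                              rng_seed = stage_seed(config, "select"))
  k <- choose_order(selection)
  model <- finalize_logistic(table, selection[[k]]$features, outcome,
                             n_boot = config$n_boot,
                             rng_seed = stage_seed(config, "finalize"))
  forest <- NULL
  w <- 1
  if (!is.null(clinical)) {
    feats <- c(selection[[k]]$features, clinical)
    if (tune_w) {
      tw <- tune_weight(table, feats, outcome, grid = config$weight_grid,
                        splits = config$splits, ratio = config$ratio,
                        n_boot = config$tune_n_boot,
                        rng_seed = stage_seed(config, "tune"))
      w <- tw$w
    }
    forest <- train_forest(table, feats, outcome, n_boot = config$n_boot,
                           w = w, rng_seed = stage_seed(config, "forest"))
  }
  structure(list(logistic = model, forest = forest, selection = selection,
                 order = k, reduced = reduced,
                 train_ids = table$patient_id, config = config, w = w),
            class = "risk_model_bundle")
}

#' Evaluate a model bundle on a designated testing table
#'
#' Computes prediction metrics (AUC, sensitivity, specificity, accuracy at
#' threshold 0.5), the concordance index against time-to-event data, and
#' Kaplan-Meier log-rank p-values for the two-group (probability 0.5) and
#' three-group (1/3, 2/3) stratifications of the forest output. Training
#' and testing sets must not share subjects; evaluating on the training
#' table itself is flagged as resubstitution in the report.
#'
#' @param bundle a [run_train()] result.
#' @param table testing feature table with outcome and survival columns.
#' @param outcome binary outcome column name.
#' @return list of class `evaluation_report` with `logistic`, `forest`
#'   (each: metrics, concordance), `km_two`, `km_three`, `risk_report`
#'   (per-subject id, probability, group) and `resubstitution`.
#' @export
run_evaluate <- function(bundle, table, outcome = "event") {
  resub <- !is.null(bundle$train_ids) && !is.null(table$patient_id) &&
    setequal(bundle$train_ids, table$patient_id)
  overlap <- intersect(bundle$train_ids, table$patient_id)
  if (!resub && length(overlap) > 0)
    stop("training and testing sets share subjects: ",
         paste(head(overlap, 5), collapse = ", "))
  y <- table[[outcome]]
  out <- list(resubstitution = resub)

  p_log <- predict(bundle$logistic, table)
  out$logistic <- list(metrics = roc_metrics(p_log, y),
                       concordance = concordance_index(p_log,
                                                       table$time_months, y))
  if (!is.null(bundle$forest)) {
    p_rf <- predict(bundle$forest, table)
    out$forest <- list(metrics = roc_metrics(p_rf, y),
                       concordance = concordance_index(p_rf,
                                                       table$time_months, y))
    g2 <- assess_risk(p_rf, "two")
    g3 <- assess_risk(p_rf, "three")
    out$km_two <- if (nlevels(droplevels(g2)) == 2 && sum(y) > 0)
      km_logrank(g2, table$time_months, y) else NULL
    out$km_three <- if (nlevels(droplevels(g3)) >= 2 && sum(y) > 0)
      km_logrank(droplevels(g3), table$time_months, y) else NULL
    out$risk_report <- data.frame(patient_id = table$patient_id,
                                  prob_RF = p_rf, group_two = g2,
                                  group_three = g3)
  }
  class(out) <- "evaluation_report"
  out
}

#' Write a run manifest recording config, seed and package version
#'
#' Identical manifests imply identical pipeline outputs: the manifest hash
#' covers the full configuration (including the master seed).
#'
#' @param config a [radrisk_config()].
#' @param path output JSON path.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(config, path) {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(config = unclass(config),
                   config_md5 = unname(tools::md5sum(tmp)),
                   package_version = as.character(utils::packageVersion("radrisk")),
                   r_version = R.version.string)
  unlink(tmp)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
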