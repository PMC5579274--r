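#' @title Partition-ensemble random forests and prognostic baselines
#' @description Forests that combine continuous radiomic variables with
#'   categorical clinical variables under the balanced-partition imbalance
#'   adjustment: every bootstrap sample is split into `P` balanced
#'   partitions and each partition grows one tree, so the forest size is the
#'   sum of partition counts over bootstraps. Minority under/oversampling
#'   weights refine the balance inside each partition.
#' @name forest_models
NULL

# One-hot encoding of a feature subset: numeric columns pass through,
# factors/characters expand to one indicator column per category.
encode_features <- function(table, features) {
  cols <- lapply(features, function(f) {
    v <- table[[f]]
    if (is.null(v)) stop("missing feature column: ", f)
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, f))
    } else {
      v <- factor(v)
      m <- sapply(levels(v), function(l) as.numeric(v == l))
      colnames(m) <- paste0(f, "=", levels(v))
    }
    m
  })
  do.call(cbind, cols)
}

#' Train an imbalance-adjusted random forest
#'
#' For each of `n_boot` class-stratified bootstrap samples, a balanced
#' partition plan is drawn ([plan_partitions()]), the minority weight `w` is
#' applied within each partition ([apply_class_weight()]), and one CART-style
#' tree (Gini impurity, `mtry = ceiling(sqrt(p))`, unlimited depth, minimum
#' node size 1) is grown per partition. The forest probability of event is
#' the fraction of trees voting for the event class.
#'
#' @param table feature table (numeric and/or categorical columns).
#' @param features feature names entering the forest.
#' @param outcome binary outcome column name.
#' @param n_boot number of bootstrap samples.
#' @param w minority under/oversampling weight in \[0.5, 2\].
#' @param rng_seed integer seed.
#' @param mtry variables tried per split (default `ceiling(sqrt(p))` on the
#'   one-hot encoded design).
#' @return object of class `imbalanced_forest` with `trees`, `partition_ids`
#'   (bootstrap index per tree), `n_trees`, `w`, `feature_schema`.
#' @export
train_forest <- function(table, features, outcome = "event", n_boot = 100L,
                         w = 1, rng_seed = 1L, mtry = NULL) {
  y <- table[[outcome]]
  stopifnot(all(y %in% 0:1))
  if (sum(y == 1) == 0) stop("no events in the training set")
  X <- encode_features(table, features)
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(X)))
  set.seed(rng_seed)
  trees <- list()
  part_ids <- integer(0)
  for (b in seq_len(n_boot)) {
    idx <- if (n_boot == 1) seq_along(y) else stratified_bootstrap(y)
    pos <- idx[y[idx] == 1]
    neg <- idx[y[idx] == 0]
    plan <- plan_partitions(neg, pos)
    for (part in plan$partitions) {
      if (w != 1) part <- apply_class_weight(part, plan$minority_idx, w)
      tree <- randomForest::randomForest(
        X[part, , drop = FALSE], factor(y[part], levels = c(0, 1)),
        ntree = 1, mtry = min(mtry, ncol(X)), replace = FALSE,
        sampsize = length(part), nodesize = 1)
      trees[[length(trees) + 1L]] <- tree
      part_ids <- c(part_ids, b)
    }
  }
  structure(list(trees = trees, partition_ids = part_ids,
                 n_trees = length(trees), w = w, features = features,
                 feature_schema = colnames(X), outcome = outcome,
                 n_boot = n_boot, rng_seed = rng_seed),
            class = "imbalanced_forest")
}

#' @export
predict.imbalanced_forest <- function(object, newdata, type = c("prob", "votes"),
                                      ...) {
  type <- match.arg(type)
  X <- encode_features(newdata, object$features)
  if (!identical(colnames(X), object$feature_schema))
    X <- align_schema(X, object$feature_schema)
  votes <- vapply(object$trees, function(tr)
    predict(tr, X) == "1", logical(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  if (type == "votes") votes else rowMeans(votes)
}

# Test-time categories can differ from training; align to the training
# one-hot schema, filling unseen columns with zeros.
align_schema <- function(X, schema) {
  out <- matrix(0, nrow(X), length(schema), dimnames = list(NULL, schema))
  shared <- intersect(colnames(X), schema)
  out[, shared] <- X[, shared, drop = FALSE]
  out
}

# Class-stratified sub-train / sub-test split preserving the event
# proportion (train fraction = ratio/(ratio+1) for a ratio:1 split).
stratified_split <- function(y, ratio = 2) {
  frac <- ratio / (ratio + 1)
  train <- unlist(lapply(split(seq_along(y), y), function(ix)
    sample(ix, round(frac * length(ix)))))
  list(train = sort(train), test = setdiff(seq_along(y), train))
}

#' Tune the minority class weight by stratified random sub-sampling
#'
#' Splits the training table `splits` times into sub-training and
#' sub-testing sets (2:1 by default, equal event proportion), trains a
#' forest per candidate weight on each sub-training set, and returns the
#' weight with the maximal mean sub-test AUC (ties go to the smaller
#' weight).
#'
#' @param table,features,outcome as in [train_forest()].
#' @param grid candidate weights, default [weight_grid()].
#' @param splits number of random sub-sampling repetitions.
#' @param ratio sub-train:sub-test size ratio.
#' @param n_boot bootstrap samples per tuning forest.
#' @param rng_seed integer seed.
#' @return list with `w` (best weight) and `auc` (mean AUC per grid value).
#' @export
tune_weight <- function(table, features, outcome = "event",
                        grid = weight_grid(), splits = 10L, ratio = 2,
                        n_boot = 10L, rng_seed = 1L) {
  stopifnot(length(grid) >= 1)
  y <- table[[outcome]]
  set.seed(rng_seed)
  seeds <- sample.int(.Machine$integer.max %/% 2, splits)
  aucs <- matrix(NA_real_, splits, length(grid))
  for (s in seq_len(splits)) {
    set.seed(seeds[s])
    sp <- stratified_split(y, ratio)
    for (k in seq_along(grid)) {
      fo <- train_forest(table[sp$train, , drop = FALSE], features, outcome,
                         n_boot = n_boot, w = grid[k],
                         rng_seed = seeds[s] + k)
      pr <- predict(fo, table[sp$test, , drop = FALSE])
      aucs[s, k] <- roc_metrics(pr, y[sp$test])$auc
    }
  }
  mean_auc <- colMeans(aucs)
  list(w = grid[which.max(mean_auc)], auc = setNames(mean_auc, grid))
}

#' Select the best group of staging variables
#'
#' Evaluates candidate staging-variable groups (by default T, N, T+N, TNM)
#' combined with the base clinical variables (age and tumour site) in a
#' forest, by stratified random sub-sampling, and picks the group with the
#' maximal mean sub-test AUC. Candidates referencing missing columns are
#' skipped with a warning; equal performance resolves to the earlier
#' candidate in the list.
#'
#' @param table clinical table with the outcome column.
#' @param outcome binary outcome column name.
#' @param base base clinical variables included with every candidate.
#' @param candidates list of character vectors of staging column names.
#' @param splits,ratio,n_boot,rng_seed as in [tune_weight()].
#' @return list with `staging` (chosen group), `auc` (mean AUC per
#'   candidate).
#' @export
select_staging <- function(table, outcome = "event",
                           base = c("age", "hn_type"),
                           candidates = list("t_stage", "n_stage",
                                             c("t_stage", "n_stage"),
                                             "tnm_stage"),
                           splits = 10L, ratio = 2, n_boot = 10L,
                           rng_seed = 1L) {
  ok <- vapply(candidates, function(cc) all(cc %in% names(table)), logical(1))
  if (any(!ok))
    warning("skipping staging candidate(s) with missing columns: ",
            paste(vapply(candidates[!ok], paste, "", collapse = "+"),
                  collapse = ", "))
  candidates <- candidates[ok]
  if (length(candidates) == 0) stop("no usable staging candidates")
  y <- table[[outcome]]
  set.seed(rng_seed)
  seeds <- sample.int(.Machine$integer.max %/% 2, splits)
  aucs <- matrix(NA_real_, splits, length(candidates))
  for (s in seq_len(splits)) {
    set.seed(seeds[s])
    sp <- stratified_split(y, ratio)
    for (k in seq_along(candidates)) {
      feats <- c(base, candidates[[k]])
      fo <- train_forest(table[sp$train, , drop = FALSE], feats, outcome,
                         n_boot = n_boot, rng_seed = seeds[s] + k)
      pr <- predict(fo, table[sp$test, , drop = FALSE])
      aucs[s, k] <- roc_metrics(pr, y[sp$test])$auc
    }
  }
  mean_auc <- colMeans(aucs)
  labels <- vapply(candidates, paste, "", collapse = "+")
  list(staging = candidates[[which.max(mean_auc)]],
       auc = setNames(mean_auc, labels))
}

#' Permutation importance of forest variables
#'
#' Importance of a variable is the mean drop in AUC when its column is
#' randomly permuted across subjects (`n_perm` permutations), leaving all
#' other variables intact.
#'
#' @param forest a fitted [train_forest()] model.
#' @param table evaluation table.
#' @param outcome binary outcome column name.
#' @param n_perm permutations per variable.
#' @param rng_seed integer seed.
#' @return named numeric vector of mean AUC drops per variable.
#' @export
permutation_importance <- function(forest, table, outcome = "event",
                                   n_perm = 20L, rng_seed = 1L) {
  y <- table[[outcome]]
  base_auc <- roc_metrics(predict(forest, table), y)$auc
  set.seed(rng_seed)
  drops <- vapply(forest$features, function(f) {
    mean(vapply(seq_len(n_perm), function(i) {
      tp <- table
      tp[[f]] <- sample(tp[[f]])
      base_auc - roc_metrics(predict(forest, tp), y)$auc
    }, numeric(1)))
  }, numeric(1))
  drops
}

#' Cox proportional-hazards linear risk model
#'
#' Fits a linear Cox model on the given features and stores the training-set
#' median of the linear predictor as the two-group stratification threshold
#' for later test sets.
#'
#' @param table feature table with survival columns.
#' @param features covariate names (numeric).
#' @param time_col,event_col survival column names.
#' @return object of class `cox_linear_model` with the `survival::coxph`
#'   fit, `features` and `median_lp`. `predict()` returns the linear
#'   predictor; [assess_risk_cox()] applies the stored median split.
#' @export
fit_cox_linear <- function(table, features, time_col = "time_months",
                           event_col = "event") {
  df <- table[, c(features, time_col, event_col)]
  fml <- stats::as.formula(paste0("survival::Surv(", time_col, ", ", event_col,
                                  ") ~ ", paste(features, collapse = " + ")))
  fit <- survival::coxph(fml, data = df)
  if (anyNA(fit$coefficients)) {
    # zero-variance covariates are dropped by coxph; report them as 0
    fit$coefficients[is.na(fit$coefficients)] <- 0
  }
  lp <- drop(as.matrix(table[, features, drop = FALSE]) %*% fit$coefficients)
  structure(list(fit = fit, features = features,
                 coefficients = fit$coefficients, median_lp = median(lp)),
            class = "cox_linear_model")
}

#' @export
predict.cox_linear_model <- function(object, newdata, ...) {
  drop(as.matrix(newdata[, object$features, drop = FALSE]) %*%
         object$coefficients)
}

#' Risk-group assignment from a forest output probability
#'
#' Two-group mode assigns low risk for probabilities up to 0.5 and high risk
#' above; three-group mode uses left-closed intervals at 1/3 and 2/3, with
#' probability 1 included in the high-risk group.
#'
#' @param prob_rf event probabilities in \[0, 1\].
#' @param mode `"two"` or `"three"`.
#' @return factor of risk groups.
#' @export
assess_risk <- function(prob_rf, mode = c("two", "three")) {
  mode <- match.arg(mode)
  stopifnot(all(prob_rf >= 0 & prob_rf <= 1))
  if (mode == "two") {
    factor(ifelse(prob_rf > 0.5, "high", "low"), levels = c("low", "high"))
  } else {
    factor(ifelse(prob_rf < 1 / 3, "low",
                  ifelse(prob_rf < 2 / 3, "medium", "high")),
           levels = c("low", "medium", "high"))
  }
}

#' @rdname assess_risk
#' @param lp Cox linear predictors.
#' @param model a [fit_cox_linear()] model carrying the training median.
#' @export
assess_risk_cox <- function(lp, model) {
  factor(ifelse(lp > model$median_lp, "high", "low"),
         levels = c("low", "high"))
}
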