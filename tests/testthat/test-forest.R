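test_that("forest size equals the sum of partition counts over bootstraps", {
  # 10 events vs 30 non-events: stratified bootstraps keep the 1:3 ratio,
  # so every bootstrap yields P = 3 partitions
  tab <- make_cohort(n = 40, event_rate = 0.25, beta = c(sig1 = 1),
                     n_noise = 1, rng_seed = 11)
  tab$event <- c(rep(1, 10), rep(0, 30))
  fo <- train_forest(tab, c("sig1", "noise01"), n_boot = 2, rng_seed = 1)
  expect_equal(fo$n_trees, 6L)
  expect_equal(fo$partition_ids, rep(1:2, each = 3))
})

test_that("the forest probability is the exact mean of binary tree votes", {
  tab <- make_cohort(n = 60, event_rate = 0.3, beta = c(sig1 = 2),
                     n_noise = 1, rng_seed = 4)
  fo <- train_forest(tab, c("sig1", "noise01"), n_boot = 3, rng_seed = 2)
  votes <- predict(fo, tab, type = "votes")
  expect_equal(predict(fo, tab), rowMeans(votes), tolerance = 1e-12)
  expect_equal(ncol(votes), fo$n_trees)
  expect_true(all(predict(fo, tab) >= 0 & predict(fo, tab) <= 1))
})

test_that("forests are deterministic under a fixed seed and error without events", {
  tab <- make_cohort(n = 50, event_rate = 0.3, beta = c(sig1 = 1.5),
                     n_noise = 1, rng_seed = 6)
  f1 <- train_forest(tab, "sig1", n_boot = 2, rng_seed = 9)
  f2 <- train_forest(tab, "sig1", n_boot = 2, rng_seed = 9)
  expect_equal(predict(f1, tab), predict(f2, tab), tolerance = 1e-12)

  tab0 <- tab; tab0$event <- 0L
  expect_error(train_forest(tab0, "sig1", n_boot = 1), "events")
})

test_that("categorical clinical variables are one-hot encoded and survive unseen levels", {
  tab <- make_cohort(n = 80, event_rate = 0.25, beta = c(sig1 = 1.5),
                     n_noise = 0, clinical = TRUE, rng_seed = 8)
  fo <- train_forest(tab, c("sig1", "hn_type", "t_stage"), n_boot = 2,
                     rng_seed = 1)
  expect_true(any(grepl("hn_type=", fo$feature_schema)))
  sub <- tab[tab$hn_type != "larynx", ]  # fewer observed categories at test time
  expect_length(predict(fo, sub), nrow(sub))
})

test_that("risk groups follow the probability thresholds and boundary rules", {
  p <- c(0.2, 1 / 3, 0.5, 0.51, 2 / 3, 1.0)
  expect_equal(as.character(assess_risk(p, "two")),
               c("low", "low", "low", "high", "high", "high"))
  expect_equal(as.character(assess_risk(p, "three")),
               c("low", "medium", "medium", "medium", "high", "high"))
  expect_error(assess_risk(c(-0.1)), "prob")
})

test_that("weight tuning enumerates the grid and degenerates correctly", {
  expect_length(weight_grid(), 16L)
  tab <- make_cohort(n = 60, event_rate = 0.3, beta = c(sig1 = 2),
                     n_noise = 1, rng_seed = 3)
  tw <- tune_weight(tab, "sig1", grid = 1.2, splits = 2, n_boot = 3,
                    rng_seed = 1)
  expect_equal(tw$w, 1.2)
  expect_length(tw$auc, 1L)
})

test_that("staging selection picks the driving stage variable and skips missing columns", {
  hits <- 0
  for (seed in 1:5) {
    tab <- make_cohort(n = 200, event_rate = 0.25, beta = c(n_stage = 2.5),
                       n_noise = 0, clinical = TRUE, rng_seed = seed)
    sel <- select_staging(tab, splits = 8, n_boot = 10, rng_seed = seed)
    if (identical(sel$staging, "n_stage")) hits <- hits + 1
  }
  expect_gte(hits, 4)

  tab2 <- make_cohort(n = 60, event_rate = 0.3, clinical = TRUE, rng_seed = 1)
  tab2$tnm_stage <- NULL
  expect_warning(sel2 <- select_staging(tab2, splits = 1, n_boot = 2,
                                        rng_seed = 1), "skip")
  expect_length(sel2$auc, 3L)
})

test_that("permutation importance separates signal from noise", {
  tab <- make_cohort(n = 150, event_rate = 0.3, beta = c(sig1 = 2.5),
                     n_noise = 1, rng_seed = 10)
  heldout <- make_cohort(n = 150, event_rate = 0.3, beta = c(sig1 = 2.5),
                         n_noise = 1, rng_seed = 11)
  fo <- train_forest(tab, c("sig1", "noise01"), n_boot = 10, rng_seed = 2)
  # held-out evaluation: the training set would credit noise with its
  # overfit in-sample contribution
  imp <- permutation_importance(fo, heldout, n_perm = 20, rng_seed = 3)
  expect_equal(names(which.max(imp)), "sig1")
  expect_lte(abs(imp["noise01"]), 0.05)
  # permuting everything jointly destroys all discrimination
  set.seed(4)
  shuffled <- heldout
  for (f in c("sig1", "noise01")) shuffled[[f]] <- sample(shuffled[[f]])
  expect_lt(abs(roc_metrics(predict(fo, shuffled), heldout$event)$auc - 0.5),
            0.1)
})

test_that("the Cox baseline recovers a known hazard ratio and the median split rule", {
  set.seed(55)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, rate = 0.05 * 2^x)  # covariate doubles the hazard
  tab <- data.frame(x = x, time_months = time, event = 1L)
  cx <- fit_cox_linear(tab, "x")
  expect_lt(abs(unname(cx$coefficients["x"]) - log(2)), 0.1)

  tab$flat <- 1
  cz <- fit_cox_linear(tab, c("x", "flat"))
  expect_equal(unname(cz$coefficients["flat"]), 0)

  # continuous covariate: the stored median splits the training set in half
  set.seed(56)
  z <- rnorm(101)
  tabc <- data.frame(z = z, time_months = rexp(101, 0.05 * exp(0.5 * z)),
                     event = 1L)
  cc <- fit_cox_linear(tabc, "z")
  grp <- assess_risk_cox(predict(cc, tabc), cc)
  expect_lte(abs(sum(grp == "low") - sum(grp == "high")), 1)
})

test_that("imbalance-adjusted forests generalize on a strongly separable imbalanced cohort", {
  train <- make_cohort(n = 200, event_rate = 0.15, rng_seed = 21)
  test <- make_cohort(n = 150, event_rate = 0.15, rng_seed = 22)
  fo <- train_forest(train, c("sig1", "sig2", "sig3"), n_boot = 15,
                     rng_seed = 5)
  m <- roc_metrics(predict(fo, test), test$event)
  expect_gte(m$auc, 0.8)
  expect_lte(abs(m$sensitivity - m$specificity), 0.35)
})
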