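test_that("the 0.632+ combination reproduces its closed forms", {
  expect_equal(combine_632plus(0.8, 0.8)$estimate, 0.8)
  expect_equal(combine_632plus(0.8, 0.8)$w, 0.632)

  deg <- combine_632plus(0.9, 0.5)
  expect_equal(deg$R, 1)
  expect_equal(deg$w, 1)
  expect_equal(deg$estimate, 0.5)
  # out-of-bag below chance is clipped to the no-information value
  expect_equal(combine_632plus(0.9, 0.42)$estimate, 0.5)

  mid <- combine_632plus(0.8, 0.7)
  expect_equal(mid$w, 0.632 / (1 - 0.368 / 3), tolerance = 1e-12)
  expect_equal(mid$estimate, 0.7280, tolerance = 1e-4)

  set.seed(20)
  for (rep in 1:20) {
    r <- combine_632plus(runif(1, 0.5, 1), runif(1, 0.3, 1))
    expect_gte(r$w, 0.632)
    expect_lte(r$w, 1)
    expect_gte(r$estimate, 0.5 - 1e-12)
    expect_lte(r$estimate, 1)
  }
})

test_that("gain-based reduction rejects redundant duplicates and honours target size", {
  set.seed(30)
  n <- 80
  tab <- data.frame(sig = rnorm(n))
  tab$dup <- tab$sig  # exact copy: MIC 1 with the original
  for (k in 1:6) tab[[paste0("noise", k)]] <- rnorm(n)
  tab$event <- rbinom(n, 1, plogis(-1.5 + 2 * tab$sig))
  red <- reduce_feature_set(tab, target_size = 4)
  expect_equal(red$feature[1], "sig")
  expect_false("dup" %in% red$feature[2:4])
  expect_equal(nrow(red), 4L)

  one <- reduce_feature_set(tab, target_size = 1)
  expect_equal(one$feature, "sig")  # argmax |r_s|

  expect_warning(all_of <- reduce_feature_set(tab, target_size = 50), "fewer")
  expect_equal(nrow(all_of), 8L)
})

test_that("reduction recovers independent predictive features among noise", {
  hits <- 0
  for (seed in 1:10) {
    tab <- make_cohort(n = 150, event_rate = 0.25,
                       beta = c(s1 = 1.2, s2 = 1.2, s3 = 1.2, s4 = 1.2,
                                s5 = 1.2),
                       n_noise = 25, rng_seed = seed)
    red <- reduce_feature_set(tab, target_size = 25)
    if (all(paste0("s", 1:5) %in% red$feature)) hits <- hits + 1
  }
  expect_gte(hits, 9)  # >= 90% of seeds
})

test_that("forward selection finds a dominant feature at order 1", {
  hits <- 0
  for (seed in 1:10) {
    tab <- make_cohort(n = 120, event_rate = 0.2, beta = c(sig1 = 2),
                       n_noise = 9, rng_seed = seed)
    sel <- forward_select(c("sig1", paste0("noise0", 1:9)), tab,
                          max_order = 1, n_boot = 10, rng_seed = seed)
    if (sel[[1]]$features == "sig1") hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("orders beyond the reduced set are truncated with a warning", {
  tab <- make_cohort(n = 60, event_rate = 0.3, beta = c(sig1 = 1.5),
                     n_noise = 1, rng_seed = 2)
  expect_warning(sel <- forward_select(c("sig1", "noise01"), tab,
                                       max_order = 5, n_boot = 5,
                                       rng_seed = 1), "truncat")
  expect_length(sel, 2L)
})

test_that("the order choice applies the one-standard-error rule", {
  fake <- function(est, se) {
    structure(lapply(seq_along(est), function(k)
      list(features = letters[1:k], estimate = est[k], se = se[k])),
      class = "forward_selection")
  }
  expect_equal(choose_order(fake(c(0.6, 0.7, 0.8), rep(1e-6, 3))), 3L)
  expect_equal(choose_order(fake(c(0.6, 0.7, 0.80, 0.805, 0.81),
                                 rep(0.01, 5))), 3L)
  expect_equal(choose_order(fake(0.7, 0.01)), 1L)
  expect_equal(choose_order(fake(c(0.6, 0.8), c(0.01, 0.01)), override = 1), 1L)
})

test_that("a balanced single-bootstrap final model equals a plain logistic fit", {
  set.seed(41)
  n <- 60
  tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  tab$event <- rep(0:1, each = n / 2)  # balanced: P = 1
  mod <- finalize_logistic(tab, c("x1", "x2"), n_boot = 1, rng_seed = 1)
  ref <- glm(event ~ x1 + x2, data = tab, family = binomial())
  expect_equal(unname(mod$intercept), unname(coef(ref)[1]), tolerance = 1e-8)
  expect_equal(unname(mod$coefficients), unname(coef(ref)[-1]),
               tolerance = 1e-8)
  expect_equal(predict(mod, tab), unname(fitted(ref)), tolerance = 1e-8)
})

test_that("zero-variance features get coefficient zero with a warning", {
  set.seed(42)
  tab <- data.frame(x1 = rnorm(40), flat = rep(1, 40),
                    event = rbinom(40, 1, 0.4))
  expect_warning(mod <- finalize_logistic(tab, c("x1", "flat"), n_boot = 2,
                                          rng_seed = 1), "zero-variance")
  expect_equal(unname(mod$coefficients["flat"]), 0)
})

test_that("final models separate strongly separable synthetic data", {
  tab <- make_cohort(n = 150, event_rate = 0.3, beta = c(sig1 = 3),
                     n_noise = 2, rng_seed = 7)
  mod <- finalize_logistic(tab, "sig1", n_boot = 20, rng_seed = 1)
  pr <- predict(mod, tab)
  expect_gte(mean(pr[tab$event == 1] > 0.5), 0.75)
  expect_gte(roc_metrics(pr, tab$event)$auc, 0.9)
})

test_that("selection is deterministic under a fixed seed and stable to row order", {
  tab <- make_cohort(n = 100, event_rate = 0.25, beta = c(sig1 = 2.5),
                     n_noise = 6, rng_seed = 5)
  s1 <- forward_select(c("sig1", paste0("noise0", 1:6)), tab, max_order = 2,
                       n_boot = 8, rng_seed = 3)
  s2 <- forward_select(c("sig1", paste0("noise0", 1:6)), tab, max_order = 2,
                       n_boot = 8, rng_seed = 3)
  expect_identical(s1[[2]]$features, s2[[2]]$features)
  set.seed(6)
  perm <- sample(nrow(tab))
  s3 <- forward_select(c("sig1", paste0("noise0", 1:6)), tab[perm, ],
                       max_order = 1, n_boot = 8, rng_seed = 3)
  expect_identical(s3[[1]]$features, s1[[1]]$features)
})

test_that("logistic models serialize to JSON and reload exactly", {
  tab <- make_cohort(n = 80, event_rate = 0.3, beta = c(sig1 = 2),
                     n_noise = 1, rng_seed = 3)
  mod <- finalize_logistic(tab, c("sig1", "noise01"), n_boot = 3, rng_seed = 2)
  path <- tempfile(fileext = ".json")
  write_logistic_model(mod, path)
  back <- read_logistic_model(path)
  expect_equal(predict(back, tab), predict(mod, tab), tolerance = 1e-12)
  unlink(path)
})
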