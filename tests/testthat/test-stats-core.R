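test_that("spearman association handles monotone, tied and constant inputs", {
  expect_equal(spearman_assoc(1:3, c(10, 20, 30))$r_s, 1)
  expect_equal(spearman_assoc(1:3, c(3, 2, 1))$r_s, -1)

  # ties: midrank Pearson-on-ranks oracle
  set.seed(2)
  x <- sample(1:5, 30, replace = TRUE)
  y <- sample(1:4, 30, replace = TRUE)
  expect_equal(spearman_assoc(x, y)$r_s, cor(rank(x), rank(y)),
               tolerance = 1e-12)

  d <- spearman_assoc(rep(2, 10), rnorm(10))
  expect_equal(d$r_s, 0)
  expect_equal(d$p, 1)
  expect_true(d$degenerate)
})

test_that("BH flags match the exhaustive step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.001, 0.2, 0.9), 0.1),
               c(TRUE, FALSE, FALSE))
  expect_equal(benjamini_hochberg(rep(1, 5), 0.1), rep(FALSE, 5))
  expect_equal(benjamini_hochberg(numeric(0), 0.1), logical(0))
  set.seed(7)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.3)
    expect_equal(benjamini_hochberg(p, q), oracle_bh(p, q))
  }
})

test_that("BH flags are monotone when any p-value decreases", {
  set.seed(8)
  for (rep in 1:10) {
    p <- runif(15)
    f1 <- benjamini_hochberg(p, 0.1)
    i <- sample(15, 1)
    p2 <- p; p2[i] <- p[i] * runif(1)
    f2 <- benjamini_hochberg(p2, 0.1)
    # every hypothesis flagged before (other than the lowered one) stays flagged
    expect_true(all(f2[setdiff(which(f1), i)]))
  }
})

test_that("MIC detects functional relations and stays low under independence", {
  set.seed(1)
  x <- runif(100)
  expect_gte(mic(x, x), 0.99)
  x2 <- runif(200, -1, 1)
  expect_gte(mic(x2, x2^2), 0.9)
  expect_equal(mic(x2, x2^2), mic(x2^2, x2), tolerance = 1e-12)  # symmetry
  expect_equal(mic(rep(1, 50), rnorm(50)), 0)
  set.seed(10)
  indep <- replicate(10, mic(runif(200), runif(200)))
  expect_lt(mean(indep), 0.3)
})

test_that("ROC metrics match the pair-counting oracle and tie rules", {
  m <- roc_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$auc, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)

  expect_equal(roc_metrics(rep(0.3, 8), rep(0:1, 4))$auc, 0.5)
  expect_error(roc_metrics(runif(5), rep(1, 5)), "class")

  set.seed(12)
  for (rep in 1:15) {
    n <- sample(6:20, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    lab <- c(0, 1, rbinom(n - 2, 1, 0.4))
    expect_equal(roc_metrics(sc, lab)$auc, oracle_auc(sc, lab))
    # AUC invariance under strictly increasing transforms
    expect_equal(roc_metrics(exp(3 * sc), lab)$auc, oracle_auc(sc, lab))
  }
})

test_that("the DeLong test returns 1 for identical predictors and tracks a permutation oracle", {
  set.seed(3)
  lab <- c(rep(1, 12), rep(0, 18))
  s <- runif(30)
  expect_equal(delong_test(s, s, lab), 1)

  sa <- lab + rnorm(30, sd = 1.2)
  sb <- lab + rnorm(30, sd = 1.2)
  p_dl <- delong_test(sa, sb, lab)
  # sign-flip permutation oracle on the paired AUC difference
  obs <- abs(oracle_auc(sa, lab) - oracle_auc(sb, lab))
  set.seed(4)
  perm <- replicate(400, {
    flip <- runif(30) < 0.5
    a <- ifelse(flip, sb, sa); b <- ifelse(flip, sa, sb)
    abs(oracle_auc(a, lab) - oracle_auc(b, lab))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_dl - p_perm), 0.1)
})

test_that("the concordance index equals exhaustive permissible-pair enumeration", {
  # perfect anti-ordering, no censoring
  time <- c(1, 2, 3, 4, 5)
  risk <- c(5, 4, 3, 2, 1)
  expect_equal(concordance_index(risk, time, rep(1, 5)), 1)
  expect_equal(concordance_index(rep(2, 5), time, rep(1, 5)), 0.5)

  # censored toy set
  time6 <- c(2, 4, 5, 7, 9, 12)
  event6 <- c(1, 0, 1, 1, 0, 1)
  risk6 <- c(0.9, 0.3, 0.8, 0.2, 0.4, 0.5)
  expect_equal(concordance_index(risk6, time6, event6),
               oracle_cindex(risk6, time6, event6))

  set.seed(14)
  for (rep in 1:10) {
    n <- 12
    tt <- sample(1:30, n)
    ev <- rbinom(n, 1, 0.6); ev[1] <- 1
    rk <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    expect_equal(concordance_index(rk, tt, ev), oracle_cindex(rk, tt, ev))
  }
})

test_that("concordance reduces to AUC for distinct uncensored times", {
  set.seed(15)
  time <- sample(1:100, 20)
  risk <- runif(20)
  lab <- as.integer(time <= median(time))  # early failures as positives
  ci <- concordance_index(risk, time, rep(1, 20))
  # pairwise agreement: CI counts all ordered pairs, AUC the class pairs;
  # with distinct times the permissible-pair oracle is the ground truth
  expect_equal(ci, oracle_cindex(risk, time, rep(1, 20)))
})

test_that("log-rank comparisons match hand computation and the null case", {
  # two identical groups
  time <- rep(c(3, 5, 8, 10, 12), 2)
  event <- rep(c(1, 0, 1, 1, 0), 2)
  grp <- rep(c("a", "b"), each = 5)
  r <- km_logrank(grp, time, event)
  expect_equal(r$chisq, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)

  # 10-subject toy against a hand-built observed/expected table
  t2 <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  e2 <- c(1, 1, 1, 1, 0, 1, 1, 0, 1, 1)
  g2 <- rep(c("a", "b"), 5)
  hand_logrank <- function(time, event, grp) {
    o_a <- 0; e_a <- 0; v <- 0
    for (t in sort(unique(time[event == 1]))) {
      at_risk <- time >= t
      d <- sum(event == 1 & time == t)
      n <- sum(at_risk); n_a <- sum(at_risk & grp == "a")
      o_a <- o_a + sum(event == 1 & time == t & grp == "a")
      e_a <- e_a + d * n_a / n
      if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    }
    (o_a - e_a)^2 / v
  }
  r2 <- km_logrank(g2, t2, e2)
  expect_equal(r2$chisq, hand_logrank(t2, e2, g2), tolerance = 1e-10)

  # single group, no censoring: empirical survival steps 1/n
  fit <- survival::survfit(survival::Surv(1:6, rep(1, 6)) ~ 1)
  expect_equal(fit$surv, seq(5, 0) / 6, tolerance = 1e-12)

  expect_error(km_logrank(rep("a", 5), 1:5, rep(1, 5)), "two")
  three <- km_logrank(rep(c("a", "b", "c"), each = 4),
                      c(1, 2, 3, 4, 2, 3, 4, 5, 5, 6, 7, 8),
                      rep(c(1, 1, 0, 1), 3))
  expect_equal(nrow(three$pairwise), 3)
  expect_true(all(three$pairwise$p >= 0 & three$pairwise$p <= 1, na.rm = TRUE))
})
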