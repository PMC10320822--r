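test_that("outlier rule removes values beyond k SDs of the full group", {
  # {0 x 9, 100}: mean 10, sd ~31.6, z(100) ~ 2.85 > 2.5
  x <- c(rep(0, 9), 100)
  out <- remove_outliers(x)
  expect_identical(which(!out$keep), 10L)
  expect_identical(remove_outliers(rep(5, 8))$n_removed, 0L)
  expect_true(all(remove_outliers(x, k = Inf)$keep))
  # grouping: trimming happens within group
  g <- rep(c("a", "b"), each = 10)
  y <- c(rep(0, 9), 100, rnorm(10, 1000, 1))
  out2 <- remove_outliers(y, g)
  expect_identical(which(!out2$keep), 10L)
})

test_that("group comparison: Welch t, Levene, covariate adjustment", {
  set.seed(21)
  x <- c(rnorm(30), rnorm(30))
  g <- rep(c("a", "b"), each = 30)
  same <- compare_groups(c(1:30, 1:30), g)
  expect_equal(same$t, 0, tolerance = 1e-12)
  # matches stats::t.test with unequal variances
  ref <- t.test(x ~ g)
  got <- compare_groups(x, g)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$df, unname(ref$parameter))
  # covariate-adjusted effect is reported
  cv <- rnorm(60)
  withcov <- compare_groups(x, g, covariate = cv)
  expect_true(is.finite(withcov$adjusted_t))
  expect_error(compare_groups(x, rep("a", 60)), "two groups")
})

test_that("variance test holds its nominal level under equal variances", {
  set.seed(22)
  p <- replicate(600, {
    compare_groups(rnorm(40), rep(c("a", "b"), each = 20))$levene_p
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.025)
})

test_that("correlation rows are internally consistent", {
  set.seed(23)
  d <- data.frame(participant = 1:35,
                  pct_encoding = rnorm(35),
                  percent_correct = rnorm(35))
  d$pct_encoding <- d$percent_correct * 0.6 + rnorm(35, 0, 0.5)
  res <- correlate_index_performance(d, indices = "pct_encoding")
  expect_s3_class(res, "index_cor")
  # t = r * sqrt((n-2)/(1-r^2)) on every row
  expect_equal(res$t, res$r * sqrt((res$n - 2) / (1 - res$r^2)),
               tolerance = 1e-9)
  expect_true(res$ci_lo <= res$r && res$r <= res$ci_hi)
  # identity index: r = 1
  d2 <- data.frame(participant = 1:10, ix = 1:10,
                   percent_correct = 1:10)
  r1 <- correlate_index_performance(d2, indices = "ix", outlier_k = Inf)
  expect_equal(r1$r, 1, tolerance = 1e-12)
})

test_that("trial-level mixed model recovers a known index effect", {
  set.seed(24)
  np <- 80; nt <- 24
  d <- expand.grid(participant = factor(seq_len(np)), trial = seq_len(nt))
  d$difficulty <- rep(seq(15, 80, length.out = nt), each = np)
  d$ix <- rnorm(nrow(d))
  u <- rnorm(np, 0, 0.7)
  beta <- 0.5
  d$correct <- rbinom(nrow(d), 1,
                      plogis(0.4 + beta * d$ix +
                               -0.02 * (d$difficulty - 50) +
                               u[d$participant]))
  fit <- trial_level_model(d, "ix", nAGQ = 0)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients$B[1] - beta), 0.15)
  # difficulty coefficient is reported per original unit
  expect_lt(abs(fit$coefficients$B[2] + 0.02), 0.012)
  # unidentifiable index flagged, not fitted
  d$flat <- 1
  expect_false(trial_level_model(d, "flat")$converged)
})

test_that("item-level adaptation correlations behave at the limits", {
  d <- expand.grid(participant = factor(1:10), trial = 1:12)
  d$difficulty <- rep(1:12 * 5, each = 10)
  d$exact <- d$difficulty          # identical to difficulty: r = 1
  d$flat <- 3                      # constant: r undefined -> NA
  res <- item_level_adaptation(d, indices = c("exact", "flat"))
  expect_equal(res$r[res$index == "exact"], 1, tolerance = 1e-12)
  expect_true(is.na(res$r[res$index == "flat"]))
  expect_equal(res$n[res$index == "exact"], 12)
})

test_that("adaptation slopes shrink to the fixed slope without heterogeneity", {
  set.seed(25)
  np <- 40; nt <- 24
  d <- expand.grid(participant = factor(seq_len(np)), trial = seq_len(nt))
  d$difficulty <- rep(seq(15, 80, length.out = nt), each = np)
  # common slope 0.01 per point, no participant variation
  d$y <- 1 + 0.01 * (d$difficulty - 50) + rnorm(nrow(d), 0, 0.05)
  fit <- adaptation_slopes(d, "y")
  expect_lt(abs(fit$fixed_slope - 0.01), 0.002)
  expect_lt(max(abs(coef(fit) - fit$fixed_slope)), 0.004)
  # mean of conditional slopes matches the fixed slope
  expect_lt(abs(mean(coef(fit)) - fit$fixed_slope), 1e-3)
})

test_that("heterogeneous difficulty slopes are recovered per participant", {
  set.seed(26)
  np <- 60; nt <- 24
  d <- expand.grid(participant = seq_len(np), trial = seq_len(nt))
  d$difficulty <- rep(seq(15, 80, length.out = nt), each = np)
  sl <- rnorm(np, 0.01, 0.008)
  d$y <- 1 + sl[d$participant] * (d$difficulty - 50) +
    rnorm(nrow(d), 0, 0.2)
  d$participant <- factor(d$participant)
  fit <- adaptation_slopes(d, "y")
  got <- coef(fit)[as.character(seq_len(np))]
  expect_gt(cor(got, sl), 0.7)
  # slope-performance correlation: identity gives r = 1
  perf <- data.frame(participant = as.character(seq_len(np)),
                     percent_correct = sl)
  res <- correlate_adaptation_performance(list(y = fit), perf,
                                          outlier_k = Inf)
  expect_gt(res$r, 0.7)
})

test_that("binary indices use a logistic adaptation model", {
  set.seed(27)
  np <- 50; nt <- 24
  d <- expand.grid(participant = factor(seq_len(np)), trial = seq_len(nt))
  d$difficulty <- rep(seq(15, 80, length.out = nt), each = np)
  sl <- rnorm(np, 0.03, 0.02)
  d$y <- rbinom(nrow(d), 1,
                plogis(-0.5 + sl[as.integer(d$participant)] *
                         (d$difficulty - 50)))
  fit <- adaptation_slopes(d, "y")
  expect_equal(fit$method, "glmm")
  expect_gt(cor(coef(fit)[as.character(seq_len(np))], sl), 0.5)
})
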