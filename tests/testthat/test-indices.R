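test_that("encoding windows match hand-checked examples", {
  expect_equal(detect_encoding(c(1, 2, 3, 10)),
               c(row = TRUE, col = FALSE))
  expect_equal(detect_encoding(c(1, 2, 3, 1, 4, 7)),
               c(row = TRUE, col = TRUE))
  expect_true(detect_integration(c(1, 2, 3, 1, 4, 7)))
  # repeat inside: window (2,1,2) etc. fails, but positions 3..5 cover 1,2,3
  expect_equal(detect_encoding(c(1, 2, 1, 2, 3)),
               c(row = TRUE, col = FALSE))
  # interrupted sweep: no window of 3 consecutive covers a row
  expect_equal(detect_encoding(c(1, 2, 4, 3)),
               c(row = FALSE, col = FALSE))
  # any order within the window counts by default ...
  expect_equal(detect_encoding(c(2, 3, 1)), c(row = TRUE, col = FALSE))
  # ... but not under the order-strict variant
  expect_equal(detect_encoding(c(2, 3, 1), order_strict = TRUE),
               c(row = FALSE, col = FALSE))
  expect_equal(detect_encoding(c(1, 2, 3), order_strict = TRUE),
               c(row = TRUE, col = FALSE))
  # off-AOI and solution-array fixations break windows
  expect_false(detect_encoding(c(1, NA, 2, 3))[["row"]])
  expect_false(detect_encoding(c(1, 10, 2, 3))[["row"]])
  expect_equal(detect_encoding(integer(0)), c(row = FALSE, col = FALSE))
})

test_that("integration needs both a row and a column event", {
  expect_false(detect_integration(c(1, 4, 7)))
  expect_true(detect_integration(c(1, 2, 3, 3, 6, 9)))
  expect_false(detect_integration(integer(0)))
})

test_that("toggle counting matches enumerated transitions", {
  expect_equal(count_toggles(c(1, 2, 10, 5, 10)), 3L)
  expect_equal(count_toggles(c(1, 2, 3)), 0L)
  expect_equal(count_toggles(c(10, 10, 10)), 0L)
  # off-AOI transparency (default) vs breaking
  expect_equal(count_toggles(c(1, NA, 10)), 1L)
  expect_equal(count_toggles(c(1, NA, 10), through_na = FALSE), 0L)
  # repeated fixations on the same AOI collapse first
  expect_equal(count_toggles(c(1, 1, 10, 10, 1)), 2L)
})

test_that("sequence detectors agree exactly with brute-force oracles", {
  set.seed(123)
  for (i in 1:2000) {
    s <- random_aoi_seq()
    expect_identical(unname(detect_encoding(s)), unname(oracle_encoding(s)))
    expect_identical(count_toggles(s), oracle_toggles(s))
  }
})

test_that("appending a matrix-array transition never decreases toggles", {
  set.seed(99)
  for (i in 1:200) {
    s <- random_aoi_seq()
    s2 <- c(s, 1, 10)
    expect_gte(count_toggles(s2), count_toggles(s))
  }
})

test_that("toggle rate is toggles per second of AOI looking time", {
  expect_equal(toggle_rate(3, 6), 0.5)
  expect_equal(toggle_rate(0, 4.2), 0)
  expect_warning(r <- toggle_rate(2, 0))
  expect_true(is.na(r))
})

test_that("time to first toggle sums AOI time before the array", {
  f <- fix_df(aoi = c(1, 2, 10), duration = c(0.5, 0.4, 0.3))
  out <- time_to_first_toggle(f)
  expect_equal(out$time, 0.9)
  expect_false(out$censored)
  f2 <- fix_df(aoi = c(10, 1), duration = c(0.3, 1))
  expect_equal(time_to_first_toggle(f2)$time, 0)
  f3 <- fix_df(aoi = c(1, 5, 9), duration = c(1, 2, 1))
  out3 <- time_to_first_toggle(f3)
  expect_equal(out3$time, 4)
  expect_true(out3$censored)
  # off-AOI time does not count toward the sum
  f4 <- fix_df(aoi = c(1, NA, 10), duration = c(0.5, 5, 0.2))
  expect_equal(time_to_first_toggle(f4)$time, 0.5)
})

test_that("proportion of matrix time and its complement partition AOI time", {
  f <- fix_df(aoi = c(1, 5, 10), duration = c(2, 1, 1))
  expect_equal(proportion_matrix_time(f), 0.75)
  expect_equal(proportion_matrix_time(fix_df(c(2, 3), c(1, 1))), 1)
  expect_equal(proportion_matrix_time(fix_df(10, 3)), 0)
  expect_warning(p <- proportion_matrix_time(fix_df(NA, 2)))
  expect_true(is.na(p))
})

test_that("matrix time distribution index follows the cell partition", {
  equal9 <- fix_df(aoi = 1:9, duration = rep(1, 9))
  expect_equal(matrix_time_distribution(equal9), -1 / 9)
  expect_equal(matrix_time_distribution(fix_df(1, 2)), 1)
  expect_equal(matrix_time_distribution(fix_df(9, 2)), -1)
  expect_warning(m <- matrix_time_distribution(fix_df(10, 1)))
  expect_true(is.na(m))
})

test_that("vectorised trial table equals the scalar index functions", {
  set.seed(7)
  rows <- list()
  for (p in 1:4) for (tr in 1:6) {
    n <- sample(3:30, 1)
    aoi <- sample(c(1:10, NA), n, replace = TRUE)
    dur <- round(runif(n, 0.1, 0.6), 3)
    rows[[length(rows) + 1]] <-
      data.frame(participant = paste0("p", p), trial = tr,
                 onset = cumsum(c(0, head(dur + 0.01, -1))),
                 duration = dur, aoi = aoi)
  }
  tab <- do.call(rbind, rows)
  ti <- trial_indices(tab)
  for (i in seq_len(nrow(ti))) {
    d <- tab[tab$participant == ti$participant[i] &
               tab$trial == ti$trial[i], ]
    enc <- detect_encoding(d$aoi)
    expect_identical(ti$encoding[i], unname(enc["row"] || enc["col"]))
    expect_identical(ti$integration[i], unname(enc["row"] && enc["col"]))
    expect_identical(ti$n_toggles[i], count_toggles(d$aoi))
    rt <- sum(d$duration[!is.na(d$aoi)])
    expect_equal(ti$response_time[i], rt)
    if (rt > 0)
      expect_equal(ti$n_toggles[i], ti$toggle_rate[i] * rt,
                   tolerance = 1e-12)
    tf <- time_to_first_toggle(d)
    expect_equal(ti$time_to_first_toggle[i], tf$time)
    expect_identical(ti$ttft_censored[i], tf$censored)
    expect_equal(ti$prop_matrix_time[i],
                 suppressWarnings(proportion_matrix_time(d)))
    expect_equal(ti$matrix_time_distribution[i],
                 suppressWarnings(matrix_time_distribution(d)))
  }
})

test_that("participant aggregation produces percentages and means", {
  tr <- data.frame(participant = rep("a", 4), trial = 1:4,
                   encoding = c(TRUE, TRUE, FALSE, FALSE),
                   integration = c(TRUE, FALSE, FALSE, FALSE),
                   n_toggles = c(2, 4, 2, 4), toggle_rate = c(1, 1, 1, 1),
                   time_to_first_toggle = c(1, 2, 3, 4),
                   prop_matrix_time = rep(0.8, 4),
                   matrix_time_distribution = rep(-0.1, 4),
                   response_time = c(5, 5, 5, 5))
  resp <- data.frame(participant = "a", trial = 1:4,
                     correct = c(TRUE, TRUE, TRUE, FALSE))
  agg <- aggregate_participants(tr, resp)
  expect_equal(agg$pct_encoding, 50)
  expect_equal(agg$pct_integration, 25)
  expect_equal(agg$time_to_first_toggle, 2.5)
  expect_equal(agg$percent_correct, 75)
  expect_equal(agg$n_trials, 4)
})

test_that("Cronbach's alpha matches closed forms and the null", {
  # perfectly correlated trials
  base <- rnorm(20)
  mat <- cbind(base, base + 1, base - 3)
  expect_equal(cronbach_alpha(mat), 1, tolerance = 1e-9)
  # two items with covariance c and equal variances v: alpha = 2c/(v+c)
  set.seed(11)
  z <- MASS::mvrnorm(5000, c(0, 0),
                     matrix(c(1, 0.6, 0.6, 1), 2), empirical = TRUE)
  expect_equal(cronbach_alpha(z), 2 * 0.6 / (1 + 0.6), tolerance = 1e-9)
  # independent noise: alpha near 0
  set.seed(12)
  noise <- matrix(rnorm(400 * 12), 400, 12)
  expect_lt(abs(cronbach_alpha(noise)), 0.15)
  expect_error(cronbach_alpha(matrix(1:4, 4, 1)), "2 trials")
})
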