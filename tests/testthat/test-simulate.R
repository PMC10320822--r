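test_that("item bank has the 3x8 set structure with 3/3/2 relations", {
  bank <- generate_item_bank()
  expect_equal(nrow(bank$items), 24)
  expect_equal(as.integer(table(bank$items$n_relations)), c(9L, 9L, 6L))
  expect_equal(as.vector(tapply(bank$items$n_relations, bank$items$set,
                                function(x) sum(x == 1))), c(3, 3, 3))
  # difficulty nondecreasing across sets on average
  m <- tapply(bank$items$difficulty, bank$items$set, mean)
  expect_true(all(diff(m) > 0))
  # exactly one correct option per item, all options present
  expect_true(all(tapply(bank$options$is_correct, bank$options$item,
                         sum) == 1))
  expect_true(all(table(bank$options$item) == 8))
  # correct option matches the item's relation count
  co <- bank$options[bank$options$is_correct, ]
  expect_equal(co$n_relations_matched[order(co$item)],
               bank$items$n_relations)
  # determinism
  expect_identical(generate_item_bank(), generate_item_bank())
  expect_error(generate_item_bank(3), "4 options")
})

test_that("single-trial simulation is deterministic and well-formed", {
  p <- group_presets()$nine
  a <- simulate_trial(p, seed = 42)
  b <- simulate_trial(p, seed = 42)
  expect_identical(a, b)
  expect_true(all(a$fixations$aoi %in% 1:10))
  expect_true(all(a$fixations$duration >= 0.1 - 1e-12))
  expect_true(all(diff(a$fixations$onset) > 0))
  c2 <- simulate_trial(p, seed = 43)
  expect_false(identical(a$fixations, c2$fixations))
})

test_that("forced constructive matcher: sweeps planted, single toggle", {
  p <- strategy_params(p_scan = 1, toggle_intensity = 1e-6,
                       first_toggle_mean = 4, rt_mean = 8,
                       missing_frac = 0.2, adapt_scan_slope = 0,
                       adapt_toggle_slope = 0)
  for (s in 1:10) {
    tr <- simulate_trial(p, seed = s)
    expect_true(tr$indices$encoding)
    expect_true(tr$indices$integration)
    expect_equal(tr$indices$n_toggles, 1L)
    expect_true(tr$truth$row_planted && tr$truth$col_planted)
  }
})

test_that("toggle counts follow the renewal-process expectation", {
  # rate 1/s over ~10 s of AOI time: expect ~10 toggles on average
  p <- strategy_params(p_scan = 0, toggle_intensity = 1, rt_mean = 10,
                       first_toggle_mean = 2, missing_frac = 0,
                       adapt_scan_slope = 0, adapt_toggle_slope = 0)
  parts <- data.frame(
    participant = "p0001", group = "g", competence = 0,
    p_scan = 0, toggle_intensity = 1, first_toggle_mean = 2,
    rt_mean = 10, adapt_scan_slope = 0, adapt_toggle_slope = 0,
    missing_frac = 0, first_block_bias = 0.4,
    fixation_dur_mean = 0.32, fixation_dur_sd = 0.13, array_dwell = 0.7,
    acc_b0 = 0, true_scan_slope = 0, true_toggle_slope = 0)
  item <- generate_item_bank()$items[12, ]
  item$difficulty <- 50
  set.seed(77)
  items_rep <- item[rep(1, 1000), ]
  items_rep$item <- 1:1000
  eng <- gazemat:::sim_engine(parts, items_rep, sim_config()$ctl)
  ti <- trial_indices(eng$fixations)
  expected <- mean(1 * eng$truth$aoi_time)   # rho * T per trial
  mc_se <- sd(ti$n_toggles) / sqrt(nrow(ti))
  expect_lt(abs(mean(ti$n_toggles) - expected), 3 * mc_se + 0.15)
  # and measured rate close to the configured intensity
  expect_lt(abs(mean(ti$toggle_rate) - 1),
            4 * sd(ti$toggle_rate) / sqrt(nrow(ti)) + 0.02)
})

test_that("accuracy model limits: uniform choice and saturation", {
  p <- group_presets()$six
  coh_u <- simulate_cohort(sim_config(
    n_per_group = 25, params = list(six = p),
    accuracy = accuracy_coefs(uniform = TRUE), seed = 6))
  expect_lt(abs(mean(coh_u$responses$correct) - 1 / 8), 0.02)
  # intercept to +infinity: always correct
  p2 <- p; p2$acc_b0 <- 50
  p2 <- do.call(strategy_params, p2[names(formals(strategy_params))])
  coh_c <- simulate_cohort(sim_config(
    n_per_group = 10, params = list(six = p2),
    loadings = c(acc = 0), noise = c(acc_b0 = 0), seed = 6))
  expect_true(all(coh_c$responses$correct))
})

test_that("cohort simulation is deterministic and internally consistent", {
  cfg <- sim_config(n_per_group = 5, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$fixations, b$fixations)
  expect_identical(a$responses, b$responses)
  # every participant x trial appears once in responses and truth
  expect_equal(nrow(a$responses), 3 * 5 * 24)
  expect_false(any(duplicated(paste(a$responses$participant,
                                    a$responses$trial))))
  # chosen option always within range; correct iff chosen == correct_option
  co <- a$items$correct_option[match(a$responses$item, a$items$item)]
  expect_identical(a$responses$correct, a$responses$chosen == co)
  # valid fraction consistent with AOI and wall-clock time
  ti <- a$trial_indices
  key <- paste(ti$participant, ti$trial)
  tt <- a$trial_truth[match(key, paste(a$trial_truth$participant,
                                       a$trial_truth$trial)), ]
  expect_equal(ti$response_time, tt$aoi_time, tolerance = 1e-9)
})

test_that("missing fraction controls the measured valid fraction", {
  pr <- group_presets()$six
  pr$missing_frac <- 0
  pr0 <- do.call(strategy_params, pr[names(formals(strategy_params))])
  coh0 <- simulate_cohort(sim_config(n_per_group = 8,
                                     params = list(six = pr0),
                                     noise = c(missing = 0), seed = 13))
  expect_equal(mean(coh0$responses$valid_fraction), 1, tolerance = 1e-9)
})

test_that("planted sweeps drive encoding; without them only chance sweeps", {
  pr <- group_presets()$six
  pr$p_scan <- 0; pr$adapt_scan_slope <- 0
  pr0 <- do.call(strategy_params, pr[names(formals(strategy_params))])
  coh <- simulate_cohort(sim_config(n_per_group = 30,
                                    params = list(six = pr0), seed = 14))
  expect_true(all(!coh$trial_truth$row_planted))
  # encoding occurs only at the accidental-sweep rate
  expect_lt(mean(coh$trial_indices$encoding), 0.2)
  # with p_scan = 1 every trial with a long-enough first dwell encodes
  pr1 <- group_presets()$six
  pr1$p_scan <- 1; pr1$adapt_scan_slope <- 0
  pr1 <- do.call(strategy_params, pr1[names(formals(strategy_params))])
  coh1 <- simulate_cohort(sim_config(n_per_group = 30,
                                     params = list(six = pr1), seed = 15))
  planted <- coh1$trial_truth$row_planted | coh1$trial_truth$col_planted
  expect_true(all(coh1$trial_indices$encoding[planted]))
  expect_gt(mean(planted), 0.9)
})
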