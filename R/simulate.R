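#' Strategy parameters for one simulated participant group
#'
#' Parameterises the generative scanpath model. A trial is laid out on the
#' axis of detected AOI looking time (the task's "response time"): the first
#' solution-array visit starts after \code{first_toggle_mean} seconds on
#' average, later matrix/array transitions form a Poisson stream whose rate
#' is solved so that the measured toggle rate (toggles per second of AOI
#' time) is an unbiased estimate of \code{toggle_intensity}, and off-AOI /
#' lost-signal time is injected between fixations so that the valid fraction
#' equals \code{1 - missing_frac}. Row and column sweeps are planted at the
#' start of a trial, each with probability \code{p_scan}; between sweeps the
#' gaze dwells and jumps among matrix cells with first-block bias
#' \code{first_block_bias} (the fraction of wandering time on cells
#' 1, 2, 4, 5, which sets the matrix time distribution index).
#'
#' Difficulty enters linearly on the natural link scales:
#' \code{logit(p_scan)} and \code{log(toggle_intensity)} shift by
#' \code{adapt_scan_slope} and \code{adapt_toggle_slope} per difficulty
#' percentage point (centred at 50).
#'
#' @param p_scan probability of planting a row sweep (and, independently, a
#'   column sweep) on a trial, in \[0, 1\].
#' @param toggle_intensity expected toggles per second of AOI looking time
#'   (1/s), > 0.
#' @param first_toggle_mean mean AOI looking time before the first
#'   solution-array fixation (s), > 0.
#' @param fixation_dur_mean,fixation_dur_sd mean and SD (s) of the lognormal
#'   fixation-duration distribution; durations are floored at 100 ms so the
#'   preprocessing minimum-duration rule is exercised.
#' @param adapt_scan_slope change in \code{logit(p_scan)} per difficulty
#'   point.
#' @param adapt_toggle_slope change in \code{log(toggle_intensity)} per
#'   difficulty point.
#' @param missing_frac expected fraction of wall-clock trial time not spent
#'   in AOI-labelled fixations, in \[0, 1).
#' @param rt_mean mean total AOI looking time per trial (s) at difficulty 50.
#' @param first_block_bias fraction of wandering fixations on cells
#'   \{1,2,4,5\}, in (0, 1).
#' @param array_dwell relative duration of solution-array visits versus the
#'   surrounding matrix dwells (1 = symmetric alternation).
#' @param acc_b0 accuracy-model intercept (logit scale) for the group.
#' @return Object of class \code{strategy_params}.
#' @export
strategy_params <- function(p_scan = 0.3, toggle_intensity = 0.4,
                            first_toggle_mean = 3, fixation_dur_mean = 0.32,
                            fixation_dur_sd = 0.13, adapt_scan_slope = 0.03,
                            adapt_toggle_slope = -0.006, missing_frac = 0.3,
                            rt_mean = 9, first_block_bias = 0.4,
                            array_dwell = 0.7, acc_b0 = 0) {
  stopifnot(p_scan >= 0, p_scan <= 1,
            toggle_intensity > 0, first_toggle_mean > 0,
            fixation_dur_mean > 0, fixation_dur_sd > 0,
            missing_frac >= 0, missing_frac < 1,
            rt_mean > 0, first_block_bias > 0, first_block_bias < 1,
            array_dwell > 0)
  structure(as.list(environment()), class = "strategy_params")
}

#' Accuracy-model coefficients
#'
#' Encodes, as the simulation's ground truth, the hypothesis that
#' constructive matching causes better performance: the probability of a
#' correct response is logistic in the trial's realised indices, increasing
#' in encoding, integration and time to first toggle, decreasing in toggle
#' rate and difficulty. Incorrect probability mass is split among the
#' distractors with type weights; the duplicate weight grows with the
#' trial's toggle rate, so response eliminators preferentially pick
#' duplicate answers.
#'
#' @param b_encoding,b_integration logit effects of the binary flags.
#' @param b_ttft logit effect per second of time to first toggle.
#' @param b_toggle_rate logit effect per unit toggle rate (1/s).
#' @param b_difficulty logit effect per difficulty point (centred at 50).
#' @param w_duplicate,w_novel,w_partial base weights of distractor types.
#' @param dup_toggle_coef log-multiplier on the duplicate weight per unit
#'   toggle rate.
#' @param uniform if \code{TRUE}, skip the logistic gate and choose among
#'   all options uniformly (so P(correct) = 1 / n_options).
#' @return Object of class \code{accuracy_coefs}.
#' @export
accuracy_coefs <- function(b_encoding = 0.9, b_integration = 0.4,
                           b_ttft = 0.06, b_toggle_rate = -1.8,
                           b_difficulty = -0.035, w_duplicate = 1.2,
                           w_novel = 0.8, w_partial = 1,
                           dup_toggle_coef = 1.2, uniform = FALSE) {
  if (any(c(w_duplicate, w_novel, w_partial) < 0) ||
      w_duplicate + w_novel + w_partial <= 0)
    stop("distractor weights must be non-negative and sum to > 0")
  structure(list(b_encoding = b_encoding, b_integration = b_integration,
                 b_ttft = b_ttft, b_toggle_rate = b_toggle_rate,
                 b_difficulty = b_difficulty, w_duplicate = w_duplicate,
                 w_novel = w_novel, w_partial = w_partial,
                 dup_toggle_coef = dup_toggle_coef, uniform = uniform),
            class = "accuracy_coefs")
}

#' Group presets emulating a developmental eyetracking study
#'
#' Three groups (6-year-olds, 9-year-olds, adults) whose generative
#' parameters reproduce the characteristic ranges of such studies: toggle
#' rates from roughly 0.25 to 0.5 per second falling with age, first-toggle
#' latencies from about 2 to 8 s rising with age, missing-data fractions of
#' 43/31/24 percent falling with age, mean response times of about 8 s in
#' children versus 22 s in adults, and encoding on roughly 30/58/78 percent
#' of trials.
#'
#' @return Named list of [strategy_params()].
#' @export
group_presets <- function() {
  list(
    six = strategy_params(p_scan = 0.11, toggle_intensity = 0.47,
                          first_toggle_mean = 2.2, fixation_dur_mean = 0.30,
                          fixation_dur_sd = 0.12, missing_frac = 0.43,
                          rt_mean = 7.6, first_block_bias = 0.27,
                          array_dwell = 0.55, acc_b0 = -0.9),
    nine = strategy_params(p_scan = 0.37, toggle_intensity = 0.38,
                           first_toggle_mean = 3.9, fixation_dur_mean = 0.32,
                           fixation_dur_sd = 0.12, missing_frac = 0.31,
                           rt_mean = 8.9, first_block_bias = 0.40,
                           array_dwell = 0.27, acc_b0 = 1.0),
    adult = strategy_params(p_scan = 0.58, toggle_intensity = 0.27,
                            first_toggle_mean = 7.5, fixation_dur_mean = 0.35,
                            fixation_dur_sd = 0.14, missing_frac = 0.24,
                            rt_mean = 21.7, first_block_bias = 0.53,
                            array_dwell = 0.28, acc_b0 = -0.85)
  )
}

#' Cohort simulation configuration
#'
#' Fixes the whole simulated study: group definitions, sample sizes,
#' between-participant heterogeneity, the competence factor that couples
#' strategy, adaptation and accuracy, and the master seed. Identical
#' configurations with the same seed produce identical cohorts.
#'
#' Between-participant draws are mean-preserving: lognormally drawn
#' positive parameters are log-shifted so their arithmetic means equal the
#' configured group values, which is what makes the cohort-level
#' calibration checks meaningful.
#'
#' @param n_per_group participants per group (scalar or per-group vector).
#' @param params named list of [strategy_params()], one per group.
#' @param accuracy an [accuracy_coefs()].
#' @param coupled if \code{FALSE}, zero all competence loadings and all
#'   index effects in the accuracy model: strategy indices and accuracy
#'   become independent across participants (the null generator used for
#'   correlation calibration).
#' @param loadings named numeric loadings of the standard-normal competence
#'   factor on (log/logit-scale) participant parameters.
#' @param noise named numeric SDs of participant-level deviations on the
#'   same scales.
#' @param n_options answer options per item.
#' @param rate nominal sampling rate (Hz) used when synthesising raw
#'   samples.
#' @param seed master seed.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_per_group = 40, params = group_presets(),
                       accuracy = accuracy_coefs(), coupled = TRUE,
                       loadings = NULL, noise = NULL, n_options = 8,
                       rate = 50, seed = 1) {
  stopifnot(all(n_per_group >= 1), length(params) >= 1)
  if (is.null(names(params)) || any(names(params) == ""))
    stop("params must be a named list of strategy_params (group labels)")
  n_per_group <- rep_len(n_per_group, length(params))
  default_load <- c(p_scan = 0.8, rho = -0.25, t1 = 0.35, rt = 0.2,
                    adapt_scan = 0.02, adapt_toggle = -0.005, acc = 0.9)
  default_noise <- c(p_scan = 0.45, rho = 0.18, t1 = 0.25, rt = 0.25,
                     adapt_scan = 0.02, adapt_toggle = 0.0075,
                     missing = 0.2, bias = 0.25, acc_b0 = 0.5)
  load <- default_load
  if (!is.null(loadings)) load[names(loadings)] <- loadings
  nz <- default_noise
  if (!is.null(noise)) nz[names(noise)] <- noise
  if (!coupled) {
    load[] <- 0
    accuracy$b_encoding <- accuracy$b_integration <- accuracy$b_ttft <-
      accuracy$b_toggle_rate <- 0
    accuracy$dup_toggle_coef <- 0
  }
  ctl <- list(rt_sdlog = 0.35, t1_shape = 8, rt_diff_slope = 0.012,
              ttft_diff_slope = 0.008, stay_prob = 0.62)
  structure(list(n_per_group = n_per_group, groups = names(params),
                 params = params, accuracy = accuracy, coupled = coupled,
                 loadings = load, noise = nz, n_options = n_options,
                 rate = rate, seed = seed, ctl = ctl),
            class = "sim_config")
}

#' Generate the 24-item bank
#'
#' Three sets of eight problems with increasing anticipated difficulty;
#' within each set, three one-relation, three two-relation and two
#' three-relation problems. The final problem stands in for a logical-rule
#' item and is counted as three-relation. Each item carries \code{n_options}
#' answer options: the correct one, one duplicate distractor, two
#' novel-feature distractors, and partial matches for the rest. The bank is
#' deterministic.
#'
#' @param n_options answer options per item (>= 4 to hold all types).
#' @return List with \code{items} (item, set, n_relations, difficulty,
#'   correct_option) and \code{options} (item, option, is_correct,
#'   is_duplicate, has_novel_feature, n_relations_matched).
#' @export
generate_item_bank <- function(n_options = 8) {
  if (n_options < 4) stop("need at least 4 options per item")
  n_rel <- rep(c(1, 1, 1, 2, 2, 2, 3, 3), 3)
  set <- rep(1:3, each = 8)
  pos <- unlist(lapply(1:3, function(s) c(0:2, 0:2, 0:1)))
  difficulty <- 12 + 22 * (set - 1) + 9 * (n_rel - 1) + 2 * pos
  items <- data.frame(item = 1:24, set = set, n_relations = n_rel,
                      difficulty = difficulty,
                      correct_option = ((1:24 * 3L) %% n_options) + 1L,
                      n_options = n_options)
  opts <- lapply(1:24, function(i) {
    co <- items$correct_option[i]
    nr <- items$n_relations[i]
    others <- setdiff(seq_len(n_options), co)
    dup <- others[1]; nov <- others[2:3]
    part <- others[-(1:3)]
    o <- data.frame(item = i, option = seq_len(n_options),
                    is_correct = seq_len(n_options) == co,
                    is_duplicate = seq_len(n_options) %in% dup,
                    has_novel_feature = seq_len(n_options) %in% nov,
                    n_relations_matched = 0)
    o$n_relations_matched[co] <- nr
    o$n_relations_matched[part] <- rep_len(seq(0, max(0, nr - 1)),
                                           length(part))
    o
  })
  list(items = items, options = do.call(rbind, opts))
}

# draw participant-level parameters around group means; lognormal draws are
# mean-corrected so cohort means equal the configured values
draw_participants <- function(config) {
  L <- config$loadings; S <- config$noise
  out <- vector("list", length(config$groups))
  pid0 <- 0
  for (gi in seq_along(config$groups)) {
    p <- config$params[[gi]]
    n <- config$n_per_group[gi]
    comp <- stats::rnorm(n)
    ln <- function(mean, load, sd) {
      v <- load^2 + sd^2
      exp(log(mean) - v / 2 + load * comp + stats::rnorm(n, 0, sd))
    }
    adapt_scan <- p$adapt_scan_slope + L["adapt_scan"] * comp +
      stats::rnorm(n, 0, S["adapt_scan"])
    adapt_toggle <- p$adapt_toggle_slope + L["adapt_toggle"] * comp +
      stats::rnorm(n, 0, S["adapt_toggle"])
    rho <- ln(p$toggle_intensity, L["rho"], S["rho"])
    out[[gi]] <- data.frame(
      participant = sprintf("p%04d", pid0 + seq_len(n)),
      group = config$groups[gi],
      competence = comp,
      p_scan = stats::plogis(stats::qlogis(p$p_scan) + L["p_scan"] * comp +
                               stats::rnorm(n, 0, S["p_scan"])),
      toggle_intensity = rho,
      first_toggle_mean = ln(p$first_toggle_mean, L["t1"], S["t1"]),
      rt_mean = ln(p$rt_mean, L["rt"], S["rt"]),
      adapt_scan_slope = adapt_scan,
      adapt_toggle_slope = adapt_toggle,
      missing_frac = stats::plogis(stats::qlogis(p$missing_frac) +
                                     stats::rnorm(n, 0, S["missing"])),
      first_block_bias = stats::plogis(stats::qlogis(p$first_block_bias) +
                                         stats::rnorm(n, 0, S["bias"])),
      fixation_dur_mean = p$fixation_dur_mean,
      fixation_dur_sd = p$fixation_dur_sd,
      array_dwell = p$array_dwell,
      acc_b0 = p$acc_b0 + L["acc"] * comp + stats::rnorm(n, 0, S["acc_b0"]),
      true_scan_slope = adapt_scan,
      true_toggle_slope = rho * adapt_toggle
    )
    pid0 <- pid0 + n
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# vectorised trial engine: builds the fixation table and trial-level truth
# for every participant x item; assumes the RNG is already seeded
sim_engine <- function(parts, items, ctl) {
  P <- nrow(parts); I <- nrow(items)
  N <- P * I
  ip <- rep(seq_len(P), each = I)
  ii <- rep(seq_len(I), P)
  dc <- items$difficulty[ii] - 50

  p_scan_t <- stats::plogis(stats::qlogis(parts$p_scan[ip]) +
                              parts$adapt_scan_slope[ip] * dc)
  # multiplicative difficulty adaptation, normalised within participant so
  # toggle_intensity keeps its task-average meaning whatever the slope
  adapt_fac <- exp(parts$adapt_toggle_slope[ip] * dc)
  fac_norm <- rowMeans(exp(outer(parts$adapt_toggle_slope,
                                 items$difficulty - 50)))
  rho_t <- parts$toggle_intensity[ip] * adapt_fac / fac_norm[ip]
  # difficulty multipliers normalised to the item-bank mean, so rt_mean and
  # first_toggle_mean keep their task-average interpretation
  f_rt <- exp(ctl$rt_diff_slope * dc)
  f_rt <- f_rt / mean(exp(ctl$rt_diff_slope * (items$difficulty - 50)))
  f_t1 <- exp(ctl$ttft_diff_slope * dc)
  f_t1 <- f_t1 / mean(exp(ctl$ttft_diff_slope * (items$difficulty - 50)))
  rtm <- parts$rt_mean[ip] * f_rt
  tt <- pmax(1.5, stats::rlnorm(N, log(rtm) - ctl$rt_sdlog^2 / 2,
                                ctl$rt_sdlog))
  # first array visit as a Beta fraction of the trial's AOI time: always
  # inside the trial, and E[t1] equals the configured first-toggle mean
  t1m <- parts$first_toggle_mean[ip] * f_t1
  mu <- pmin(0.9, t1m / rtm)
  nu <- ctl$t1_shape
  t1 <- tt * stats::rbeta(N, mu * nu, (1 - mu) * nu)
  cens <- t1 >= tt

  # transition rate solved so E[toggles] = rho_t * T given (T, t1)
  lam <- ifelse(cens, 0, pmax(0, rho_t * tt - 1) / (tt - t1))
  n2 <- stats::rpois(N, lam * pmax(0, tt - t1))
  K <- ifelse(cens, 0L, 1L + n2)          # transitions per trial
  nseg <- K + 1L

  # transition times: t1 first, then sorted uniforms on (t1, T)
  ut <- rep(seq_len(N), n2)
  u <- stats::runif(length(ut), t1[ut], tt[ut])
  u <- u[order(ut, u)]
  ntr <- sum(K)
  trans <- numeric(ntr)
  kpos <- cumsum(K) - K + 1L               # first transition slot per trial
  has <- K > 0L
  trans[kpos[has]] <- t1[has]
  if (length(u)) trans[-kpos[has]] <- u

  # segments: alternating matrix/array, grouped by trial
  nseg_tot <- sum(nseg)
  seg_trial <- rep(seq_len(N), nseg)
  spos <- cumsum(nseg) - nseg + 1L
  starts <- numeric(nseg_tot); ends <- numeric(nseg_tot)
  starts[spos] <- 0
  if (ntr) starts[-spos] <- trans
  last <- cumsum(nseg)
  ends[last] <- tt
  if (ntr) ends[-last] <- trans
  seg_len <- ends - starts
  within <- sequence(nseg)
  is_matrix <- (within %% 2L) == 1L

  # shorten array dwells (except trial-final ones), handing the slack to
  # the following matrix segment, so that the array/matrix dwell ratio is
  # array_dwell while transition times and total AOI time are preserved
  kappa <- parts$array_dwell[ip][seg_trial]
  phi <- 2 * kappa / (1 + kappa)
  shrink <- !is_matrix & seq_len(nseg_tot) != last[seg_trial]
  cut <- ifelse(shrink, seg_len * (1 - phi), 0)
  seg_len <- seg_len - cut
  seg_len[which(shrink) + 1L] <- seg_len[which(shrink) + 1L] + cut[shrink]

  # fixation counts and durations per segment (>= 100 ms each)
  pfix <- ip[seg_trial]
  sdlog_f <- sqrt(log(1 + (parts$fixation_dur_sd[pfix] /
                             parts$fixation_dur_mean[pfix])^2))
  dseg <- stats::rlnorm(nseg_tot,
                        log(parts$fixation_dur_mean[pfix]) - sdlog_f^2 / 2,
                        sdlog_f)
  k <- pmax(1L, pmin(as.integer(round(seg_len / dseg)),
                     as.integer(floor(seg_len / 0.1))))

  # decide the planted sweeps now, and give the first dwell enough
  # fixations to hold them (still respecting the 100 ms floor)
  roll_r <- stats::runif(N) < p_scan_t
  roll_c <- stats::runif(N) < p_scan_t
  need <- 3L * roll_r + 3L * roll_c
  k[spos] <- pmax(k[spos], pmin(need,
                                as.integer(floor(seg_len[spos] / 0.1))))
  M <- sum(k)
  fix_seg <- rep(seq_len(nseg_tot), k)
  w <- stats::rexp(M)
  ws <- as.vector(rowsum(w, fix_seg))[fix_seg]
  dur <- 0.1 + pmax(0, (seg_len - 0.1 * k))[fix_seg] * w / ws

  # AOI labels: array segments look at 10; matrix wandering dwells and
  # jumps among cells with first-block bias
  fix_trial <- seg_trial[fix_seg]
  aoi <- rep(10L, M)
  mfix <- is_matrix[fix_seg]
  nm <- sum(mfix)
  if (nm) {
    firstfix <- !duplicated(fix_seg)
    jump <- stats::runif(M) > ctl$stay_prob
    jump[firstfix] <- TRUE
    jm <- jump & mfix
    bias <- parts$first_block_bias[ip[fix_trial]]
    nj <- sum(jm)
    inblock <- stats::runif(nj) < bias[jm]
    cellA <- c(1L, 2L, 4L, 5L)[1L + as.integer(floor(stats::runif(nj) * 4))]
    cellB <- c(3L, 6L, 7L, 8L, 9L)[1L +
                                     as.integer(floor(stats::runif(nj) * 5))]
    tgt <- ifelse(inblock, cellA, cellB)
    jid <- cumsum(jm)
    aoi[mfix] <- tgt[pmax(1L, jid[mfix])]
  }

  # planted sweeps at the start of each trial's first matrix segment
  k1 <- k[spos]
  row_pick <- as.integer(floor(stats::runif(N) * 3))   # 0,1,2
  col_pick <- as.integer(floor(stats::runif(N) * 3))
  row_planted <- roll_r & k1 >= 3L
  col_planted <- roll_c & k1 >= (3L + 3L * row_planted)
  off1 <- (cumsum(k) - k + 1L)[spos]                   # first fixation slot
  if (any(row_planted)) {
    nr <- sum(row_planted)
    idx <- rep(off1[row_planted], each = 3) + rep(0:2, nr)
    aoi[idx] <- rep(3L * row_pick[row_planted], each = 3) + rep(1:3, nr)
  }
  if (any(col_planted)) {
    nc <- sum(col_planted)
    idx <- rep(off1[col_planted] + 3L * row_planted[col_planted],
               each = 3) + rep(0:2, nc)
    aoi[idx] <- rep(col_pick[col_planted], each = 3) +
      rep(c(1L, 4L, 7L), nc)
  }

  # off-AOI gap time sized to hit the participant's missing fraction
  t_real <- as.vector(rowsum(dur, fix_trial))
  miss <- parts$missing_frac[ip]
  G <- t_real * miss / (1 - miss)
  gw <- stats::rexp(M)
  gs <- as.vector(rowsum(gw, fix_trial))[fix_trial]
  gap <- G[fix_trial] * gw / gs
  cs <- cumsum(gap + dur)
  ftrial <- which(!duplicated(fix_trial))
  before <- (cs - (gap + dur))[ftrial]
  onset <- cs - dur - before[fix_trial]

  fixations <- data.frame(
    participant = parts$participant[ip[fix_trial]],
    group = parts$group[ip[fix_trial]],
    trial = items$item[ii[fix_trial]],
    onset = onset, duration = dur, aoi = aoi)

  truth <- data.frame(
    participant = parts$participant[ip], group = parts$group[ip],
    trial = items$item[ii], difficulty = items$difficulty[ii],
    p_scan_trial = p_scan_t, toggle_intensity_trial = rho_t,
    aoi_time = t_real, trial_duration = t_real + G,
    first_toggle_latent = ifelse(cens, NA_real_, t1),
    n_transitions = K, censored = cens,
    row_planted = row_planted, col_planted = col_planted)

  list(fixations = fixations, truth = truth)
}

#' Simulate a full cohort
#'
#' Draws participants for every group, generates each trial's fixation
#' sequence over AOIs 1--10 with off-AOI gaps, computes the realised
#' strategic indices, and draws responses from the accuracy model. The
#' truth tables record every drawn parameter and latent event so that
#' parameter-recovery tests can compare pipeline output against the
#' generator's ground truth.
#'
#' @param config a [sim_config()].
#' @param seed optional override of \code{config$seed}.
#' @return Object of class \code{gaze_cohort}: list with \code{fixations}
#'   (participant, group, trial, onset, duration, aoi), \code{responses}
#'   (participant, group, trial, item, chosen, correct, error_type,
#'   n_relations_matched, response_time, trial_duration, valid_fraction),
#'   \code{trial_indices}, \code{items}, \code{options},
#'   \code{participants} (drawn parameters = participant truth),
#'   \code{trial_truth}, and \code{config}.
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  set.seed(if (is.null(seed)) config$seed else seed)
  bank <- generate_item_bank(config$n_options)
  parts <- draw_participants(config)
  eng <- sim_engine(parts, bank$items, config$ctl)
  ti <- trial_indices(eng$fixations)
  key_t <- paste(eng$truth$participant, eng$truth$trial)
  ti <- ti[match(key_t, paste(ti$participant, ti$trial)), ]
  resp <- draw_responses(ti, eng$truth, parts, bank, config$accuracy)
  structure(list(fixations = eng$fixations, responses = resp,
                 trial_indices = ti, items = bank$items,
                 options = bank$options, participants = parts,
                 trial_truth = eng$truth, config = config),
            class = "gaze_cohort")
}

# logistic accuracy gate + weighted distractor choice (Gumbel argmax)
draw_responses <- function(ti, truth, parts, bank, acc) {
  N <- nrow(ti)
  item_row <- match(truth$trial, bank$items$item)
  dc <- bank$items$difficulty[item_row] - 50
  b0 <- parts$acc_b0[match(truth$participant, parts$participant)]
  eta <- b0 + acc$b_encoding * ti$encoding +
    acc$b_integration * ti$integration +
    acc$b_ttft * ti$time_to_first_toggle +
    acc$b_toggle_rate * ti$toggle_rate +
    acc$b_difficulty * dc
  p <- stats::plogis(eta)
  nopt <- bank$items$n_options[1]
  co <- bank$items$correct_option[item_row]
  if (isTRUE(acc$uniform)) {
    chosen <- 1L + as.integer(floor(stats::runif(N) * nopt))
  } else {
    correct_draw <- stats::runif(N) < p
    # option type matrix (items x options) -> distractor log-weights
    om <- bank$options
    itr <- match(om$item, bank$items$item)
    type <- matrix("partial", nrow(bank$items), nopt)
    type[cbind(itr, om$option)] <-
      ifelse(om$is_correct, "correct",
             ifelse(om$is_duplicate, "duplicate",
                    ifelse(om$has_novel_feature, "novel", "partial")))
    basew <- matrix(acc$w_partial, nrow(bank$items), nopt)
    basew[type == "novel"] <- acc$w_novel
    basew[type == "duplicate"] <- acc$w_duplicate
    logw <- log(basew)[item_row, , drop = FALSE]
    dupm <- type[item_row, , drop = FALSE] == "duplicate"
    logw[dupm] <- logw[dupm] +
      acc$dup_toggle_coef * ti$toggle_rate[row(dupm)[dupm]]
    logw[cbind(seq_len(N), co)] <- -Inf
    gum <- -log(-log(matrix(stats::runif(N * nopt), N, nopt)))
    pick <- max.col(logw + gum, ties.method = "first")
    chosen <- ifelse(correct_draw, co, pick)
  }
  correct <- chosen == co
  feat <- bank$options[match(paste(truth$trial, chosen),
                             paste(bank$options$item,
                                   bank$options$option)), ]
  data.frame(
    participant = truth$participant, group = truth$group,
    trial = truth$trial, item = truth$trial, chosen = chosen,
    correct = correct,
    n_relations_matched = feat$n_relations_matched,
    error_type = classify_error(correct, feat$is_duplicate,
                                feat$has_novel_feature,
                                feat$n_relations_matched),
    p_correct_latent = if (isTRUE(acc$uniform)) 1 / nopt else p,
    response_time = ti$response_time,
    trial_duration = truth$trial_duration,
    valid_fraction = truth$aoi_time / truth$trial_duration)
}

#' Simulate a single trial
#'
#' Convenience wrapper around the cohort engine for one participant and one
#' item: returns the fixation sequence, its realised indices, the response
#' and the latent truth. Deterministic given the seed.
#'
#' @param params a [strategy_params()].
#' @param item one row of the \code{items} table from
#'   [generate_item_bank()] (defaults to item 12 of the default bank).
#' @param seed integer seed.
#' @param accuracy an [accuracy_coefs()].
#' @return List with \code{fixations}, \code{indices}, \code{response},
#'   \code{truth}.
#' @export
simulate_trial <- function(params, item = NULL, seed = 1,
                           accuracy = accuracy_coefs()) {
  stopifnot(inherits(params, "strategy_params"))
  bank <- generate_item_bank()
  if (is.null(item)) item <- bank$items[12, ]
  set.seed(seed)
  parts <- data.frame(
    participant = "p0001", group = "single", competence = 0,
    p_scan = params$p_scan, toggle_intensity = params$toggle_intensity,
    first_toggle_mean = params$first_toggle_mean,
    rt_mean = params$rt_mean,
    adapt_scan_slope = params$adapt_scan_slope,
    adapt_toggle_slope = params$adapt_toggle_slope,
    missing_frac = params$missing_frac,
    first_block_bias = params$first_block_bias,
    fixation_dur_mean = params$fixation_dur_mean,
    fixation_dur_sd = params$fixation_dur_sd,
    array_dwell = params$array_dwell,
    acc_b0 = params$acc_b0,
    true_scan_slope = params$adapt_scan_slope,
    true_toggle_slope = params$toggle_intensity * params$adapt_toggle_slope)
  ctl <- sim_config()$ctl
  eng <- sim_engine(parts, item, ctl)
  ti <- trial_indices(eng$fixations)
  bank2 <- list(items = item, options =
                  bank$options[bank$options$item == item$item, ])
  resp <- draw_responses(ti, eng$truth, parts, bank2, accuracy)
  list(fixations = eng$fixations, indices = ti, response = resp,
       truth = eng$truth)
}

#' Synthesise raw gaze samples from a fixation table
#'
#' Renders each AOI-labelled fixation as a run of samples at the AOI
#' rectangle's centre plus isotropic jitter, at the nominal sampling rate;
#' gaps between fixations produce no samples (signal loss), so the raw
#' stream exercises the preprocessing path end-to-end.
#'
#' @param fixations fixation table with \code{participant}, \code{trial},
#'   \code{onset}, \code{duration}, \code{aoi}.
#' @param layout an [aoi_layout()].
#' @param rate sampling rate (Hz).
#' @param jitter_px SD of positional jitter.
#' @param seed seed for the jitter.
#' @return Data frame \code{participant}, \code{trial}, \code{t}, \code{x},
#'   \code{y}, \code{valid}.
#' @export
synthesize_samples <- function(fixations, layout = default_aoi_layout(),
                               rate = 50, jitter_px = 4, seed = 1) {
  set.seed(seed)
  f <- as.data.frame(fixations)
  r <- layout$rects
  cx <- (r$x0 + r$x1) / 2; cy <- (r$y0 + r$y1) / 2
  ns <- pmax(2L, as.integer(round(f$duration * rate)))
  idx <- rep(seq_len(nrow(f)), ns)
  step <- sequence(ns) - 1L
  t <- f$onset[idx] + step / rate
  a <- f$aoi[idx]
  x <- cx[a] + stats::rnorm(length(idx), 0, jitter_px)
  y <- cy[a] + stats::rnorm(length(idx), 0, jitter_px)
  out <- data.frame(participant = f$participant[idx],
                    trial = f$trial[idx], t = t, x = x, y = y,
                    valid = TRUE)
  out[order(out$participant, out$trial, out$t), ]
}

#' @exportS3Method base::print
print.gaze_cohort <- function(x, ...) {
  cat("Simulated matrix-completion cohort\n")
  tab <- table(x$participants$group)
  cat("  participants:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "), "\n")
  cat("  trials:", nrow(x$responses), " fixations:", nrow(x$fixations), "\n")
  cat("  mean accuracy:",
      round(100 * mean(x$responses$correct), 1), "%\n")
  invisible(x)
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat("Simulation config:", paste(x$groups, collapse = "/"),
      "x", paste(x$n_per_group, collapse = "/"), "participants,",
      x$n_options, "options, seed", x$seed,
      if (x$coupled) "(coupled)" else "(null)", "\n")
  invisible(x)
}

#' @exportS3Method base::print
print.strategy_params <- function(x, ...) {
  cat("Strategy parameters:\n")
  v <- unlist(x)
  print(round(v, 4))
  invisible(x)
}
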