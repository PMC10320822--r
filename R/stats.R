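#' Univariate outlier trimming
#'
#' Flags values more than \code{k} SDs from their group mean (mean and SD
#' taken from the full group, single pass). With zero SD nothing is
#' removed. Trimming is applied per analysis, not globally.
#'
#' @param x numeric vector.
#' @param group optional grouping vector (same length as \code{x}).
#' @param k SD multiplier (default 2.5).
#' @return List: \code{keep} (logical), \code{n_removed}, \code{report}
#'   (per-group counts).
#' @export
remove_outliers <- function(x, group = NULL, k = 2.5) {
  if (is.null(group)) group <- rep("all", length(x))
  keep <- rep(TRUE, length(x))
  for (g in unique(group)) {
    i <- which(group == g & !is.na(x))
    if (length(i) < 3) next
    m <- mean(x[i]); s <- stats::sd(x[i])
    if (is.na(s) || s == 0) next
    keep[i] <- abs(x[i] - m) <= k * s
  }
  keep[is.na(x)] <- FALSE
  rep_df <- aggregate(list(n_removed = !keep & !is.na(x)),
                      by = list(group = group), FUN = sum)
  list(keep = keep, n_removed = sum(!keep & !is.na(x)), report = rep_df)
}

#' Two-group comparison with variance-homogeneity check
#'
#' Welch's t test by default (pooled-variance variant behind
#' \code{var_equal}), plus a Levene/Brown-Forsythe test on group-centred
#' absolute deviations (median-centred by default). An optional covariate
#' (e.g. the fraction of available eyetracking data) switches the mean
#' comparison to an adjusted linear model.
#'
#' @param x numeric outcome.
#' @param group two-level grouping vector.
#' @param var_equal use the pooled-variance t test.
#' @param center \code{"median"} (Brown-Forsythe) or \code{"mean"} for the
#'   variance test.
#' @param covariate optional numeric covariate.
#' @return List with \code{t}, \code{df}, \code{p}, the variance test
#'   (\code{levene_F}, \code{levene_p}) and, when a covariate is given,
#'   the adjusted group effect.
#' @export
compare_groups <- function(x, group, var_equal = FALSE, center = "median",
                           covariate = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required")
  if (any(table(group) < 2)) stop("each group needs >= 2 values")
  tt <- stats::t.test(x ~ group, var.equal = var_equal)
  lev <- car::leveneTest(x, group, center = match.arg(center,
                                                      c("median", "mean")))
  out <- list(t = unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value, mean_diff = unname(diff(rev(tt$estimate))),
              levene_F = lev[1, "F value"], levene_p = lev[1, "Pr(>F)"])
  if (!is.null(covariate)) {
    fit <- stats::lm(x ~ group + covariate)
    sm <- summary(fit)$coefficients
    out$adjusted_t <- sm[2, "t value"]
    out$adjusted_p <- sm[2, "Pr(>|t|)"]
  }
  out
}

# a boundary (singular) random-effects fit is still a valid fit; only
# optimizer failures count as non-convergence
lme4_converged <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  is.null(msgs) || all(grepl("singular|boundary", msgs))
}

# Pearson correlation with t-based p and CI, as one result row
cor_row <- function(x, y, index, group = "all") {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(data.frame(index = index, group = group, r = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_, t = NA_real_,
                      p = NA_real_, n = n))
  ct <- stats::cor.test(x[ok], y[ok])
  ci <- if (n >= 4) ct$conf.int else c(NA_real_, NA_real_)
  data.frame(index = index, group = group, r = unname(ct$estimate),
             ci_lo = ci[1], ci_hi = ci[2], t = unname(ct$statistic),
             p = ct$p.value, n = n)
}

#' Correlations between strategic indices and overall performance
#'
#' For each index and group: trim outliers (on the index and on
#' performance, per analysis), then Pearson's r against percent correct
#' with t-based p and 95\% CI. Optionally excludes below-chance
#' participants first (sensitivity re-analysis).
#'
#' @param participants participant table from [aggregate_participants()]
#'   with \code{percent_correct} and a \code{group} column (optional).
#' @param indices character vector of index columns.
#' @param outlier_k SD multiplier for trimming; \code{Inf} disables.
#' @param exclude_below_chance drop participants below \code{chance}.
#' @param chance chance-level percent (see [chance_level()]).
#' @return Data frame of class \code{index_cor}: index, group, r, ci_lo,
#'   ci_hi, t, p, n.
#' @export
correlate_index_performance <- function(participants,
                                        indices = c("pct_encoding",
                                                    "pct_integration",
                                                    "n_toggles",
                                                    "toggle_rate",
                                                    "time_to_first_toggle",
                                                    "prop_matrix_time",
                                                    "matrix_time_distribution"),
                                        outlier_k = 2.5,
                                        exclude_below_chance = FALSE,
                                        chance = chance_level(8)) {
  d <- as.data.frame(participants)
  if (is.null(d$group)) d$group <- "all"
  if (exclude_below_chance) d <- d[d$percent_correct >= chance, ]
  rows <- list()
  for (g in unique(d$group)) {
    dg <- d[d$group == g, ]
    for (ix in indices) {
      keep <- remove_outliers(dg[[ix]], k = outlier_k)$keep &
        remove_outliers(dg$percent_correct, k = outlier_k)$keep
      rows[[paste(g, ix)]] <- cor_row(dg[[ix]][keep],
                                      dg$percent_correct[keep], ix, g)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("index_cor", "data.frame")
  out
}

#' @exportS3Method base::print
print.index_cor <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Trial-level mixed logistic model for one strategic index
#'
#' Fits \code{correct ~ index + difficulty + (1 | participant)} by
#' \code{lme4::glmer} (binomial), the trial-level specificity model: does
#' the index predict accuracy on the very trial it was measured on, over
#' and above item difficulty? Difficulty is centred at 50 and scaled to
#' tens internally; reported coefficients are per original unit.
#'
#' @param trials trial table with \code{correct}, the index column,
#'   \code{difficulty} and \code{participant}.
#' @param index name of the index column.
#' @param nAGQ integration points passed to \code{glmer} (0 is fast and
#'   adequate for calibration sweeps).
#' @return Object of class \code{trial_glmm}: coefficient table (B, Wald
#'   95\% CI, z, p), convergence flag and the underlying fit.
#' @export
trial_level_model <- function(trials, index, nAGQ = 1) {
  d <- as.data.frame(trials)
  d$.index <- as.numeric(d[[index]])
  d <- d[stats::complete.cases(d$correct, d$.index, d$difficulty), ]
  if (stats::var(d$.index) == 0)
    return(structure(list(index = index, converged = FALSE,
                          coefficients = NULL, fit = NULL,
                          message = "index has zero variance"),
                     class = "trial_glmm"))
  d$.diff10 <- (d$difficulty - 50) / 10
  fit <- suppressWarnings(suppressMessages(
    lme4::glmer(correct ~ .index + .diff10 + (1 | participant),
                data = d, family = stats::binomial(), nAGQ = nAGQ)))
  conv <- lme4_converged(fit)
  sm <- summary(fit)$coefficients
  co <- data.frame(term = c(index, "difficulty"),
                   B = sm[2:3, "Estimate"], se = sm[2:3, "Std. Error"],
                   z = sm[2:3, "z value"], p = sm[2:3, "Pr(>|z|)"])
  co$B[2] <- co$B[2] / 10; co$se[2] <- co$se[2] / 10
  co$z[2] <- co$B[2] / co$se[2]
  co$ci_lo <- co$B - 1.96 * co$se
  co$ci_hi <- co$B + 1.96 * co$se
  structure(list(index = index, converged = conv, coefficients = co,
                 ranef_var = unname(lme4::VarCorr(fit)$participant[1]),
                 fit = fit),
            class = "trial_glmm")
}

#' @exportS3Method base::print
print.trial_glmm <- function(x, ...) {
  cat("Trial-level mixed logistic model: accuracy ~", x$index,
      "+ difficulty + (1 | participant)\n")
  if (!x$converged) cat("  [did not converge", x$message, "]\n")
  if (!is.null(x$coefficients)) {
    y <- x$coefficients
    y[-1] <- lapply(y[-1], signif, 3)
    print(y, row.names = FALSE)
    cat("  random-intercept variance:", signif(x$ranef_var, 3), "\n")
  }
  invisible(x)
}

#' Item-level strategy adaptation to difficulty
#'
#' Averages each strategic index within item across a group, then
#' correlates the item means with item difficulty (n = number of items).
#' Positive r for an index means the group shifts toward that behaviour on
#' harder problems.
#'
#' @param trials trial table with index columns, \code{difficulty} (per
#'   item x group) and optionally \code{group}.
#' @param indices index columns to analyse.
#' @return \code{index_cor} data frame (one row per index x group).
#' @export
item_level_adaptation <- function(trials,
                                  indices = c("encoding", "integration",
                                              "n_toggles", "toggle_rate",
                                              "time_to_first_toggle",
                                              "prop_matrix_time",
                                              "matrix_time_distribution")) {
  d <- as.data.frame(trials)
  if (is.null(d$group)) d$group <- "all"
  rows <- list()
  for (g in unique(d$group)) {
    dg <- d[d$group == g, ]
    im <- aggregate(dg[c(indices, "difficulty")],
                    by = list(item = dg$trial),
                    FUN = function(v) mean(as.numeric(v), na.rm = TRUE))
    for (ix in indices)
      rows[[paste(g, ix)]] <- cor_row(im[[ix]], im$difficulty, ix, g)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("index_cor", "data.frame")
  out
}

#' Per-participant adaptation slopes (random difficulty slopes)
#'
#' Fits \code{index ~ difficulty + (difficulty | participant)} --
#' logistic for binary indices (encoding, integration), linear otherwise --
#' and extracts each participant's conditional slope as their
#' strategy-adaptation index: values away from 0 mean stronger adjustment
#' of that behaviour to problem difficulty. If the mixed fit fails, falls
#' back to per-participant ordinary regressions (flagged).
#'
#' @param trials trial table with the index column, \code{difficulty} and
#'   \code{participant}.
#' @param index index column name.
#' @param binary force logistic (\code{TRUE}) or linear (\code{FALSE});
#'   default guesses from the data.
#' @param random_intercept also include a random intercept (default TRUE).
#' @return Object of class \code{adaptation_fit}: \code{slopes}
#'   (participant, slope, in index units per difficulty point),
#'   \code{fixed_slope}, \code{method} ("glmm", "lmm" or "ols"),
#'   \code{converged}, and the fit.
#' @export
adaptation_slopes <- function(trials, index, binary = NULL,
                              random_intercept = TRUE) {
  d <- as.data.frame(trials)
  d$.y <- as.numeric(d[[index]])
  d <- d[stats::complete.cases(d$.y, d$difficulty, d$participant), ]
  d$.d10 <- (d$difficulty - 50) / 10
  if (is.null(binary)) binary <- all(d$.y %in% 0:1)
  re <- if (random_intercept) "(1 + .d10 | participant)" else
    "(0 + .d10 | participant)"
  form <- stats::as.formula(paste(".y ~ .d10 +", re))
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      if (binary)
        lme4::glmer(form, data = d, family = stats::binomial(), nAGQ = 0)
      else
        lme4::lmer(form, data = d, REML = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    conv <- lme4_converged(fit)
    cf <- stats::coef(fit)$participant
    slopes <- data.frame(participant = rownames(cf),
                         slope = cf[, ".d10"] / 10)
    fixed <- unname(lme4::fixef(fit)[".d10"]) / 10
    method <- if (binary) "glmm" else "lmm"
  } else {
    # fall back to independent per-participant regressions
    sp <- split(d, d$participant)
    sl <- vapply(sp, function(dd) {
      if (stats::var(dd$.d10) == 0) return(NA_real_)
      if (binary && stats::var(dd$.y) > 0) {
        f <- suppressWarnings(stats::glm(.y ~ .d10, data = dd,
                                         family = stats::binomial()))
        stats::coef(f)[2]
      } else stats::coef(stats::lm(.y ~ .d10, data = dd))[2]
    }, numeric(1))
    slopes <- data.frame(participant = names(sl), slope = sl / 10)
    fixed <- mean(slopes$slope, na.rm = TRUE)
    method <- "ols"
    conv <- FALSE
  }
  rownames(slopes) <- NULL
  structure(list(index = index, slopes = slopes, fixed_slope = fixed,
                 method = method, converged = conv, binary = binary,
                 fit = fit),
            class = "adaptation_fit")
}

#' @exportS3Method base::print
print.adaptation_fit <- function(x, ...) {
  cat("Adaptation slopes:", x$index, "~ difficulty, method", x$method,
      if (x$binary) "(logistic link)" else "(linear link)", "\n")
  cat("  fixed slope:", signif(x$fixed_slope, 4), "per difficulty point;",
      nrow(x$slopes), "participants",
      if (!x$converged) "[not converged]" else "", "\n")
  invisible(x)
}

#' @export
coef.adaptation_fit <- function(object, ...) {
  stats::setNames(object$slopes$slope, object$slopes$participant)
}

#' Per-group adaptation slopes
#'
#' Fits [adaptation_slopes()] separately within each group (mirroring an
#' analysis run within each age group) and pools the per-participant
#' slopes. Fitting within group avoids shrinking all groups toward one
#' common difficulty slope when baselines differ.
#'
#' @inheritParams adaptation_slopes
#' @param group_col grouping column; when absent a single model is fitted.
#' @return Object of class \code{adaptation_fit} whose \code{fit} element
#'   is the named list of group fits.
#' @export
adaptation_slopes_by_group <- function(trials, index, group_col = "group",
                                       binary = NULL,
                                       random_intercept = TRUE) {
  d <- as.data.frame(trials)
  if (is.null(d[[group_col]]))
    return(adaptation_slopes(d, index, binary = binary,
                             random_intercept = random_intercept))
  fits <- lapply(split(d, d[[group_col]]), adaptation_slopes,
                 index = index, binary = binary,
                 random_intercept = random_intercept)
  slopes <- do.call(rbind, lapply(fits, `[[`, "slopes"))
  rownames(slopes) <- NULL
  structure(list(index = index, slopes = slopes,
                 fixed_slope = mean(vapply(fits, `[[`, 0, "fixed_slope")),
                 method = fits[[1]]$method,
                 converged = all(vapply(fits, `[[`, TRUE, "converged")),
                 binary = fits[[1]]$binary, fit = fits),
            class = "adaptation_fit")
}

#' Correlations between adaptation slopes and overall performance
#'
#' Pearson r (per group) between per-participant difficulty slopes of each
#' index and percent correct, with the usual outlier trimming.
#'
#' @param slopes named list of [adaptation_slopes()] fits (names = index).
#' @param performance participant table with \code{participant},
#'   \code{percent_correct}, optional \code{group}.
#' @param outlier_k SD multiplier for trimming; \code{Inf} disables.
#' @return \code{index_cor} data frame.
#' @export
correlate_adaptation_performance <- function(slopes, performance,
                                             outlier_k = 2.5) {
  perf <- as.data.frame(performance)
  if (is.null(perf$group)) perf$group <- "all"
  rows <- list()
  for (ix in names(slopes)) {
    s <- slopes[[ix]]$slopes
    m <- merge(s, perf, by = "participant")
    for (g in unique(m$group)) {
      mg <- m[m$group == g, ]
      keep <- remove_outliers(mg$slope, k = outlier_k)$keep &
        remove_outliers(mg$percent_correct, k = outlier_k)$keep
      rows[[paste(g, ix)]] <- cor_row(mg$slope[keep],
                                      mg$percent_correct[keep], ix, g)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("index_cor", "data.frame")
  out
}

#' End-to-end strategy analysis of a trial table
#'
#' One call from trial-level indices + responses to the full result set:
#' participant aggregates and descriptives with trial-order reliability,
#' index-performance correlations, trial-level mixed logistic models,
#' item-level difficulty adaptation, and adaptation-slope correlations
#' with performance. Item difficulty is computed per group from the
#' responses (100 minus mean percent correct) and merged into the trial
#' table.
#'
#' @param trials output of [trial_indices()].
#' @param responses response table with \code{participant}, \code{trial},
#'   \code{item}, \code{correct}, optional \code{group}.
#' @param trial_model_indices indices for the trial-level models.
#' @param adaptation_indices indices for the random-slope models.
#' @param nAGQ passed to [trial_level_model()].
#' @return List of class \code{strategy_analysis} with elements
#'   \code{participants}, \code{descriptives}, \code{reliability},
#'   \code{item_difficulty}, \code{index_performance} ,
#'   \code{trial_models}, \code{item_adaptation},
#'   \code{adaptation_fits}, \code{adaptation_performance}.
#' @export
run_strategy_analysis <- function(trials, responses,
                                  trial_model_indices =
                                    c("encoding", "toggle_rate",
                                      "time_to_first_toggle",
                                      "prop_matrix_time"),
                                  adaptation_indices =
                                    c("encoding", "integration",
                                      "toggle_rate",
                                      "time_to_first_toggle"),
                                  nAGQ = 1) {
  trials <- as.data.frame(trials)
  responses <- as.data.frame(responses)
  if (is.null(responses$item)) responses$item <- responses$trial
  idiff <- item_difficulty(responses)
  grp <- if (!is.null(responses$group)) "group" else NULL
  tr <- merge(trials,
              responses[, c("participant", "trial", "correct",
                            if (!is.null(responses$group)) "group")],
              by = c("participant", "trial"))
  tr <- merge(tr, idiff[, c("item", "group", "difficulty")],
              by.x = c("trial", if (!is.null(tr$group)) "group" else NULL),
              by.y = c("item", if (!is.null(tr$group)) "group" else NULL))
  parts <- aggregate_participants(trials, responses)
  desc_cols <- c("percent_correct", "response_time", "pct_encoding",
                 "pct_integration", "n_toggles", "toggle_rate",
                 "time_to_first_toggle", "prop_matrix_time",
                 "matrix_time_distribution")
  desc_cols <- intersect(desc_cols, names(parts))
  grp_vec <- if (!is.null(parts$group)) parts$group else
    rep("all", nrow(parts))
  descriptives <- do.call(rbind, lapply(split(parts, grp_vec), function(d) {
    data.frame(group = d$group[1] %||% "all",
               index = desc_cols,
               mean = vapply(desc_cols, function(cn) mean(d[[cn]],
                                                          na.rm = TRUE), 0),
               sd = vapply(desc_cols, function(cn) stats::sd(d[[cn]],
                                                             na.rm = TRUE),
                           0))
  }))
  rownames(descriptives) <- NULL
  rel_ix <- c("encoding", "integration", "n_toggles", "toggle_rate",
              "time_to_first_toggle", "prop_matrix_time",
              "matrix_time_distribution")
  reliability <- data.frame(
    index = rel_ix,
    alpha = vapply(rel_ix, function(ix)
      tryCatch(cronbach_alpha(tr, index = ix), error = function(e)
        NA_real_), 0))
  trial_models <- lapply(stats::setNames(trial_model_indices,
                                         trial_model_indices),
                         function(ix) trial_level_model(tr, ix,
                                                        nAGQ = nAGQ))
  fits <- lapply(stats::setNames(adaptation_indices, adaptation_indices),
                 function(ix) adaptation_slopes_by_group(tr, ix))
  structure(list(
    participants = parts,
    descriptives = descriptives,
    reliability = reliability,
    item_difficulty = idiff,
    index_performance = correlate_index_performance(parts),
    trial_models = trial_models,
    item_adaptation = item_level_adaptation(tr),
    adaptation_fits = fits,
    adaptation_performance = correlate_adaptation_performance(fits, parts)),
    class = "strategy_analysis")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.strategy_analysis <- function(x, ...) {
  cat("Matrix-completion strategy analysis\n")
  cat("  participants:", nrow(x$participants), "\n\n")
  cat("Index-performance correlations:\n")
  print(x$index_performance)
  cat("\nItem-level adaptation (index vs difficulty):\n")
  print(x$item_adaptation)
  cat("\nAdaptation-performance correlations:\n")
  print(x$adaptation_performance)
  invisible(x)
}
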