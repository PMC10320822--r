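#' Detect row/column encoding events in an AOI sequence
#'
#' An encoding event is a consecutive series of three fixations covering the
#' three distinct cells of one matrix row (\{1,2,3\}, \{4,5,6\}, \{7,8,9\})
#' or one column (\{1,4,7\}, \{2,5,8\}, \{3,6,9\}), at any point during the
#' trial. By default the three cells may be visited in any order
#' (\code{order_strict = FALSE}); the strict variant requires the canonical
#' left-to-right / top-to-bottom order, for sensitivity analysis. Off-AOI
#' fixations (\code{NA}) and solution-array fixations (10) break a window:
#' an encoding sweep must be an unbroken scan of the matrix.
#'
#' @param aoi_seq integer vector of AOI labels (1--10, \code{NA} off-AOI) in
#'   fixation order.
#' @param order_strict require the in-order sweep variant.
#' @return Named logical vector \code{c(row = , col = )}.
#' @export
detect_encoding <- function(aoi_seq, order_strict = FALSE) {
  a <- as.integer(aoi_seq)
  n <- length(a)
  if (n < 3) return(c(row = FALSE, col = FALSE))
  i <- seq_len(n - 2)
  a1 <- a[i]; a2 <- a[i + 1]; a3 <- a[i + 2]
  ok <- !is.na(a1) & !is.na(a2) & !is.na(a3) &
        a1 <= 9 & a2 <= 9 & a3 <= 9
  code <- if (order_strict) {
    a1 * 100 + a2 * 10 + a3
  } else {
    m1 <- pmin(a1, a2, a3); m3 <- pmax(a1, a2, a3)
    m1 * 100 + (a1 + a2 + a3 - m1 - m3) * 10 + m3
  }
  c(row = any(ok & code %in% c(123L, 456L, 789L)),
    col = any(ok & code %in% c(147L, 258L, 369L)))
}

#' Detect integration (both a row and a column encoding event)
#'
#' True when the trial contains at least one horizontal and at least one
#' vertical encoding event; the two events may overlap or be disjoint.
#'
#' @inheritParams detect_encoding
#' @return Logical flag.
#' @export
detect_integration <- function(aoi_seq, order_strict = FALSE) {
  e <- detect_encoding(aoi_seq, order_strict = order_strict)
  unname(e["row"] && e["col"])
}

#' Count matrix/solution-array toggles
#'
#' A toggle is a gaze transition from any matrix cell (1--9) to the solution
#' array (10) or vice versa. Off-AOI fixations are transparent by default
#' (a blink between matrix and array still yields one toggle); set
#' \code{through_na = FALSE} to let them break adjacency instead. Repeated
#' consecutive fixations on the same AOI are collapsed first, so
#' re-fixations within a region never create transitions.
#'
#' @inheritParams detect_encoding
#' @param through_na treat off-AOI fixations as transparent for adjacency.
#' @return Integer toggle count.
#' @export
count_toggles <- function(aoi_seq, through_na = TRUE) {
  a <- as.integer(aoi_seq)
  if (through_na) a <- a[!is.na(a)]
  if (length(a) < 2) return(0L)
  a <- a[c(TRUE, is.na(a[-1]) | is.na(a[-length(a)]) |
             a[-1] != a[-length(a)])]
  if (length(a) < 2) return(0L)
  x <- a[-length(a)]; y <- a[-1]
  sum(!is.na(x) & !is.na(y) & ((x <= 9 & y == 10) | (x == 10 & y <= 9)))
}

#' Toggle rate
#'
#' Toggles per second of detected looking time: the toggle count divided by
#' the trial's response time, where response time is the total detected
#' fixation time on the AOIs (not wall-clock time). This removes the bias
#' whereby slower responders accumulate more toggles.
#'
#' @param n_toggles toggle count.
#' @param response_time total detected AOI fixation time (s), > 0.
#' @return Rate (1/s); \code{NA} with a warning when \code{response_time}
#'   is not positive (such trials are dropped downstream).
#' @export
toggle_rate <- function(n_toggles, response_time) {
  out <- ifelse(response_time > 0, n_toggles / response_time, NA_real_)
  if (anyNA(out)) warning("toggle rate undefined for response_time <= 0")
  out
}

#' Time to first toggle
#'
#' Cumulative detected AOI fixation time strictly before the first fixation
#' on the solution array. Trials with no array fixation are censored at the
#' response time and flagged; dropping them instead would bias the index
#' against pure constructive matchers.
#'
#' @param fixes one trial's fixations: data frame with \code{aoi} and
#'   \code{duration}, in time order.
#' @return List with \code{time} (s) and \code{censored} (logical).
#' @export
time_to_first_toggle <- function(fixes) {
  aoi <- fixes$aoi; dur <- fixes$duration
  on_aoi <- !is.na(aoi)
  first10 <- which(on_aoi & aoi == 10)[1]
  if (is.na(first10)) {
    list(time = sum(dur[on_aoi]), censored = TRUE)
  } else {
    before <- seq_len(first10 - 1)
    list(time = sum(dur[before][on_aoi[before]]), censored = FALSE)
  }
}

#' Proportion of looking time on the matrix
#'
#' Time fixated on matrix cells 1--9 divided by the total time fixated on
#' the matrix and the solution array.
#'
#' @inheritParams time_to_first_toggle
#' @return Proportion in \[0, 1\]; \code{NA} with a warning when no AOI
#'   time exists.
#' @export
proportion_matrix_time <- function(fixes) {
  aoi <- fixes$aoi; dur <- fixes$duration
  tm <- sum(dur[!is.na(aoi) & aoi <= 9])
  ta <- sum(dur[!is.na(aoi) & aoi == 10])
  if (tm + ta <= 0) {
    warning("no AOI fixation time; proportion undefined")
    return(NA_real_)
  }
  tm / (tm + ta)
}

#' Matrix time distribution index
#'
#' The proportion of matrix looking time on the initial cells \{1,2,4,5\}
#' minus the proportion on the latter cells \{3,6,7,8,9\}. Values near 0
#' reflect even coverage of the matrix (more complete relational encoding);
#' strongly negative values reflect dwelling on the final row/column.
#'
#' @inheritParams time_to_first_toggle
#' @return Index in \[-1, 1\]; \code{NA} with a warning when there is no
#'   matrix fixation time.
#' @export
matrix_time_distribution <- function(fixes) {
  aoi <- fixes$aoi; dur <- fixes$duration
  m <- !is.na(aoi) & aoi <= 9
  tm <- sum(dur[m])
  if (tm <= 0) {
    warning("no matrix fixation time; distribution index undefined")
    return(NA_real_)
  }
  t_first <- sum(dur[m & aoi %in% c(1, 2, 4, 5)])
  (t_first - (tm - t_first)) / tm
}

#' Trial-level strategic indices for a cohort fixation table
#'
#' Computes all seven strategic indices, the response time (total detected
#' AOI fixation time) and the censoring flag for every participant x trial
#' in one pass. Equivalent to applying the scalar index functions trial by
#' trial, but vectorised.
#'
#' @param fixations data frame with columns \code{participant}, \code{trial},
#'   \code{onset}, \code{duration}, \code{aoi} (1--10 or \code{NA}).
#' @param order_strict,through_na see [detect_encoding()], [count_toggles()].
#' @return Data frame, one row per trial: \code{participant}, \code{trial},
#'   \code{encoding}, \code{integration}, \code{n_toggles},
#'   \code{toggle_rate}, \code{time_to_first_toggle}, \code{ttft_censored},
#'   \code{prop_matrix_time}, \code{matrix_time_distribution},
#'   \code{response_time}. Ratio indices are \code{NA} on trials whose
#'   denominator is zero.
#' @export
trial_indices <- function(fixations, order_strict = FALSE,
                          through_na = TRUE) {
  f <- as.data.frame(fixations)
  f <- f[order(f$participant, f$trial, f$onset, method = "radix"), ]
  n_all <- nrow(f)
  newg <- if (n_all) c(TRUE, f$participant[-1] != f$participant[-n_all] |
                         f$trial[-1] != f$trial[-n_all]) else logical(0)
  g <- cumsum(newg)
  ng <- if (n_all) g[n_all] else 0L
  first_idx <- which(newg)
  out <- data.frame(participant = f$participant[first_idx],
                    trial = f$trial[first_idx])
  a <- as.integer(f$aoi); dur <- f$duration
  on_aoi <- !is.na(a)

  sum_by <- function(x) {
    s <- numeric(ng)
    r <- rowsum(x, g)
    s[as.integer(rownames(r))] <- r
    s
  }
  rt <- sum_by(dur * on_aoi)
  tm <- sum_by(dur * (on_aoi & a <= 9))
  ta <- sum_by(dur * (on_aoi & a == 10))
  tf <- sum_by(dur * (on_aoi & a %in% c(1L, 2L, 4L, 5L)))

  # encoding windows: three consecutive matrix fixations within one trial
  n <- nrow(f)
  row_ev <- col_ev <- logical(ng)
  if (n >= 3) {
    i <- seq_len(n - 2)
    same <- g[i] == g[i + 2]
    a1 <- a[i]; a2 <- a[i + 1]; a3 <- a[i + 2]
    ok <- same & !is.na(a1) & !is.na(a2) & !is.na(a3) &
          a1 <= 9 & a2 <= 9 & a3 <= 9
    code <- if (order_strict) {
      a1 * 100L + a2 * 10L + a3
    } else {
      m1 <- pmin(a1, a2, a3); m3 <- pmax(a1, a2, a3)
      m1 * 100L + (a1 + a2 + a3 - m1 - m3) * 10L + m3
    }
    hit_r <- ok & code %in% c(123L, 456L, 789L)
    hit_c <- ok & code %in% c(147L, 258L, 369L)
    row_ev <- sum_by(c(hit_r, FALSE, FALSE) * 1) > 0
    col_ev <- sum_by(c(hit_c, FALSE, FALSE) * 1) > 0
  }

  # toggles on the collapsed, optionally NA-transparent sequence
  keep <- if (through_na) on_aoi else rep(TRUE, n)
  ak <- a[keep]; gk <- g[keep]
  nk <- length(ak)
  n_tog <- integer(ng)
  if (nk >= 2) {
    first <- c(TRUE, gk[-1] != gk[-nk] |
                 is.na(ak[-1]) | is.na(ak[-nk]) | ak[-1] != ak[-nk])
    ak <- ak[first]; gk <- gk[first]
    nk <- length(ak)
    if (nk >= 2) {
      x <- ak[-nk]; y <- ak[-1]
      adj <- gk[-nk] == gk[-1] & !is.na(x) & !is.na(y) &
             ((x <= 9 & y == 10) | (x == 10 & y <= 9))
      tg <- rowsum(adj * 1L, gk[-nk])
      n_tog[as.integer(rownames(tg))] <- tg
    }
  }

  # time to first array fixation (cumulative AOI time before it)
  cs <- stats::ave(dur * on_aoi, g, FUN = cumsum)
  prior <- cs - dur * on_aoi
  is10 <- on_aoi & a == 10
  idx10 <- which(is10)
  firsts <- idx10[!duplicated(g[idx10])]
  ttft <- rt
  censored <- rep(TRUE, ng)
  ttft[g[firsts]] <- prior[firsts]
  censored[g[firsts]] <- FALSE

  out$encoding <- row_ev | col_ev
  out$integration <- row_ev & col_ev
  out$n_toggles <- n_tog
  out$toggle_rate <- ifelse(rt > 0, n_tog / rt, NA_real_)
  out$time_to_first_toggle <- ttft
  out$ttft_censored <- censored
  out$prop_matrix_time <- ifelse(tm + ta > 0, tm / (tm + ta), NA_real_)
  out$matrix_time_distribution <-
    ifelse(tm > 0, (tf - (tm - tf)) / tm, NA_real_)
  out$response_time <- rt
  rownames(out) <- NULL
  out
}

#' Aggregate trial indices to participants
#'
#' Binary indices (encoding, integration) become the percentage of retained
#' trials with the event; the remaining indices become per-trial means; the
#' response table contributes percent correct over retained trials.
#'
#' @param trials output of [trial_indices()], restricted to retained trials.
#' @param responses optional data frame \code{participant}, \code{trial},
#'   \code{correct} (logical/0-1), optionally \code{group}.
#' @return Data frame, one row per participant, with \code{pct_encoding},
#'   \code{pct_integration}, \code{n_toggles}, \code{toggle_rate},
#'   \code{time_to_first_toggle}, \code{prop_matrix_time},
#'   \code{matrix_time_distribution}, \code{response_time},
#'   \code{percent_correct} (when responses given), \code{n_trials} and
#'   \code{group} when available.
#' @export
aggregate_participants <- function(trials, responses = NULL) {
  t <- as.data.frame(trials)
  if (!is.null(responses)) {
    t <- merge(t, responses[, intersect(names(responses),
                                        c("participant", "trial",
                                          "correct", "group"))],
               by = c("participant", "trial"), all.x = TRUE)
  }
  sp <- split(t, t$participant)
  rows <- lapply(sp, function(d) {
    out <- data.frame(
      participant = d$participant[1],
      pct_encoding = 100 * mean(d$encoding),
      pct_integration = 100 * mean(d$integration),
      n_toggles = mean(d$n_toggles),
      toggle_rate = mean(d$toggle_rate, na.rm = TRUE),
      time_to_first_toggle = mean(d$time_to_first_toggle, na.rm = TRUE),
      prop_matrix_time = mean(d$prop_matrix_time, na.rm = TRUE),
      matrix_time_distribution = mean(d$matrix_time_distribution,
                                      na.rm = TRUE),
      response_time = mean(d$response_time),
      n_trials = nrow(d)
    )
    if (!is.null(d$correct))
      out$percent_correct <- 100 * mean(d$correct, na.rm = TRUE)
    if (!is.null(d$group)) out$group <- d$group[1]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cronbach's alpha over trials
#'
#' Treats the task's trials, in fixed order, as items: for one index,
#' \eqn{\alpha = k/(k-1) (1 - \sum_i s_i^2 / s_T^2)} with \eqn{s_i^2} the
#' per-trial variances across participants and \eqn{s_T^2} the variance of
#' participant sums. Participants with missing trials are dropped listwise.
#'
#' @param mat numeric matrix, participants in rows, trials (items) in
#'   columns; or a trial-index data frame plus \code{index} naming the column
#'   to reshape by \code{participant} x \code{trial}.
#' @param index column name when \code{mat} is a trial table.
#' @return Alpha coefficient; \code{NA} when the total variance is zero.
#' @export
cronbach_alpha <- function(mat, index = NULL) {
  if (is.data.frame(mat) && !is.null(index)) {
    mat <- tapply(mat[[index]], list(mat$participant, mat$trial),
                  function(x) as.numeric(x)[1])
  }
  mat <- as.matrix(mat) * 1
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  k <- ncol(mat)
  if (k < 2 || nrow(mat) < 2)
    stop("need >= 2 trials and >= 2 participants")
  vt <- stats::var(rowSums(mat))
  if (vt == 0) return(NA_real_)
  k / (k - 1) * (1 - sum(apply(mat, 2, stats::var)) / vt)
}
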