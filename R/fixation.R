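#' Adaptive per-participant velocity threshold
#'
#' Computes a fixation/saccade velocity threshold from a participant's own
#' sample-to-sample velocity distribution: \code{median(v) + 3 * mad(v)},
#' floored at \code{floor_px_s}. Setting the threshold per participant
#' compensates for systematic data-quality differences (e.g. noisier signal
#' in young children) the way adaptive parsers are intended to.
#'
#' @param samples data frame with columns \code{t} (s), \code{x}, \code{y}
#'   (px) and optionally \code{valid} (logical); typically all samples of one
#'   participant, pooled over trials.
#' @param floor_px_s lower bound on the threshold (px/s). With a noiseless
#'   signal the median and MAD are 0; the floor keeps the threshold usable.
#' @return Threshold in px/s.
#' @export
velocity_threshold <- function(samples, floor_px_s = 100) {
  v <- sample_velocities(samples)
  v <- v[is.finite(v)]
  if (!length(v)) return(floor_px_s)
  max(floor_px_s, stats::median(v) + 3 * stats::mad(v))
}

# point-to-point velocities between consecutive valid samples; NA elsewhere
sample_velocities <- function(samples) {
  ok <- sample_validity(samples)
  n <- nrow(samples)
  v <- rep(NA_real_, n)
  if (n < 2) return(v)
  i <- 2:n
  dt <- samples$t[i] - samples$t[i - 1]
  d <- sqrt((samples$x[i] - samples$x[i - 1])^2 +
            (samples$y[i] - samples$y[i - 1])^2)
  v[i] <- ifelse(ok[i] & ok[i - 1] & dt > 0, d / dt, NA_real_)
  v
}

sample_validity <- function(samples) {
  ok <- !is.na(samples$x) & !is.na(samples$y)
  if (!is.null(samples$valid)) ok <- ok & as.logical(samples$valid)
  ok
}

#' Parse raw gaze samples into fixations (velocity-threshold classification)
#'
#' Samples whose point-to-point velocity stays at or below the threshold are
#' grouped into fixation candidates; candidates shorter than
#' \code{min_duration} are discarded, so saccades and sub-threshold jitter
#' never enter downstream time sums. Runs of invalid samples shorter than
#' \code{bridge_gap} inside an otherwise stationary run are bridged (single
#' dropped samples are common at 50 Hz); longer losses break the run.
#'
#' A fixation's duration is the time span of its samples plus one sample
#' period (each sample represents one period of looking), so six stationary
#' samples at 50 Hz yield a 120 ms fixation.
#'
#' @param samples one trial's samples: data frame with \code{t} (s, strictly
#'   increasing), \code{x}, \code{y} (px), optional \code{valid}.
#' @param rate nominal sampling rate (Hz).
#' @param min_duration minimum fixation duration (s); 0.100 by default.
#' @param threshold velocity threshold (px/s); if \code{NULL}, computed from
#'   these samples via [velocity_threshold()]. When parsing many trials, pass
#'   the participant-level threshold explicitly.
#' @param bridge_gap maximum invalid-gap length (s) bridged inside a run.
#' @param floor_px_s passed to [velocity_threshold()] when computing one.
#' @return Data frame of fixations: \code{onset}, \code{duration}, \code{x},
#'   \code{y} (centroid), time-ordered and non-overlapping.
#' @export
detect_fixations <- function(samples, rate = 50, min_duration = 0.1,
                             threshold = NULL, bridge_gap = 0.075,
                             floor_px_s = 100) {
  empty <- data.frame(onset = numeric(0), duration = numeric(0),
                      x = numeric(0), y = numeric(0))
  samples <- as.data.frame(samples)
  if (nrow(samples) && is.unsorted(samples$t, strictly = TRUE))
    stop("sample timestamps must be strictly increasing within a trial")
  ok <- sample_validity(samples)
  if (sum(ok) < 2) {
    warning("fewer than 2 valid samples; no fixations detected")
    return(empty)
  }
  if (is.null(threshold)) threshold <- velocity_threshold(samples, floor_px_s)
  v <- sample_velocities(samples)
  # a sample belongs to a fixation if the velocity into it is sub-threshold;
  # the first valid sample inherits the status of its successor
  fixsamp <- ok & !is.na(v) & v <= threshold
  first_ok <- which(ok)[1]
  nxt <- which(ok)[2]
  fixsamp[first_ok] <- fixsamp[nxt]
  # break runs at invalid gaps longer than bridge_gap
  idx <- which(fixsamp)
  if (!length(idx)) return(empty)
  gap <- c(0, samples$t[idx[-1]] - samples$t[idx[-length(idx)]])
  newrun <- gap > max(bridge_gap, 1.5 / rate)
  run <- cumsum(newrun)
  out <- lapply(split(idx, run), function(ii) {
    dur <- samples$t[ii[length(ii)]] - samples$t[ii[1]] + 1 / rate
    data.frame(onset = samples$t[ii[1]], duration = dur,
               x = mean(samples$x[ii]), y = mean(samples$y[ii]))
  })
  out <- do.call(rbind, out)
  out <- out[out$duration >= min_duration, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only fixations made while the problem was on screen
#'
#' Fixations after the response (spacebar press, when the matrix disappears)
#' are dropped; a fixation straddling the boundary is truncated to it.
#'
#' @param fixes fixation data frame with \code{onset} and \code{duration}.
#' @param response_time boundary (s, same clock as \code{onset}).
#' @return The truncated fixation data frame.
#' @export
truncate_at_response <- function(fixes, response_time) {
  stopifnot(response_time >= 0)
  keep <- fixes$onset < response_time
  fixes <- fixes[keep, , drop = FALSE]
  over <- fixes$onset + fixes$duration > response_time
  fixes$duration[over] <- response_time - fixes$onset[over]
  rownames(fixes) <- NULL
  fixes
}

#' Per-trial data-quality record
#'
#' The valid fraction is summed AOI-labelled fixation time over the full
#' trial time, so saccades, signal loss and off-AOI looking all count as
#' non-valid.
#'
#' @param fixes one trial's fixations with an \code{aoi} column (1--10 or
#'   \code{NA}) and \code{duration}.
#' @param trial_duration full trial time (s), > 0.
#' @return One-row data frame: \code{valid_fraction}, \code{aoi_time},
#'   \code{trial_duration}.
#' @export
compute_qc <- function(fixes, trial_duration) {
  if (!is.numeric(trial_duration) || trial_duration <= 0)
    stop("trial_duration must be > 0")
  aoi_time <- sum(fixes$duration[!is.na(fixes$aoi)])
  data.frame(valid_fraction = min(1, aoi_time / trial_duration),
             aoi_time = aoi_time, trial_duration = trial_duration)
}

#' Flag low-quality trials and empty participants
#'
#' Trials whose valid fraction falls below \code{threshold} are excluded;
#' participants left with zero retained trials are flagged for removal.
#'
#' @param qc data frame with \code{participant}, \code{trial},
#'   \code{valid_fraction}, optionally \code{group}.
#' @param threshold minimum valid fraction to retain a trial (default 0.20).
#' @return List: \code{qc} (input plus \code{excluded}, \code{reason}),
#'   \code{participants_excluded}, and \code{summary} (exclusion counts,
#'   by group when available).
#' @export
exclude_trials_participants <- function(qc, threshold = 0.2) {
  qc <- as.data.frame(qc)
  qc$excluded <- qc$valid_fraction < threshold
  qc$reason <- ifelse(qc$excluded, "low_valid_fraction", "")
  kept <- tapply(!qc$excluded, qc$participant, sum)
  gone <- names(kept)[kept == 0]
  by <- if (!is.null(qc$group)) qc$group else rep("all", nrow(qc))
  summary <- aggregate(list(n_trials = qc$excluded,
                            n_excluded = qc$excluded),
                       by = list(group = by),
                       FUN = length)
  summary$n_excluded <- aggregate(qc$excluded, by = list(group = by),
                                  FUN = sum)$x
  list(qc = qc, participants_excluded = gone, summary = summary,
       threshold = threshold)
}

#' Preprocess a cohort of raw gaze samples into an AOI fixation table
#'
#' Convenience wrapper: computes a velocity threshold per participant over
#' all their samples, parses each trial's samples into fixations, truncates
#' at the response boundary when a response table is supplied, labels
#' fixations with AOIs, and attaches QC records.
#'
#' @param samples data frame: \code{participant}, \code{trial}, \code{t},
#'   \code{x}, \code{y}, optional \code{valid}.
#' @param layout an [aoi_layout()].
#' @param responses optional data frame \code{participant}, \code{trial},
#'   \code{response_time} giving the on-screen boundary per trial.
#' @param qc_threshold passed to [exclude_trials_participants()].
#' @inheritParams detect_fixations
#' @return List: \code{fixations} (participant, trial, onset, duration, x, y,
#'   aoi), \code{qc}, \code{exclusions}, \code{thresholds} (px/s per
#'   participant).
#' @export
preprocess_gaze <- function(samples, layout = default_aoi_layout(),
                            responses = NULL, rate = 50, min_duration = 0.1,
                            qc_threshold = 0.2, bridge_gap = 0.075,
                            floor_px_s = 100) {
  samples <- as.data.frame(samples)
  thr <- vapply(split(samples, samples$participant),
                velocity_threshold, numeric(1), floor_px_s = floor_px_s)
  key <- interaction(samples$participant, samples$trial, drop = TRUE)
  res <- lapply(split(samples, key), function(s) {
    p <- as.character(s$participant[1]); tr <- s$trial[1]
    f <- detect_fixations(s, rate = rate, min_duration = min_duration,
                          threshold = thr[[p]], bridge_gap = bridge_gap)
    tdur <- max(s$t) - min(s$t) + 1 / rate
    if (!is.null(responses)) {
      rt <- responses$response_time[responses$participant == p &
                                    responses$trial == tr]
      if (length(rt) == 1) {
        f <- truncate_at_response(f, rt)
        tdur <- min(tdur, rt)
      }
    }
    f$aoi <- assign_aoi(f$x, f$y, layout)
    qc <- compute_qc(f, tdur)
    list(fix = if (nrow(f)) cbind(participant = p, trial = tr, f),
         qc = cbind(participant = p, trial = tr, qc))
  })
  fixations <- do.call(rbind, lapply(res, `[[`, "fix"))
  qc <- do.call(rbind, lapply(res, `[[`, "qc"))
  rownames(fixations) <- rownames(qc) <- NULL
  excl <- exclude_trials_participants(qc, threshold = qc_threshold)
  list(fixations = fixations, qc = excl$qc, exclusions = excl,
       thresholds = thr)
}
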