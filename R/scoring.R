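#' Percent correct per participant
#'
#' Accuracy is the percentage of correct responses over the trials that
#' survive preprocessing; participants with zero retained trials are dropped
#' with a message.
#'
#' @param responses data frame with \code{participant} and \code{correct}
#'   (logical/0-1), one row per retained trial.
#' @return Data frame: \code{participant}, \code{percent_correct},
#'   \code{n_trials}.
#' @export
percent_correct <- function(responses) {
  r <- as.data.frame(responses)
  r <- r[!is.na(r$correct), ]
  if (!nrow(r)) stop("no retained trials")
  agg <- aggregate(list(percent_correct = as.numeric(r$correct)),
                   by = list(participant = r$participant), FUN = mean)
  agg$percent_correct <- 100 * agg$percent_correct
  agg$n_trials <- aggregate(r$correct, by = list(r$participant),
                            FUN = length)$x
  agg
}

#' Relational score
#'
#' Credits each response with the number of correct relations its chosen
#' option embodies (a 2-of-3-relations response scores 2), then sums over a
#' participant's retained trials. Summation rather than averaging keeps the
#' score on the range produced by 24 trials with partial credit; per-relation
#' fractional credit can be injected through the option metadata.
#'
#' @param responses data frame: \code{participant}, \code{item},
#'   \code{chosen} (option index).
#' @param options option metadata: \code{item}, \code{option},
#'   \code{n_relations_matched}.
#' @return List with \code{trials} (per-trial scores) and
#'   \code{participants} (summed \code{relational_score}).
#' @export
relational_score <- function(responses, options) {
  r <- merge(as.data.frame(responses), as.data.frame(options),
             by.x = c("item", "chosen"), by.y = c("item", "option"),
             all.x = TRUE)
  miss <- is.na(r$n_relations_matched)
  if (any(miss)) {
    warning(sum(miss), " response(s) without option metadata skipped")
    r <- r[!miss, ]
  }
  if (!nrow(r))
    return(list(trials = r[, c("participant", "item", "chosen")],
                participants = data.frame(participant = character(0),
                                          relational_score = numeric(0))))
  r$relational_score <- r$n_relations_matched
  part <- aggregate(list(relational_score = r$relational_score),
                    by = list(participant = r$participant), FUN = sum)
  list(trials = r[, c("participant", "item", "chosen", "relational_score")],
       participants = part)
}

#' Classify a response's error type
#'
#' Single-label classification with fixed precedence: a correct response is
#' \code{correct}; otherwise \code{duplicate} (the chosen option duplicates
#' a matrix item), else \code{novel_feature} (contains a feature absent from
#' the matrix), else \code{partial} (matches at least one required
#' relation), else \code{other}. The precedence order is configurable.
#'
#' @param correct logical vector.
#' @param is_duplicate,has_novel_feature logical vectors.
#' @param n_relations_matched integer vector.
#' @param precedence order in which the three error flags are checked.
#' @return Factor with levels correct/duplicate/novel_feature/partial/other.
#' @export
classify_error <- function(correct, is_duplicate, has_novel_feature,
                           n_relations_matched,
                           precedence = c("duplicate", "novel_feature",
                                          "partial")) {
  n <- length(correct)
  out <- rep("other", n)
  flag <- list(duplicate = as.logical(is_duplicate),
               novel_feature = as.logical(has_novel_feature),
               partial = n_relations_matched >= 1)
  for (p in rev(precedence)) out[flag[[p]]] <- p
  out[as.logical(correct)] <- "correct"
  factor(out, levels = c("correct", "duplicate", "novel_feature",
                         "partial", "other"))
}

#' Group-wise item difficulty
#'
#' Difficulty of an item for a group is 100 minus the group's mean
#' percentage correct on that item; higher numbers mean harder problems.
#'
#' @param responses data frame: \code{item}, \code{correct}, and a grouping
#'   column named by \code{group_col} (omit for a single group).
#' @param group_col name of the grouping column, or \code{NULL}.
#' @return Data frame: \code{item}, \code{group}, \code{percent_correct},
#'   \code{difficulty}, \code{n}.
#' @export
item_difficulty <- function(responses, group_col = "group") {
  r <- as.data.frame(responses)
  grp <- if (!is.null(group_col) && group_col %in% names(r))
    r[[group_col]] else rep("all", nrow(r))
  agg <- aggregate(list(percent_correct = as.numeric(r$correct)),
                   by = list(item = r$item, group = grp), FUN = mean)
  agg$percent_correct <- 100 * agg$percent_correct
  agg$difficulty <- 100 - agg$percent_correct
  agg$n <- aggregate(r$correct, by = list(r$item, grp), FUN = length)$x
  agg[order(agg$group, agg$item), ]
}

#' Chance-level accuracy
#'
#' Expected percent correct of a uniform random responder:
#' \code{100 / n_options} (12.5\% for the standard 8-option array). Used to
#' flag below-chance participants for sensitivity re-analysis.
#'
#' @param n_options number of answer options, >= 2.
#' @return Percent.
#' @export
chance_level <- function(n_options) {
  if (!is.numeric(n_options) || any(n_options < 2))
    stop("n_options must be >= 2")
  100 / n_options
}
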