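#' Sex-specific binge drinking threshold
#'
#' Binge drinking is defined as consuming at least 4 standard drinks for women
#' or at least 5 for men on a single occasion. The threshold anchors both binge
#' classification and the floor of the adaptive drinking-limit goal policy
#' (the largest non-binge amount, `threshold - 1`).
#'
#' @param sex Character vector, each element `"female"` or `"male"`.
#' @return Integer vector of binge thresholds (4 for female, 5 for male).
#' @examples
#' binge_threshold(c("female", "male"))
#' @export
binge_threshold <- function(sex) {
  if (!all(sex %in% c("female", "male"))) {
    rlang::abort("`sex` must be \"female\" or \"male\".")
  }
  ifelse(sex == "female", 4L, 5L)
}

#' Classify a drink count as a binge episode
#'
#' @param drinks Non-negative integer vector of drinks consumed on one occasion.
#' @param sex Character vector (`"female"`/`"male"`), recycled against `drinks`.
#' @return Logical vector: `TRUE` when `drinks >= binge_threshold(sex)`.
#' @examples
#' binge_classify(4, "female") # TRUE
#' binge_classify(4, "male")   # FALSE
#' @export
binge_classify <- function(drinks, sex) {
  if (any(drinks < 0, na.rm = TRUE)) {
    rlang::abort("`drinks` must be non-negative.")
  }
  drinks >= binge_threshold(sex)
}

#' Running average of the prior two weekend maxima
#'
#' The adaptive goal policy bases each week's prompted drinking limit on the
#' running average of the largest number of drinks the participant reported on
#' any occasion over the prior two weekends. Only responded weekends count;
#' the look-back extends past two calendar weeks when intermediate weekends
#' are missing. With a single responded weekend its value is used alone; with
#' none the average is undefined (`NA`), signalling that no goal can be
#' prompted that week.
#'
#' @param history Data frame of weekend records with columns `week_index`
#'   (run-in weeks -2, -1; intervention weeks 1, 2, ...), `max_drinks`
#'   (integer, `NA` when unanswered) and `responded` (logical).
#' @param week Intervention week (integer >= 1) the goal is being set for.
#' @return A single numeric value, or `NA_real_` when no responded weekend
#'   precedes `week`.
#' @examples
#' h <- tibble::tibble(
#'   week_index = c(-2, -1), max_drinks = c(20L, 10L), responded = TRUE
#' )
#' running_average(h, week = 1) # 15
#' @export
running_average <- function(history, week) {
  stopifnot(is.data.frame(history), week >= 1)
  h <- history[history$responded & history$week_index < week, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(NA_real_)
  }
  h <- h[order(h$week_index, decreasing = TRUE), , drop = FALSE]
  mean(h$max_drinks[seq_len(min(2L, nrow(h)))])
}

#' Adaptive step-down drinking-limit goal
#'
#' Maps a running average of weekend maxima to the drinking-limit goal the
#' participant is prompted to commit to, following behavioural-shaping
#' principles (small successive approximations toward a non-binge limit):
#'
#' * average above 10 drinks: the limit is capped at 10 (`basis = "cap"`);
#' * average at most 10 but above the binge threshold: the limit steps down to
#'   `floor(average) - 1` (`basis = "step_down"`);
#' * otherwise the limit rests at the largest non-binge amount,
#'   `binge_threshold - 1` (`basis = "floor"`).
#'
#' Limits are always integers in `[binge_threshold - 1, 10]`. `above_binge`
#' flags prompts whose limit still sits at or above the binge threshold.
#'
#' @param avg Numeric vector of running averages (non-negative, non-missing).
#' @param sex Character vector (`"female"`/`"male"`), recycled against `avg`.
#' @return A tibble with one row per input: `limit` (integer drinks), `basis`
#'   (`"cap"`, `"step_down"` or `"floor"`) and `above_binge` (logical).
#' @examples
#' goal_limit(c(12, 8, 4), "male")
#' @export
goal_limit <- function(avg, sex) {
  if (any(is.na(avg))) {
    rlang::abort("`avg` must not contain missing values; an undefined running average means no goal is prompted.")
  }
  if (any(avg < 0)) {
    rlang::abort("`avg` must be non-negative.")
  }
  n <- max(length(avg), length(sex))
  avg <- rep_len(avg, n)
  thr <- rep_len(binge_threshold(rep_len(sex, n)), n)
  basis <- dplyr::case_when(
    avg > 10 ~ "cap",
    avg > thr & floor(avg) - 1 >= thr - 1 ~ "step_down",
    .default = "floor"
  )
  limit <- dplyr::case_when(
    basis == "cap" ~ 10L,
    basis == "step_down" ~ as.integer(floor(avg)) - 1L,
    .default = thr - 1L
  )
  tibble::tibble(limit = limit, basis = basis, above_binge = limit >= thr)
}

# scalar fast path used by the engine's inner loop
.goal_limit1 <- function(avg, thr) {
  if (avg > 10) {
    list(limit = 10L, basis = "cap", above_binge = TRUE)
  } else if (avg > thr && floor(avg) - 1 >= thr - 1) {
    limit <- as.integer(floor(avg)) - 1L
    list(limit = limit, basis = "step_down", above_binge = limit >= thr)
  } else {
    list(limit = thr - 1L, basis = "floor", above_binge = FALSE)
  }
}

#' Was a committed drinking-limit goal met?
#'
#' A goal is met when the reported weekend maximum does not exceed the
#' committed limit (abstinence always meets any goal).
#'
#' @param limit Integer vector of committed drinking limits.
#' @param reported_max Integer vector of reported weekend maximum drinks.
#' @return Character vector, `"met"` or `"not_met"`.
#' @seealso [goal_met()] for the logical 0/1 coding.
#' @examples
#' evaluate_goal(7, c(0, 7, 8))
#' @export
evaluate_goal <- function(limit, reported_max) {
  ifelse(goal_met(limit, reported_max), "met", "not_met")
}

#' @rdname evaluate_goal
#' @export
goal_met <- function(limit, reported_max) {
  if (any(limit < 0) || any(reported_max < 0)) {
    rlang::abort("`limit` and `reported_max` must be non-negative.")
  }
  reported_max <= limit
}

#' Build this week's goal prompt from a participant's weekend history
#'
#' Convenience wrapper chaining [running_average()] and [goal_limit()]. The
#' displayed number in the commitment message ("drink less than X drinks") is
#' `limit + 1`, so the inclusive stored limit and the exclusive wording agree.
#'
#' @inheritParams running_average
#' @param sex `"female"` or `"male"`.
#' @return A tibble with zero rows when the running average is undefined,
#'   otherwise one row: `week_index`, `limit`, `basis`, `above_binge`,
#'   `displayed` (`limit + 1`).
#' @export
prompt_goal <- function(history, week, sex) {
  avg <- running_average(history, week)
  if (is.na(avg)) {
    return(tibble::tibble(
      week_index = integer(), limit = integer(), basis = character(),
      above_binge = logical(), displayed = integer()
    ))
  }
  g <- goal_limit(avg, sex)
  tibble::tibble(
    week_index = as.integer(week), limit = g$limit, basis = g$basis,
    above_binge = g$above_binge, displayed = g$limit + 1L
  )
}
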