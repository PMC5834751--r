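# Analysis battery: EMA compliance, goal metrics, association tests, and
# repeated-measures Poisson trend models.

.prompt_templates <- c("plan_prompt", "goal_prompt", "confidence_prompt", "max_prompt")

.add_log_groups <- function(log) {
  log |>
    dplyr::mutate(
      block = dplyr::if_else(.data$week_index < 0, "run_in",
                             paste0("block", ceiling(.data$week_index / 4))),
      slot_type = dplyr::if_else(.data$template_id == "confidence_prompt",
                                 "fri_sat", "thu_sun")
    )
}

#' EMA response-rate table
#'
#' Aggregates prompts issued and in-window responses over an event log.
#' Prompts are the four assessment templates (drinking plan, goal commitment,
#' confidence, weekend maximum); invitations and one-way messages are not
#' compliance-bearing. Rates are responses/prompts; groups with no prompts do
#' not appear (an absent cell is undefined, never zero). Rows with a missing
#' template or type are skipped with a message.
#'
#' @param log Event-log tibble.
#' @param by Grouping columns, any of `"block"`, `"slot_type"`,
#'   `"week_index"`, `"day"`, `"template_id"`, `"participant_id"`. Default
#'   groups by 4-week block and slot type (Thursday/Sunday assessments vs
#'   Friday/Saturday confidence queries).
#' @return A `compliance_table` tibble: grouping columns plus `prompts`,
#'   `responses`, `rate`.
#' @export
response_rates <- function(log, by = c("block", "slot_type")) {
  bad <- is.na(log$template_id) | is.na(log$type)
  if (any(bad)) {
    rlang::inform(sprintf("Skipping %d malformed log rows.", sum(bad)))
    log <- log[!bad, , drop = FALSE]
  }
  log <- .add_log_groups(dplyr::filter(log, .data$template_id %in% .prompt_templates))
  prompts <- log |>
    dplyr::filter(.data$type == "message") |>
    dplyr::count(dplyr::pick(dplyr::all_of(by)), name = "prompts")
  answers <- log |>
    dplyr::filter(.data$type == "response", .data$in_window) |>
    dplyr::count(dplyr::pick(dplyr::all_of(by)), name = "responses")
  out <- prompts |>
    dplyr::left_join(answers, by = by) |>
    tidyr::replace_na(list(responses = 0L)) |>
    dplyr::mutate(rate = .data$responses / .data$prompts)
  class(out) <- c("compliance_table", class(out))
  out
}

# committed-and-evaluated weekends: one row per (participant, week) with a
# committed goal, joined to the Sunday maximum report and the weekend's
# lowest reported confidence
.goal_weekends <- function(log) {
  offers <- log |>
    dplyr::filter(.data$type == "message", .data$template_id == "goal_prompt") |>
    dplyr::select("participant_id", "week_index", "limit", "basis", "above_binge",
                  offer_id = "event_id")
  replies <- log |>
    dplyr::filter(.data$type == "response", .data$template_id == "goal_prompt") |>
    dplyr::select(offer_id = "in_reply_to", commit_value = "value")
  maxima <- log |>
    dplyr::filter(.data$type == "response", .data$template_id == "max_prompt") |>
    dplyr::mutate(reported_max = suppressWarnings(as.integer(.data$value))) |>
    dplyr::select("participant_id", "week_index", "reported_max")
  conf <- log |>
    dplyr::filter(.data$type == "response", .data$template_id == "confidence_prompt") |>
    dplyr::mutate(conf = suppressWarnings(as.numeric(.data$value))) |>
    dplyr::filter(!is.na(.data$conf))
  conf <- if (nrow(conf) == 0L) {
    tibble::tibble(participant_id = character(), week_index = integer(),
                   min_confidence = numeric())
  } else {
    dplyr::summarise(conf, min_confidence = min(.data$conf),
                     .by = c("participant_id", "week_index"))
  }
  offers |>
    dplyr::left_join(replies, by = "offer_id") |>
    dplyr::mutate(committed = !is.na(.data$commit_value) & .is_yes(.data$commit_value)) |>
    dplyr::left_join(maxima, by = c("participant_id", "week_index")) |>
    dplyr::left_join(conf, by = c("participant_id", "week_index")) |>
    dplyr::mutate(
      evaluated = .data$committed & !is.na(.data$reported_max),
      met = dplyr::if_else(.data$evaluated, .data$reported_max <= .data$limit, NA)
    )
}

#' Goal commitment, tailoring and success metrics
#'
#' Summarises the goal-support stream of an event log: the proportion of
#' answered goal prompts that were committed to; the share of goal prompts
#' above the binge threshold by week; and the goal-success proportion over
#' committed-and-evaluated weekends, overall and stratified by the weekend's
#' lowest reported confidence (below 4 vs 4-5) and by goal level (above the
#' binge threshold vs at it). Every proportion carries its numerator and
#' denominator; undefined proportions (zero denominator) are `NA`.
#'
#' @param log Event-log tibble.
#' @return An object of class `goal_metrics`: list of tibbles `overall`,
#'   `above_binge_by_week`, `success_by_confidence`, `success_by_goal_level`
#'   and the per-weekend table `weekends`.
#' @export
goal_summary <- function(log) {
  gw <- .goal_weekends(log)
  prop_row <- function(metric, num, den) {
    tibble::tibble(
      metric = metric, numerator = num, denominator = den,
      proportion = ifelse(den > 0, num / den, NA_real_)
    )
  }
  answered <- gw[!is.na(gw$commit_value), , drop = FALSE]
  ev <- gw[gw$evaluated, , drop = FALSE]
  overall <- dplyr::bind_rows(
    prop_row("commitment", sum(answered$committed), nrow(answered)),
    prop_row("goal_success", sum(ev$met), nrow(ev)),
    prop_row("above_binge_prompts", sum(gw$above_binge), nrow(gw))
  )
  above_week <- gw |>
    dplyr::summarise(
      prompts = dplyr::n(), above_binge = sum(.data$above_binge),
      .by = "week_index"
    ) |>
    dplyr::mutate(proportion = .data$above_binge / .data$prompts) |>
    dplyr::arrange(.data$week_index)
  by_conf <- ev |>
    dplyr::filter(!is.na(.data$min_confidence)) |>
    dplyr::mutate(confidence = dplyr::if_else(.data$min_confidence < 4, "low", "high")) |>
    dplyr::summarise(
      met = sum(.data$met), weekends = dplyr::n(), .by = "confidence"
    ) |>
    dplyr::mutate(proportion = .data$met / .data$weekends) |>
    dplyr::arrange(.data$confidence)
  by_level <- ev |>
    dplyr::mutate(goal_level = dplyr::if_else(.data$above_binge, "above_binge", "at_threshold")) |>
    dplyr::summarise(
      met = sum(.data$met), weekends = dplyr::n(), .by = "goal_level"
    ) |>
    dplyr::mutate(proportion = .data$met / .data$weekends) |>
    dplyr::arrange(.data$goal_level)
  structure(
    list(
      overall = overall, above_binge_by_week = above_week,
      success_by_confidence = by_conf, success_by_goal_level = by_level,
      weekends = gw
    ),
    class = "goal_metrics"
  )
}

#' @export
print.goal_metrics <- function(x, ...) {
  cat("Goal metrics\n")
  print(x$overall)
  cat("\nGoal success by weekend-lowest confidence (<4 vs 4-5):\n")
  print(x$success_by_confidence)
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square without continuity correction (df = 1), the default
#' for the univariate goal-success associations; Yates' correction is
#' available as an option. Tables with a zero margin are undefined and return
#' `NA` with a warning.
#'
#' @param tab A 2x2 matrix of non-negative counts, or the four counts
#'   `a, b, c, d` given row-wise via `...`.
#' @param correct Apply Yates' continuity correction (default `FALSE`).
#' @param ... Counts `b`, `c`, `d` when `tab` is scalar `a`.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' crosstab_chi2(matrix(c(32, 10, 56, 1), 2, byrow = TRUE))
#' @export
crosstab_chi2 <- function(tab, ..., correct = FALSE) {
  if (!is.matrix(tab)) {
    tab <- matrix(c(tab, ...), 2, 2, byrow = TRUE)
  }
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0) || any(tab != floor(tab))) {
    rlang::abort("Counts must be non-negative integers.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    rlang::warn("Chi-square undefined: a table margin is zero.")
    return(tibble::tibble(statistic = NA_real_, df = 1L, p_value = NA_real_))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  tibble::tibble(
    statistic = unname(ct$statistic), df = 1L, p_value = ct$p.value
  )
}

# exact distribution of W+ over sign assignments, supporting tied (half-)
# ranks: ranks are doubled to integers and the distribution built by
# convolution, equivalent to enumerating all 2^n sign vectors
.signrank_exact_p <- function(ranks2, w2) {
  probs <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), probs)
    probs <- c(probs, rep(0, r)) + shifted
  }
  probs <- probs / 2^length(ranks2)
  lower <- sum(probs[seq_len(w2 + 1L)])
  upper <- sum(probs[(w2 + 1L):length(probs)])
  min(1, 2 * min(lower, upper))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Matched-pairs signed-rank test as used for baseline versus follow-up
#' comparisons of weekend maxima and alcohol consequences. Zero differences
#' are dropped; tied absolute differences receive average ranks. For up to
#' `exact_max` non-zero pairs the two-sided p-value is exact (full
#' enumeration of sign assignments, computed by convolution, valid under
#' ties); beyond that a tie-corrected normal approximation without continuity
#' correction is used. If all differences are zero the test is undefined and
#' returns `NA` with a warning.
#'
#' @param pre,post Equal-length paired numeric vectors.
#' @param exact_max Largest number of non-zero pairs for which the exact
#'   p-value is computed (default 25).
#' @return One-row tibble: `statistic` (W+, the positive-rank sum of the
#'   `pre - post` differences), `n_nonzero`, `p_value`, `method`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3), c(2, 4, 6))
#' @export
wilcoxon_signed_rank <- function(pre, post, exact_max = 25L) {
  stopifnot(length(pre) == length(post))
  d <- pre - post
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    rlang::warn("Signed-rank test undefined: all paired differences are zero.")
    return(tibble::tibble(statistic = NA_real_, n_nonzero = 0L,
                          p_value = NA_real_, method = "undefined"))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- .signrank_exact_p(as.integer(round(2 * r)), as.integer(round(2 * w_plus)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  tibble::tibble(statistic = w_plus, n_nonzero = n, p_value = p, method = method)
}

#' Two-sample test of proportions
#'
#' Pooled-variance z test for the difference of two independent proportions,
#' as used for the prevalence of any binge drinking episode in a typical
#' week at baseline versus follow-up.
#'
#' @param x1,n1,x2,n2 Successes and trials in each sample.
#' @return One-row tibble: `estimate1`, `estimate2`, `z`, `p_value`.
#' @examples
#' two_sample_proportion_test(14, 32, 9, 32)
#' @export
two_sample_proportion_test <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) rlang::abort("Sample sizes must be positive.")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    rlang::abort("Successes must lie in 0..n.")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  tibble::tibble(
    estimate1 = p1, estimate2 = p2, z = z,
    p_value = 2 * stats::pnorm(-abs(z))
  )
}

#' Repeated-measures Poisson trend in weekend maxima
#'
#' Fits, per enrollment-length stratum, a Poisson log-link panel model of the
#' weekend maximum drink count on intervention week with a participant-level
#' random intercept: `max_drinks ~ (week - 1) + (1 | participant)`. The
#' intercept is therefore the week-1 log-mean and the slope the weekly log
#' rate of change. Estimation uses Laplace approximation with the bobyqa
#' optimizer and fixed settings, so repeated fits of identical data are
#' identical. An AR(1) within-participant residual structure is available via
#' `method = "ar1"` (fitted with glmmTMB).
#'
#' @param records Data frame with columns `participant_id`, `week_index`,
#'   `max_drinks` (rows with missing maxima are dropped) and, if `strata` is
#'   given, that column.
#' @param strata Name of the stratum column, or `NULL` to fit a single model
#'   to all records.
#' @param method `"random_intercept"` (default) or `"ar1"`.
#' @param conf_level Confidence level for Wald intervals (default 0.95).
#' @param min_participants Strata with fewer participants are skipped with a
#'   warning (default 3).
#' @return An object of class `weekend_trend`; see [tidy.weekend_trend()].
#' @export
fit_weekend_trend <- function(records, strata = NULL,
                              method = c("random_intercept", "ar1"),
                              conf_level = 0.95, min_participants = 3L) {
  method <- match.arg(method)
  records <- tibble::as_tibble(records) |>
    dplyr::filter(!is.na(.data$max_drinks), .data$week_index >= 1) |>
    dplyr::mutate(week_c = .data$week_index - 1)
  groups <- if (is.null(strata)) {
    list(all = records)
  } else {
    split(records, records[[strata]])
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  fits <- list()
  rows <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    npart <- dplyr::n_distinct(d$participant_id)
    if (npart < min_participants) {
      rlang::warn(sprintf(
        "Stratum '%s' skipped: %d participant(s) < %d required.", g, npart,
        min_participants
      ))
      next
    }
    if (method == "random_intercept") {
      fit <- lme4::glmer(
        max_drinks ~ week_c + (1 | participant_id),
        data = d, family = stats::poisson(),
        control = lme4::glmerControl(optimizer = "bobyqa")
      )
      b <- lme4::fixef(fit)
      se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    } else {
      if (!requireNamespace("glmmTMB", quietly = TRUE)) {
        rlang::abort("method = \"ar1\" requires the glmmTMB package.")
      }
      d$week_f <- factor(d$week_index)
      fit <- glmmTMB::glmmTMB(
        max_drinks ~ week_c + glmmTMB::ar1(week_f + 0 | participant_id),
        data = d, family = stats::poisson()
      )
      b <- glmmTMB::fixef(fit)$cond
      se <- sqrt(diag(as.matrix(stats::vcov(fit)$cond)))
    }
    fits[[g]] <- fit
    rows[[g]] <- tibble::tibble(
      stratum = g, term = c("intercept", "slope"),
      estimate = unname(b), std.error = unname(se),
      conf.low = unname(b - z * se), conf.high = unname(b + z * se),
      p.value = 2 * stats::pnorm(-abs(unname(b) / unname(se))),
      n_participants = npart, n_obs = nrow(d)
    )
  }
  structure(
    list(
      table = dplyr::bind_rows(rows), fits = fits, method = method,
      conf_level = conf_level
    ),
    class = "weekend_trend"
  )
}

#' @export
print.weekend_trend <- function(x, ...) {
  cat(sprintf("Poisson weekend-maxima trend (%s)\n", x$method))
  print(x$table)
  invisible(x)
}

#' Tidy a weekend-trend fit
#'
#' @param x A `weekend_trend` object from [fit_weekend_trend()].
#' @param ... Unused.
#' @return A tibble with one row per stratum and term (`intercept` at week 1
#'   on the log scale, `slope` per week): `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `p.value`, `n_participants`, `n_obs`.
#' @exportS3Method generics::tidy
tidy.weekend_trend <- function(x, ...) {
  x$table
}

#' Model-level summary of a weekend-trend fit
#'
#' @param x A `weekend_trend` object.
#' @param ... Unused.
#' @return A tibble with one row per stratum: `n_participants`, `n_obs`,
#'   `logLik`, `AIC`.
#' @exportS3Method generics::glance
glance.weekend_trend <- function(x, ...) {
  purrr::imap(x$fits, function(fit, g) {
    tt <- x$table[x$table$stratum == g, ]
    tibble::tibble(
      stratum = g, n_participants = tt$n_participants[1], n_obs = tt$n_obs[1],
      logLik = as.numeric(stats::logLik(fit)), AIC = stats::AIC(fit)
    )
  }) |>
    dplyr::bind_rows()
}

#' Baseline versus follow-up outcome comparison
#'
#' Produces the pre/post outcome table for a cohort: median (IQR) of the
#' maximum weekend drinks and of the consequence count with Wilcoxon
#' signed-rank p-values, and n (%) with any binge episode in a typical week
#' with a pooled two-sample proportion test, per exposure group and pooled
#' over exposed groups.
#'
#' @param baseline,followup Data frames with columns `participant_id`,
#'   `max_weekend_drinks`, `any_binge` (0/1), `consequences`; only
#'   participants present in both are compared.
#' @param groups Optional data frame `participant_id`, `group` assigning
#'   exposure strata; pooled rows are labelled `"any"`.
#' @return A tibble: `outcome`, `group`, `n`, `baseline`, `followup`
#'   (formatted summaries), `p_value`.
#' @export
compare_prepost <- function(baseline, followup, groups = NULL) {
  merged <- dplyr::inner_join(
    tibble::as_tibble(baseline), tibble::as_tibble(followup),
    by = "participant_id", suffix = c("_pre", "_post")
  )
  if (is.null(groups)) {
    merged$group <- "any"
  } else {
    merged <- dplyr::inner_join(merged, groups, by = "participant_id")
  }
  grp_levels <- unique(c(merged$group, if (!is.null(groups)) "any"))
  med_iqr <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 2)
    sprintf("%g (%g-%g)", q[2], q[1], q[3])
  }
  one_group <- function(d, g) {
    n <- nrow(d)
    dplyr::bind_rows(
      tibble::tibble(
        outcome = "max_weekend_drinks", group = g, n = n,
        baseline = med_iqr(d$max_weekend_drinks_pre),
        followup = med_iqr(d$max_weekend_drinks_post),
        p_value = wilcoxon_signed_rank(d$max_weekend_drinks_pre,
                                       d$max_weekend_drinks_post)$p_value
      ),
      tibble::tibble(
        outcome = "any_binge", group = g, n = n,
        baseline = sprintf("%d (%.0f%%)", sum(d$any_binge_pre),
                           100 * mean(d$any_binge_pre)),
        followup = sprintf("%d (%.0f%%)", sum(d$any_binge_post),
                           100 * mean(d$any_binge_post)),
        p_value = two_sample_proportion_test(
          sum(d$any_binge_pre), n, sum(d$any_binge_post), n
        )$p_value
      ),
      tibble::tibble(
        outcome = "consequences", group = g, n = n,
        baseline = med_iqr(d$consequences_pre),
        followup = med_iqr(d$consequences_post),
        p_value = wilcoxon_signed_rank(d$consequences_pre,
                                       d$consequences_post)$p_value
      )
    )
  }
  out <- purrr::map(grp_levels, function(g) {
    d <- if (g == "any") merged else merged[merged$group == g, , drop = FALSE]
    one_group(d, g)
  })
  dplyr::bind_rows(out) |> dplyr::arrange(.data$outcome)
}

#' Exact binomial acceptance region
#'
#' Central acceptance region of counts for a Binomial(n, p) draw at the given
#' level, used for calibration checks of simulated proportions against their
#' generating values.
#'
#' @param n Number of trials.
#' @param p Generating probability.
#' @param level Coverage level (default 0.99).
#' @return Integer vector `c(lower, upper)` of counts.
#' @export
binom_accept_region <- function(n, p, level = 0.99) {
  alpha <- (1 - level) / 2
  c(stats::qbinom(alpha, n, p), stats::qbinom(1 - alpha, n, p))
}
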