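# Seeded generative model of participant behavior. All random draws for a
# participant are pregenerated in a fixed order from a participant-specific
# substream, then consumed deterministically while the engine runs; cohort
# size changes therefore never reshuffle existing participants, and the
# emitted event log is byte-identical across runs with the same parameters.

#' Simulation parameters for a synthetic intervention cohort
#'
#' The defaults describe a cohort like the one the analysis battery targets:
#' emergency-department-recruited young adults entering a 2-week
#' assessment-only run-in followed by up to six voluntary 4-week intervention
#' blocks. Weekly latent desired consumption for participant *i* in
#' enrollment-length stratum *g* is
#' `desired ~ Poisson(exp(b0_i + slope_g * (week - 1)))` with
#' `b0_i ~ Normal(intercept_g, intercept_sd_g)`; run-in weekends use the
#' week-1 level (the intervention effect has not started). A committed,
#' adherent weekend reports `min(desired, limit)`; otherwise `desired`.
#'
#' @param n_participants Number of participants entering the run-in (default
#'   50).
#' @param p_female Probability a participant is female (default 0.56).
#' @param strata Labels of the enrollment-length strata.
#' @param stratum_weights Mixing weights over strata (sum to 1); defaults to
#'   the 6/8/9/9 split over 4, 8, 12 and more-than-12 week strata.
#' @param intercepts,slopes Per-stratum week-1 log-mean maxima and weekly
#'   log-rate-of-change; defaults (2.82, -0.34), (1.6, -0.17), (1.99, -0.13),
#'   (0.61, -0.03).
#' @param intercept_sd Per-stratum SD of the participant random intercept
#'   (default 0.5 each).
#' @param plan_prob Probability of planning to drink, per intervention week
#'   (weeks beyond the vector reuse the last value; run-in weekends use the
#'   first). Default declines 0.78 to 0.46 over weeks 1-4.
#' @param commit_prob Probability of committing to a prompted goal (default
#'   0.96).
#' @param conf_high_prob Probability a weekend's latent confidence is high
#'   (reported 4-5 rather than 1-3); default 0.6.
#' @param adherence_high,adherence_low Probability of adhering to a committed
#'   limit given high/low weekend confidence (defaults 0.98 / 0.76).
#' @param resp_thu_sun,resp_fri_sat Response probabilities for the
#'   Thursday/Sunday assessments and the Friday/Saturday confidence queries
#'   (defaults 0.82 / 0.58).
#' @param p_low_engager Share of participants with persistently low response
#'   propensity (default 0.24), emulating run-in failures.
#' @param low_engager_resp Response probability (all slots) for low engagers
#'   (default 0.2).
#' @param enroll_prob Probability of texting "Go" at the enrollment
#'   invitation when run-in eligible (default 1).
#' @param reenroll_probs Probability of opting in at the end of blocks 1..6;
#'   defaults to the observed continuation fractions 29/38, 19/29, 9/19, 6/9,
#'   2/6, 1/2.
#' @param max_blocks Maximum number of 4-week blocks (default 6).
#' @param seed Integer RNG seed.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_participants = 50L,
                       p_female = 0.56,
                       strata = c("4wk", "8wk", "12wk", ">12wk"),
                       stratum_weights = c(6, 8, 9, 9) / 32,
                       intercepts = c(2.82, 1.6, 1.99, 0.61),
                       slopes = c(-0.34, -0.17, -0.13, -0.03),
                       intercept_sd = rep(0.5, 4),
                       plan_prob = c(0.78, 0.67, 0.57, 0.46),
                       commit_prob = 0.96,
                       conf_high_prob = 0.6,
                       adherence_high = 0.98,
                       adherence_low = 0.76,
                       resp_thu_sun = 0.82,
                       resp_fri_sat = 0.58,
                       p_low_engager = 0.24,
                       low_engager_resp = 0.2,
                       enroll_prob = 1,
                       reenroll_probs = c(29 / 38, 19 / 29, 9 / 19, 6 / 9, 2 / 6, 1 / 2),
                       max_blocks = 6L,
                       seed = 1L) {
  p <- structure(
    list(
      n_participants = as.integer(n_participants), p_female = p_female,
      strata = strata, stratum_weights = stratum_weights,
      intercepts = intercepts, slopes = slopes,
      intercept_sd = rep_len(intercept_sd, length(strata)),
      plan_prob = plan_prob, commit_prob = commit_prob,
      conf_high_prob = conf_high_prob, adherence_high = adherence_high,
      adherence_low = adherence_low, resp_thu_sun = resp_thu_sun,
      resp_fri_sat = resp_fri_sat, p_low_engager = p_low_engager,
      low_engager_resp = low_engager_resp, enroll_prob = enroll_prob,
      reenroll_probs = rep_len(reenroll_probs, max_blocks),
      max_blocks = as.integer(max_blocks), seed = as.integer(seed)
    ),
    class = "sim_params"
  )
  validate_sim_params(p)
}

#' @rdname sim_params
#' @param params A `sim_params` list to validate.
#' @export
validate_sim_params <- function(params) {
  probs <- c(
    params$p_female, params$plan_prob, params$commit_prob,
    params$conf_high_prob, params$adherence_high, params$adherence_low,
    params$resp_thu_sun, params$resp_fri_sat, params$p_low_engager,
    params$low_engager_resp, params$enroll_prob, params$reenroll_probs,
    params$stratum_weights
  )
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    rlang::abort("All simulation probabilities must lie in [0, 1].")
  }
  if (abs(sum(params$stratum_weights) - 1) > 1e-8) {
    rlang::abort("`stratum_weights` must sum to 1.")
  }
  if (any(params$intercept_sd < 0)) {
    rlang::abort("`intercept_sd` must be non-negative.")
  }
  k <- length(params$strata)
  if (length(params$intercepts) != k || length(params$slopes) != k ||
      length(params$stratum_weights) != k) {
    rlang::abort("strata, weights, intercepts and slopes must have equal length.")
  }
  if (params$n_participants < 1 || params$max_blocks < 1 || params$max_blocks > 6) {
    rlang::abort("`n_participants` must be >= 1 and `max_blocks` in 1..6.")
  }
  params
}

# deterministic per-participant substream seed (< 2^31)
.participant_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 1000003) %% 2147483647L)
}

.sim_lattice <- function(params, i) {
  set.seed(.participant_seed(params$seed, i))
  weeks <- c(-2L, -1L, seq_len(4L * params$max_blocks))
  nw <- length(weeks)
  sex <- if (stats::runif(1) < params$p_female) "female" else "male"
  low <- stats::runif(1) < params$p_low_engager
  s <- sample.int(length(params$strata), 1L, prob = params$stratum_weights)
  b0 <- stats::rnorm(1, params$intercepts[s], params$intercept_sd[s])
  b1 <- params$slopes[s]
  lambda <- exp(b0 + b1 * pmax(weeks - 1L, 0L))
  pp <- params$plan_prob[pmin(pmax(weeks, 1L), length(params$plan_prob))]
  conf_high <- stats::runif(nw) < params$conf_high_prob
  p_thu_sun <- if (low) params$low_engager_resp else params$resp_thu_sun
  p_fri_sat <- if (low) params$low_engager_resp else params$resp_fri_sat
  list(
    weeks = weeks, sex = sex, low_engager = low,
    stratum = params$strata[s], b0 = b0, b1 = b1,
    desired = stats::rpois(nw, lambda),
    plan = stats::runif(nw) < pp,
    commit = stats::runif(nw) < params$commit_prob,
    conf_high = conf_high,
    conf_fri = ifelse(conf_high, sample(4:5, nw, replace = TRUE),
                      sample(1:3, nw, replace = TRUE)),
    conf_sat = ifelse(conf_high, sample(4:5, nw, replace = TRUE),
                      sample(1:3, nw, replace = TRUE)),
    adherent = stats::runif(nw) <
      ifelse(conf_high, params$adherence_high, params$adherence_low),
    resp_thu = stats::runif(nw) < p_thu_sun,
    resp_fri = stats::runif(nw) < p_fri_sat,
    resp_sat = stats::runif(nw) < p_fri_sat,
    resp_sun = stats::runif(nw) < p_thu_sun,
    enroll_go = stats::runif(1) < params$enroll_prob,
    reenroll_go = stats::runif(params$max_blocks) < params$reenroll_probs
  )
}

.sim_respond_fn <- function(lat) {
  force(lat)
  function(state, msg) {
    w <- match(state$week, lat$weeks)
    switch(msg$template_id,
      plan_prompt = if (lat$resp_thu[w]) {
        list(value = if (lat$plan[w]) "yes" else "no")
      },
      goal_prompt = list(value = if (lat$commit[w]) "yes" else "no"),
      confidence_prompt = if (msg$day == "Fri") {
        if (lat$resp_fri[w]) list(value = lat$conf_fri[w])
      } else {
        if (lat$resp_sat[w]) list(value = lat$conf_sat[w])
      },
      max_prompt = if (lat$resp_sun[w]) {
        reported <- if (!is.null(state$committed_goal) && lat$adherent[w]) {
          min(lat$desired[w], state$committed_goal$limit)
        } else {
          lat$desired[w]
        }
        list(value = reported)
      },
      enroll_invite = if (lat$enroll_go) list(value = "Go"),
      block_invite = if (lat$reenroll_go[state$block_index]) list(value = "Go"),
      NULL
    )
  }
}

#' Simulate a synthetic intervention cohort
#'
#' Generates an engine-format event log by running each simulated
#' participant's pregenerated behavior through the scheduling/tailoring state
#' machine: run-in weekends, eligibility gating, adaptive goal prompts,
#' commitment, confidence reports, weekend maxima (truncated at the committed
#' limit on adherent weekends) and voluntary block re-enrollment. The full
#' latent ground truth is returned for parameter-recovery testing.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `cohort_sim`: a list with `events` (event-log
#'   tibble in canonical order), `participants` (per-participant truth:
#'   `participant_id`, `sex`, `stratum`, `b0`, `b1`, `low_engager`, final
#'   `phase`, `block_index`, `weeks_observed`), `truth` (per-week latent
#'   draws) and `params`.
#' @examples
#' sim <- simulate_cohort(sim_params(n_participants = 5, seed = 42))
#' dplyr::count(sim$events, type)
#' @export
simulate_cohort <- function(params) {
  params <- validate_sim_params(params)
  n <- params$n_participants
  all_events <- vector("list", n)
  parts <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("P%04d", i)
    lat <- .sim_lattice(params, i)
    state <- new_participant(pid, lat$sex)
    run <- .run_participant(state, .sim_respond_fn(lat),
                            max_weeks = 4L * params$max_blocks)
    all_events[[i]] <- run$events
    s <- run$state
    parts[[i]] <- tibble::tibble(
      participant_id = pid, sex = lat$sex, stratum = lat$stratum,
      b0 = lat$b0, b1 = lat$b1, low_engager = lat$low_engager,
      phase = s$phase, block_index = s$block_index,
      weeks_observed = length(s$history_week)
    )
    truths[[i]] <- tibble::tibble(
      participant_id = pid, week_index = lat$weeks, desired = lat$desired,
      plan = lat$plan, commit = lat$commit, conf_high = lat$conf_high,
      conf_fri = lat$conf_fri, conf_sat = lat$conf_sat,
      adherent = lat$adherent, resp_thu = lat$resp_thu,
      resp_fri = lat$resp_fri, resp_sat = lat$resp_sat,
      resp_sun = lat$resp_sun
    )
  }
  structure(
    list(
      events = arrange_event_log(.events_tibble(unlist(all_events, recursive = FALSE))),
      participants = dplyr::bind_rows(parts),
      truth = dplyr::bind_rows(truths),
      params = params
    ),
    class = "cohort_sim"
  )
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "<cohort_sim: %d participants, %d events, seed %d>\n",
    nrow(x$participants), nrow(x$events), x$params$seed
  ))
  invisible(x)
}

#' Generate synthetic screening records
#'
#' Produces a screening table in the layout expected by [score_screening()],
#' with a configurable mix of eligible-by-construction and ineligible
#' records. Ineligible records violate one randomly chosen criterion (AUDIT-C
#' below the sex-specific cutoff, no past-month binge day, or an exclusion
#' flag). Remaining fields are drawn to resemble a hazardous-drinking young
#' adult ED sample: 10-rung motivation ladder weighted toward
#' precontemplation, around nine of 24 alcohol consequences endorsed,
#' quarter daily smokers, half any-cannabis, 10% any-opioid, and DDQ
#' calendars concentrated on Friday/Saturday.
#'
#' @param n Number of records (default 72).
#' @param p_eligible Probability a record is eligible by construction
#'   (default 50/72).
#' @param seed Integer RNG seed.
#' @return A tibble of screening records.
#' @export
generate_screening <- function(n = 72L, p_eligible = 50 / 72, seed = 1L) {
  stopifnot(n >= 1, p_eligible >= 0, p_eligible <= 1)
  set.seed(as.integer(seed))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sex <- if (stats::runif(1) < 0.56) "female" else "male"
    cutoff <- if (sex == "female") 3L else 4L
    eligible <- stats::runif(1) < p_eligible
    flags <- c(FALSE, FALSE, FALSE)
    repeat {
      items <- sample(0:4, 3, replace = TRUE)
      if (sum(items) >= cutoff) break
    }
    binge_days <- sample(1:10, 1)
    if (!eligible) {
      violation <- sample(3, 1)
      if (violation == 1L) {
        repeat {
          items <- sample(0:4, 3, replace = TRUE)
          if (sum(items) < cutoff) break
        }
      } else if (violation == 2L) {
        binge_days <- 0L
      } else {
        flags[sample(3, 1)] <- TRUE
      }
    }
    ddq_typ <- c(stats::rpois(3, 0.5), stats::rpois(1, 1),
                 stats::rpois(2, 3), stats::rpois(1, 1))
    ddq_heavy <- ddq_typ + c(rep(0L, 4), stats::rpois(2, 3), stats::rpois(1, 1))
    row <- c(
      list(
        participant_id = sprintf("S%04d", i), age = sample(18:25, 1), sex = sex
      ),
      stats::setNames(as.list(items), paste0("auditc_", 1:3)),
      list(
        binge_days_past_month = binge_days,
        past_substance_treatment = flags[1], psychiatric_treatment = flags[2],
        no_sms_phone = flags[3],
        ladder_rung = sample(1:10, 1, prob = rep(c(0.38, 0.18, 0.16, 0.14, 0.14) / 2, each = 2))
      ),
      stats::setNames(as.list(as.integer(stats::runif(24) < 0.375)), paste0("byaacq_", 1:24)),
      list(
        cig_freq = if (stats::runif(1) < 0.26) 4L else sample(0:3, 1),
        cannabis_freq = if (stats::runif(1) < 0.5) sample(1:4, 1) else 0L,
        opioid_freq = if (stats::runif(1) < 0.10) sample(1:4, 1) else 0L
      ),
      stats::setNames(as.list(ddq_typ),
                      paste0("ddq_typical_", c("mon", "tue", "wed", "thu", "fri", "sat", "sun"))),
      stats::setNames(as.list(ddq_heavy),
                      paste0("ddq_heavy_", c("mon", "tue", "wed", "thu", "fri", "sat", "sun")))
    )
    rows[[i]] <- tibble::as_tibble(row)
  }
  dplyr::bind_rows(rows)
}
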