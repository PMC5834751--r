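# Independent oracles and small fixture builders used across tests.

# Pearson chi-square by the definitional formula sum((O - E)^2 / E)
chi2_brute <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Exact signed-rank two-sided p by enumerating all 2^n sign assignments
wilcox_enum_p <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  all_w <- as.vector(signs %*% r)
  min(1, 2 * min(mean(all_w <= w), mean(all_w >= w)))
}

# weekend-history tibble from a vector of maxima (NA = unanswered weekend)
make_history <- function(maxima, weeks = NULL) {
  if (is.null(weeks)) {
    weeks <- seq_along(maxima)
  }
  tibble::tibble(
    week_index = as.integer(weeks),
    max_drinks = as.integer(maxima),
    responded = !is.na(maxima)
  )
}

# simulation parameters for a single-stratum recovery cohort: everyone
# responds, no goals are committed, so reported maxima equal the latent
# Poisson draws over one 8-week enrollment (two blocks)
recovery_params <- function(intercept, slope, n = 200L, seed = 1L,
                            intercept_sd = 0.5) {
  sim_params(
    n_participants = n, stratum_weights = c(1, 0, 0, 0),
    intercepts = rep(intercept, 4), slopes = rep(slope, 4),
    intercept_sd = rep(intercept_sd, 4), plan_prob = 1, commit_prob = 0,
    adherence_high = 0, adherence_low = 0,
    resp_thu_sun = 1, resp_fri_sat = 1, p_low_engager = 0,
    reenroll_probs = c(1, 0, 0, 0, 0, 0), seed = seed
  )
}

# reported weekend maxima from an event log, as fit_weekend_trend input
log_to_records <- function(log) {
  log |>
    dplyr::filter(.data$type == "response", .data$template_id == "max_prompt",
                  .data$week_index >= 1) |>
    dplyr::transmute(
      participant_id = .data$participant_id,
      week_index = .data$week_index,
      max_drinks = as.integer(.data$value)
    )
}

# fully-compliant small cohort for engine property checks
compliant_params <- function(n = 20L, seed = 1L, max_blocks = 6L) {
  sim_params(
    n_participants = n, plan_prob = 1, commit_prob = 1,
    resp_thu_sun = 1, resp_fri_sat = 1, p_low_engager = 0,
    reenroll_probs = rep(0.7, 6), max_blocks = max_blocks, seed = seed
  )
}
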