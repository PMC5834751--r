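suppressMessages(library(dplyr))

test_that("chi-square matches the definitional formula on the printed goal-success tables", {
  t1 <- matrix(c(32, 10, 56, 1), 2, byrow = TRUE) # low vs high confidence
  t2 <- matrix(c(26, 8, 104, 8), 2, byrow = TRUE) # above-binge vs at-threshold goals
  r1 <- crosstab_chi2(t1)
  expect_equal(r1$statistic, chi2_brute(t1)$statistic)
  expect_equal(r1$statistic, 11.9098, tolerance = 1e-4)
  expect_equal(r1$p_value, 5.584e-4, tolerance = 1e-3)
  r2 <- crosstab_chi2(t2)
  expect_equal(r2$statistic, chi2_brute(t2)$statistic)
  expect_equal(r2$statistic, 7.1773, tolerance = 1e-4)
  expect_equal(r2$p_value, 7.383e-3, tolerance = 1e-3)

  # identical proportions
  flat <- crosstab_chi2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # zero margin is undefined, with an explicit signal
  expect_warning(z <- crosstab_chi2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "margin")
  expect_true(is.na(z$statistic))
  expect_error(crosstab_chi2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("signed-rank exact p agrees with full sign enumeration and the no-tie reference", {
  r <- wilcoxon_signed_rank(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.25)
  expect_equal(r$method, "exact")

  expect_warning(u <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_true(is.na(u$p_value))

  # antisymmetry: swapping pre and post flips W+ but keeps p
  pre <- c(3, 1, 4, 1, 5)
  post <- c(2, 7, 1, 8, 2)
  a <- wilcoxon_signed_rank(pre, post)
  b <- wilcoxon_signed_rank(post, pre)
  expect_equal(a$p_value, b$p_value)
  n <- a$n_nonzero
  expect_equal(a$statistic + b$statistic, n * (n + 1) / 2)

  # random small samples (with ties) against enumeration
  set.seed(99)
  for (i in 1:60) {
    n <- sample(2:8, 1)
    pre <- sample(0:6, n, replace = TRUE)
    post <- sample(0:6, n, replace = TRUE)
    if (all(post == pre)) next
    expect_equal(
      wilcoxon_signed_rank(pre, post)$p_value,
      wilcox_enum_p(pre, post),
      info = sprintf("case %d", i)
    )
  }

  # tie-free case agrees with the classical exact distribution
  set.seed(7)
  pre <- sample(1:100, 10)
  post <- pre + sample(c(-30:-1, 1:30), 10)
  ref <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE, exact = TRUE))
  expect_equal(wilcoxon_signed_rank(pre, post)$p_value, ref$p.value)
})

test_that("two-sample proportion test reproduces the pooled z benchmarks", {
  r <- two_sample_proportion_test(14, 32, 9, 32)
  expect_equal(r$p_value, 0.1927, tolerance = 1e-3)
  r2 <- two_sample_proportion_test(4, 6, 2, 6)
  expect_equal(r2$z, 1.1547, tolerance = 1e-4)
  expect_equal(r2$p_value, 0.2482, tolerance = 1e-3)
  eq <- two_sample_proportion_test(5, 10, 5, 10)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  expect_error(two_sample_proportion_test(1, 0, 1, 2), "positive")
  expect_error(two_sample_proportion_test(3, 2, 1, 2), "0..n")
})

test_that("response rates count in-window replies per prompt group", {
  sim <- simulate_cohort(compliant_params(n = 5, seed = 4, max_blocks = 1))
  rr <- response_rates(sim$events)
  expect_true(all(rr$rate == 1))
  expect_s3_class(rr, "compliance_table")

  # late replies are logged but not counted
  ev <- sim$events
  idx <- which(ev$type == "response" & ev$template_id == "max_prompt")
  ev$in_window[idx[1]] <- FALSE
  rr2 <- response_rates(ev, by = "template_id")
  max_row <- rr2[rr2$template_id == "max_prompt", ]
  expect_equal(max_row$responses, max_row$prompts - 1L)

  empty <- response_rates(sim$events[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("goal summary proportions carry auditable numerators and denominators", {
  sim <- simulate_cohort(compliant_params(n = 10, seed = 13, max_blocks = 2))
  gs <- goal_summary(sim$events)
  ov <- gs$overall
  expect_equal(ov$proportion, ov$numerator / ov$denominator)
  expect_equal(ov$proportion[ov$metric == "commitment"], 1) # commit_prob = 1

  # zero commitments: success proportion is undefined, not zero
  p0 <- sim_params(n_participants = 6, commit_prob = 0, plan_prob = 1,
                   resp_thu_sun = 1, resp_fri_sat = 1, p_low_engager = 0,
                   reenroll_probs = c(1, 0, 0, 0, 0, 0), seed = 2)
  gs0 <- goal_summary(simulate_cohort(p0)$events)
  expect_true(is.na(gs0$overall$proportion[gs0$overall$metric == "goal_success"]))

  # hand-checked success split: maxima (5,7,9) against limits (7,7,7)
  expect_equal(sum(evaluate_goal(7, c(5, 7, 9)) == "met") / 3, 2 / 3)
})

test_that("weekend trend fit recovers a known slope and flags degenerate strata", {
  # no-trend limit: constant counts give slope ~ 0
  flat <- tibble::tibble(
    participant_id = rep(sprintf("F%02d", 1:6), each = 4),
    week_index = rep(1:4, 6),
    max_drinks = rep(c(3L, 5L, 2L, 4L, 6L, 3L), each = 4)
  )
  fit0 <- fit_weekend_trend(flat)
  expect_lt(abs(tidy(fit0)$estimate[tidy(fit0)$term == "slope"]), 0.01)

  # recovery from simulated data with known truth
  sim <- simulate_cohort(recovery_params(2.82, -0.34, n = 200, seed = 51))
  fit <- fit_weekend_trend(log_to_records(sim$events))
  slope <- tidy(fit) |> filter(term == "slope") |> pull(estimate)
  expect_lt(abs(slope - (-0.34)), 0.05)
  td <- tidy(fit)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  g <- glance(fit)
  expect_equal(g$n_participants, 200L)

  # a stratum with fewer than 3 participants is skipped with a warning
  tiny <- flat |> mutate(stratum = rep(c("a", "b"), c(4, 20)))
  expect_warning(fit2 <- fit_weekend_trend(tiny, strata = "stratum"), "skipped")
  expect_false("a" %in% tidy(fit2)$stratum)
})

test_that("pre/post comparison produces the outcome table with matched tests", {
  set.seed(5)
  n <- 24
  base <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:n),
    max_weekend_drinks = rpois(n, 5),
    any_binge = rbinom(n, 1, 0.45),
    consequences = rpois(n, 9)
  )
  fup <- base |>
    mutate(
      max_weekend_drinks = pmax(0L, max_weekend_drinks - rpois(n, 2)),
      any_binge = rbinom(n, 1, 0.3),
      consequences = pmax(0L, consequences - rpois(n, 4))
    )
  groups <- tibble::tibble(
    participant_id = base$participant_id,
    group = rep(c("4wk", "8wk"), each = n / 2)
  )
  tab <- compare_prepost(base, fup, groups)
  expect_equal(sort(unique(tab$group)), c("4wk", "8wk", "any"))
  expect_equal(nrow(tab), 9L) # 3 outcomes x (2 groups + pooled)
  prop_p <- two_sample_proportion_test(sum(base$any_binge), n, sum(fup$any_binge), n)$p_value
  expect_equal(tab$p_value[tab$outcome == "any_binge" & tab$group == "any"], prop_p)
  wil_p <- wilcoxon_signed_rank(base$consequences, fup$consequences)$p_value
  expect_equal(tab$p_value[tab$outcome == "consequences" & tab$group == "any"], wil_p)
})
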