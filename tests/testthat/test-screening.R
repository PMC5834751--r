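test_that("AUDIT-C scoring sums three 0-4 items", {
  expect_equal(audit_c_score(c(0, 0, 0)), 0L)
  expect_equal(audit_c_score(c(4, 4, 4)), 12L)
  expect_equal(audit_c_score(c(4, 3, 3)), 10L)
  expect_equal(audit_c_score(rbind(c(1, 2, 3), c(0, 4, 0))), c(6L, 4L))
  expect_error(audit_c_score(c(5, 0, 0)), "0..4")
  expect_error(audit_c_score(c(1, 2)), "3 items")
})

test_that("eligibility applies sex-specific cutoffs, binge criterion, age and flags", {
  expect_true(screen_eligible("female", 3, 1, 21))
  expect_false(screen_eligible("male", 3, 2, 21)) # men need >= 4
  expect_true(screen_eligible("male", 4, 1, 25))
  expect_false(screen_eligible("female", 8, 0, 21)) # no binge day
  expect_false(screen_eligible("female", 8, 2, 26)) # too old
  expect_false(screen_eligible("female", 8, 2, 21, past_treatment = TRUE))
  expect_false(screen_eligible("female", 8, 2, 21, no_sms_phone = TRUE))

  # monotone in AUDIT-C score, everything else fixed
  for (sex in c("female", "male")) {
    elig <- screen_eligible(sex, 0:12, 1, 21)
    expect_true(all(diff(as.integer(elig)) >= 0))
  }
})

test_that("B-YAACQ is the count of endorsed items", {
  expect_equal(byaacq_sum(rep(FALSE, 24)), 0L)
  expect_equal(byaacq_sum(rep(TRUE, 24)), 24L)
  expect_equal(byaacq_sum(c(rep(1, 9), rep(0, 15))), 9L)
  expect_error(byaacq_sum(rep(TRUE, 23)), "24 items")
  expect_error(byaacq_sum(c(rep(1, 23), 2)), "dichotomous")
})

test_that("ladder rungs map two-per-stage onto the full stage continuum", {
  expect_equal(ladder_to_stage(1), "precontemplation")
  expect_equal(ladder_to_stage(5), "preparation")
  expect_equal(ladder_to_stage(10), "maintenance")
  stages <- ladder_to_stage(1:10)
  expect_equal(unique(stages), c(
    "precontemplation", "contemplation", "preparation", "action", "maintenance"
  ))
  expect_equal(as.vector(table(stages)), rep(2L, 5))
  expect_error(ladder_to_stage(0), "1..10")
  expect_error(ladder_to_stage(11), "1..10")
})

test_that("DDQ weekend maximum is over Thursday-Sunday only", {
  expect_equal(ddq_weekend_max(rep(0, 7)), 0L)
  expect_equal(ddq_weekend_max(c(0, 0, 0, 2, 8, 6, 1)), 8L)
  expect_equal(ddq_weekend_max(c(9, 0, 0, 0, 0, 0, 0)), 0L) # Monday excluded
})

test_that("NM-ASSIST recodes cigarettes to daily and cannabis/opioids to any", {
  none <- nm_assist_recode(0, 0, 0)
  expect_equal(unlist(none), c(cig_daily = 0L, cannabis_any = 0L, opioid_any = 0L))
  mixed <- nm_assist_recode(4, 0, 1)
  expect_equal(unlist(mixed), c(cig_daily = 1L, cannabis_any = 0L, opioid_any = 1L))
  expect_equal(nm_assist_recode(3, 0, 0)$cig_daily, 0L) # weekly < daily
})

test_that("score_screening derives all columns and survives a CSV round trip", {
  scr <- generate_screening(n = 40, seed = 7)
  scored <- score_screening(scr)
  expect_true(all(c(
    "auditc_score", "byaacq_total", "stage", "ddq_typical_weekend_max",
    "ddq_heavy_weekend_max", "cig_daily", "cannabis_any", "opioid_any", "eligible"
  ) %in% names(scored)))
  expect_true(all(scored$auditc_score >= 0 & scored$auditc_score <= 12))
  expect_true(all(scored$byaacq_total >= 0 & scored$byaacq_total <= 24))
  expect_true(all(scored$ddq_heavy_weekend_max >= scored$ddq_typical_weekend_max))

  path <- withr::local_tempfile(fileext = ".csv")
  write_screening(scr, path)
  again <- score_screening(read_screening(path))
  expect_equal(again$eligible, scored$eligible)
  expect_equal(again$auditc_score, scored$auditc_score)
})

test_that("generated screening mixes hit their eligibility targets", {
  all_in <- score_screening(generate_screening(n = 30, p_eligible = 1, seed = 1))
  expect_true(all(all_in$eligible))
  none_in <- score_screening(generate_screening(n = 30, p_eligible = 0, seed = 1))
  expect_false(any(none_in$eligible))

  # default mix: observed eligible count within the exact binomial 99% region
  scr <- score_screening(generate_screening(n = 300, seed = 11))
  region <- binom_accept_region(300, 50 / 72, 0.99)
  expect_gte(sum(scr$eligible), region[1])
  expect_lte(sum(scr$eligible), region[2])
})
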