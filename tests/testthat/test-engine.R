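suppressMessages(library(dplyr))

active_state <- function(maxima = c(10, 8), sex = "male") {
  s <- new_participant("T1", sex)
  s$phase <- "active"
  s$week <- 3L
  s$history_week <- seq_along(maxima)
  s$history_max <- as.integer(maxima)
  s$history_resp <- rep(TRUE, length(maxima))
  s
}

test_that("schedule grid: run-in sends Thu/Sun only, active adds goal support", {
  s <- new_participant("P1", "female")
  thu <- emit_prompts(s, "Thu")
  expect_equal(thu$template_id, "plan_prompt")
  expect_equal(thu$slot_time, "17:00")
  expect_equal(nrow(emit_prompts(s, "Fri")), 0L)
  expect_equal(nrow(emit_prompts(s, "Sat")), 0L)
  expect_equal(emit_prompts(s, "Sun")$template_id, "max_prompt")
  expect_equal(emit_prompts(s, "Sun")$slot_time, "13:00")

  a <- active_state()
  expect_equal(emit_prompts(a, "Thu")$template_id, "plan_prompt")
  # no committed goal: Friday/Saturday are silent
  expect_equal(nrow(emit_prompts(a, "Fri")), 0L)
  a$committed_goal <- list(week = 3L, limit = 7L, basis = "step_down", above_binge = TRUE)
  fri <- emit_prompts(a, "Fri")
  expect_equal(fri$template_id, c("goal_reminder", "confidence_prompt"))
  expect_equal(unique(fri$slot_time), "20:00")

  done <- active_state()
  done$phase <- "completed"
  expect_warning(out <- emit_prompts(done, "Thu"), "phase")
  expect_equal(nrow(out), 0L)
})

test_that("a yes plan reply triggers the adaptive goal prompt; no reply path is silent", {
  a <- active_state(maxima = c(10, 8)) # running average 9 -> limit 8
  res <- handle_response(a, list(template_id = "plan_prompt", value = "yes", day = "Thu"))
  expect_equal(res$messages$template_id, "goal_prompt")
  expect_equal(res$messages$limit, 8L)
  expect_equal(res$messages$payload, 9) # displayed "less than 9"
  expect_true(res$messages$above_binge)

  res2 <- handle_response(a, list(template_id = "plan_prompt", value = "no", day = "Thu"))
  expect_equal(nrow(res2$messages), 0L)
  expect_null(res2$state$committed_goal)

  # no responded weekend at all: plan yes but no goal prompt
  empty <- new_participant("T2", "male")
  empty$phase <- "active"
  empty$week <- 1L
  res3 <- handle_response(empty, list(template_id = "plan_prompt", value = "yes", day = "Thu"))
  expect_equal(nrow(res3$messages), 0L)
})

test_that("commitment stores the offered goal; confidence replies are tailored at <4", {
  a <- active_state()
  a <- handle_response(a, list(template_id = "plan_prompt", value = "yes", day = "Thu"))$state
  a <- handle_response(a, list(template_id = "goal_prompt", value = "yes", day = "Thu"))$state
  expect_equal(a$committed_goal$limit, 8L)

  low <- handle_response(a, list(template_id = "confidence_prompt", value = 3, day = "Fri"))
  expect_equal(low$messages$template_id, "support_low")
  high <- handle_response(a, list(template_id = "confidence_prompt", value = 4, day = "Sat"))
  expect_equal(high$messages$template_id, "support_high")
  bad <- handle_response(a, list(template_id = "confidence_prompt", value = 7, day = "Fri"))
  expect_equal(bad$messages$template_id, "reprompt")
})

test_that("Sunday maxima reports evaluate goals and record weekend history", {
  a <- active_state()
  a <- handle_response(a, list(template_id = "plan_prompt", value = "yes", day = "Thu"))$state
  a <- handle_response(a, list(template_id = "goal_prompt", value = "yes", day = "Thu"))$state

  ok <- handle_response(a, list(template_id = "max_prompt", value = 6, day = "Sun"))
  expect_equal(ok$messages$template_id, "feedback_success")
  hist <- weekend_history(ok$state)
  expect_equal(hist$max_drinks[hist$week_index == 3], 6L)

  fail <- handle_response(a, list(template_id = "max_prompt", value = 9, day = "Sun"))
  expect_equal(fail$messages$template_id, "feedback_failure")

  # without a committed goal the reply draws consumption feedback
  b <- active_state()
  cons <- handle_response(b, list(template_id = "max_prompt", value = 9, day = "Sun"))
  expect_equal(cons$messages$template_id, "feedback_consumption")

  # invalid drink counts are re-prompted, not crashed on
  bad <- handle_response(a, list(template_id = "max_prompt", value = -2, day = "Sun"))
  expect_equal(bad$messages$template_id, "reprompt")
  expect_false(3L %in% weekend_history(bad$state)$week_index)
})

test_that("run-in compliance gate requires answering at least half of prompts", {
  sim <- simulate_cohort(sim_params(n_participants = 30, seed = 5))
  el <- run_in_eligible(sim$events)
  expect_equal(nrow(el), 30L)
  expect_true(all(el$issued == 4L))
  expect_equal(el$eligible, el$answered / el$issued >= 0.5)
  # engine's own gating agrees: participants excluded at run-in are exactly
  # the ineligible or non-opting ones
  excluded <- sim$participants$participant_id[sim$participants$phase == "excluded"]
  expect_true(all(el$participant_id[!el$eligible] %in% excluded))
})

test_that("block transitions honour opt-in and the six-block cap", {
  s <- active_state()
  s$week <- 4L
  s2 <- block_transition(s, TRUE)
  expect_equal(s2$block_index, 2L)
  expect_equal(s2$phase, "active")

  s$block_index <- 6L
  s$week <- 24L
  expect_equal(block_transition(s, TRUE)$phase, "completed")
  s$block_index <- 3L
  s$week <- 12L
  expect_equal(block_transition(s, FALSE)$phase, "completed")

  s$week <- 13L
  expect_error(block_transition(s, TRUE), "boundary")
})

test_that("goal evaluations are conserved: one per committed weekend with an answered Sunday", {
  sim <- simulate_cohort(sim_params(n_participants = 40, seed = 3))
  ev <- sim$events
  feedback <- ev |>
    filter(type == "message", template_id %in% c("feedback_success", "feedback_failure"))
  gw <- goal_summary(ev)$weekends
  expect_equal(nrow(feedback), sum(gw$evaluated))

  # every goal prompt corresponds to a plan=yes reply with a defined average
  plan_yes <- ev |>
    filter(type == "response", template_id == "plan_prompt", week_index >= 1,
           tolower(value) == "yes")
  goal_prompts <- ev |> filter(type == "message", template_id == "goal_prompt")
  expect_lte(nrow(goal_prompts), nrow(plan_yes))
  # under full compliance the counts match exactly (average always defined)
  full <- simulate_cohort(compliant_params(n = 10, seed = 2, max_blocks = 2))
  py <- full$events |>
    filter(type == "response", template_id == "plan_prompt", week_index >= 1,
           tolower(value) == "yes")
  gp <- full$events |> filter(type == "message", template_id == "goal_prompt")
  expect_equal(nrow(gp), nrow(py))
})

test_that("no goal-support prompt is sent without a committed goal and none after completion", {
  sim <- simulate_cohort(sim_params(n_participants = 40, seed = 9))
  ev <- sim$events
  frisat <- ev |>
    filter(type == "message", day %in% c("Fri", "Sat"),
           template_id %in% c("goal_reminder", "confidence_prompt"))
  committed <- goal_summary(ev)$weekends |> filter(committed)
  expect_true(all(
    paste(frisat$participant_id, frisat$week_index) %in%
      paste(committed$participant_id, committed$week_index)
  ))
  # no events beyond each participant's final observed week
  last_week <- ev |>
    summarise(last = max(week_index), .by = participant_id)
  per_block <- sim$participants |>
    mutate(cap = block_index * 4L) |>
    inner_join(last_week, by = "participant_id")
  expect_true(all(per_block$last <= per_block$cap))
})

test_that("replaying an event log reproduces it exactly", {
  sim <- simulate_cohort(sim_params(n_participants = 15, seed = 21))
  rep1 <- replay_log(sim$events, sim$participants)
  rep2 <- replay_log(sim$events, sim$participants)
  expect_identical(rep1, rep2)
  expect_identical(arrange_event_log(rep1$events), sim$events)
  final <- rep1$states
  expect_equal(
    final$phase,
    sim$participants$phase[match(final$participant_id, sim$participants$participant_id)]
  )
})
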