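# EMA scheduling/tailoring state machine.
#
# Internal event representation is a plain named list (one per message or
# response) so the simulator and replay driver can run thousands of day-steps
# cheaply; events are bound into a tibble once per cohort. Public wrappers
# (emit_prompts, handle_response, replay_log) present tibbles.

ENGINE_SCHEMA_VERSION <- 1L

.days <- c("Thu", "Fri", "Sat", "Sun")

.slot_times <- c(Thu = "17:00", Fri = "20:00", Sat = "20:00", Sun = "13:00")

.event_fields <- c(
  "type", "participant_id", "week_index", "day", "slot_time", "template_id",
  "payload", "limit", "basis", "above_binge", "value", "in_reply_to",
  "in_window", "event_id"
)

#' EMA message templates
#'
#' The schedule grid of message templates the engine can emit. The five
#' assessment strings are fixed wording; tailored support and feedback
#' messages are identified by template only, with site-configurable text.
#' `[X]` in the goal-commitment prompt is replaced by the displayed number
#' `limit + 1` ("drink less than X" with an inclusive stored limit).
#'
#' @return A tibble with columns `template_id`, `text`, `expects_reply` and
#'   `days` (comma-separated days the template may be sent on).
#' @export
ema_templates <- function() {
  tibble::tribble(
    ~template_id, ~text, ~expects_reply, ~days,
    "plan_prompt", "Do you plan on drinking this weekend?", TRUE, "Thu",
    "goal_prompt", "Would you be willing to commit to a goal to drink less than [X] drinks on any occasion this weekend?", TRUE, "Thu",
    "goal_reminder", "[configurable goal reminder]", FALSE, "Fri,Sat",
    "confidence_prompt", "How confident are you that you will meet this goal on a scale from 1 (not at all) to 5 (completely)?", TRUE, "Fri,Sat",
    "max_prompt", "Between Thursday and today, what is the MOST drinks you had on any occasion?", TRUE, "Sun",
    "ack", "Thanks for completing this assessment. We will check in with you on [Thursday and Sunday].", FALSE, "Thu,Sun",
    "support_low", "[configurable self-efficacy support]", FALSE, "Fri,Sat",
    "support_high", "[configurable reinforcement]", FALSE, "Fri,Sat",
    "feedback_success", "[configurable success feedback]", FALSE, "Sun",
    "feedback_failure", "[configurable failure reframing]", FALSE, "Sun",
    "feedback_consumption", "[configurable consumption feedback]", FALSE, "Sun",
    "reprompt", "[configurable re-prompt after invalid reply]", FALSE, "Thu,Fri,Sat,Sun",
    "enroll_invite", "[configurable enrollment invitation: reply Go]", TRUE, "Sun",
    "block_invite", "[configurable re-enrollment invitation: reply Go]", TRUE, "Sun"
  )
}

.expects_reply <- local({
  tab <- NULL
  function(template_id) {
    if (is.null(tab)) {
      t <- ema_templates()
      tab <<- stats::setNames(t$expects_reply, t$template_id)
    }
    tab[[template_id]]
  }
})

.msg_id <- function(pid, week, day, template) {
  paste(pid, paste0("w", week), day, template, sep = "/")
}

.msg <- function(state, template, day, payload = NA_real_, limit = NA_integer_,
                 basis = NA_character_, above_binge = NA) {
  list(
    type = "message", participant_id = state$participant_id,
    week_index = state$week, day = day, slot_time = .slot_times[[day]],
    template_id = template, payload = as.numeric(payload),
    limit = as.integer(limit), basis = basis, above_binge = above_binge,
    value = NA_character_, in_reply_to = NA_character_, in_window = NA,
    event_id = .msg_id(state$participant_id, state$week, day, template)
  )
}

.resp <- function(state, msg, value, in_window = TRUE) {
  list(
    type = "response", participant_id = state$participant_id,
    week_index = state$week, day = msg$day, slot_time = msg$slot_time,
    template_id = msg$template_id, payload = NA_real_,
    limit = NA_integer_, basis = NA_character_, above_binge = NA,
    value = as.character(value), in_reply_to = msg$event_id,
    in_window = isTRUE(in_window),
    event_id = paste0(msg$event_id, "/r")
  )
}

.events_tibble <- function(events) {
  if (length(events) == 0L) {
    out <- tibble::tibble(
      type = character(), participant_id = character(), week_index = integer(),
      day = character(), slot_time = character(), template_id = character(),
      payload = numeric(), limit = integer(), basis = character(),
      above_binge = logical(), value = character(), in_reply_to = character(),
      in_window = logical(), event_id = character()
    )
    return(out)
  }
  dplyr::bind_rows(events)
}

#' Create a participant state
#'
#' Initializes the engine state for one participant at the start of the
#' 2-week assessment-only run-in (week -2). Intervention weeks are numbered
#' 1..24 across up to six voluntary 4-week blocks; there is no week 0.
#'
#' @param participant_id Character scalar.
#' @param sex `"female"` or `"male"` (drives the binge threshold used by the
#'   goal policy).
#' @param phase Starting phase, normally `"run_in"`.
#' @param week Starting week index (default -2).
#' @return An object of class `participant_state`.
#' @export
new_participant <- function(participant_id, sex, phase = "run_in", week = -2L) {
  stopifnot(sex %in% c("female", "male"))
  structure(
    list(
      participant_id = as.character(participant_id), sex = sex,
      phase = phase, block_index = 1L, week = as.integer(week),
      plan_to_drink = NA, offered_goal = NULL, committed_goal = NULL,
      confidence = c(Fri = NA_integer_, Sat = NA_integer_),
      history_week = integer(), history_max = integer(), history_resp = logical(),
      runin_issued = 0L, runin_answered = 0L
    ),
    class = "participant_state"
  )
}

#' @export
print.participant_state <- function(x, ...) {
  cat(sprintf(
    "<participant_state %s: %s, phase=%s, block=%d, week=%d, goal=%s>\n",
    x$participant_id, x$sex, x$phase, x$block_index, x$week,
    if (is.null(x$committed_goal)) "none" else x$committed_goal$limit
  ))
  invisible(x)
}

#' Weekend history of a participant state as a tibble
#'
#' @param state A `participant_state`.
#' @return Tibble with `week_index`, `max_drinks`, `responded`.
#' @export
weekend_history <- function(state) {
  tibble::tibble(
    week_index = state$history_week,
    max_drinks = state$history_max,
    responded = state$history_resp
  )
}

# running average on the internal history vectors (fast path)
.running_avg <- function(state, week) {
  keep <- state$history_resp & state$history_week < week
  if (!any(keep)) {
    return(NA_real_)
  }
  w <- state$history_week[keep]
  m <- state$history_max[keep]
  ord <- order(w, decreasing = TRUE)
  mean(m[ord[seq_len(min(2L, length(ord)))]])
}

# -- emission ---------------------------------------------------------------

.emit <- function(state, day) {
  if (!state$phase %in% c("run_in", "active")) {
    rlang::warn(sprintf(
      "emit_prompts called for participant %s in phase '%s'; no prompts sent.",
      state$participant_id, state$phase
    ))
    return(list(state = state, events = list()))
  }
  events <- list()
  if (state$phase == "run_in") {
    if (day == "Thu") events <- list(.msg(state, "plan_prompt", day))
    if (day == "Sun") events <- list(.msg(state, "max_prompt", day))
    state$runin_issued <- state$runin_issued + length(events)
  } else {
    if (day == "Thu") events <- list(.msg(state, "plan_prompt", day))
    if (day %in% c("Fri", "Sat") && !is.null(state$committed_goal)) {
      g <- state$committed_goal
      events <- list(
        .msg(state, "goal_reminder", day, payload = g$limit, limit = g$limit,
             basis = g$basis, above_binge = g$above_binge),
        .msg(state, "confidence_prompt", day)
      )
    }
    if (day == "Sun") events <- list(.msg(state, "max_prompt", day))
  }
  list(state = state, events = events)
}

# -- response handling ------------------------------------------------------

.is_yes <- function(value) tolower(trimws(value)) %in% c("yes", "y", "1")
.is_go <- function(value) tolower(trimws(value)) == "go"

.handle <- function(state, resp) {
  if (!state$phase %in% c("run_in", "active")) {
    rlang::warn(sprintf(
      "response from participant %s ignored in phase '%s'.",
      state$participant_id, state$phase
    ))
    return(list(state = state, events = list()))
  }
  out <- list()
  tpl <- resp$template_id
  day <- resp$day

  if (tpl == "plan_prompt") {
    yes <- .is_yes(resp$value)
    state$plan_to_drink <- yes
    if (state$phase == "run_in") {
      if (isTRUE(resp$in_window)) state$runin_answered <- state$runin_answered + 1L
      out <- c(out, list(.msg(state, "ack", day)))
    } else if (yes) {
      avg <- .running_avg(state, state$week)
      if (!is.na(avg)) {
        g <- .goal_limit1(avg, binge_threshold(state$sex))
        state$offered_goal <- list(
          week = state$week, limit = g$limit, basis = g$basis,
          above_binge = g$above_binge
        )
        out <- c(out, list(.msg(
          state, "goal_prompt", day, payload = g$limit + 1,
          limit = g$limit, basis = g$basis, above_binge = g$above_binge
        )))
      }
    }
  } else if (tpl == "goal_prompt") {
    if (.is_yes(resp$value) && !is.null(state$offered_goal)) {
      state$committed_goal <- state$offered_goal
    } else {
      state$committed_goal <- NULL
    }
  } else if (tpl == "confidence_prompt") {
    v <- suppressWarnings(as.numeric(resp$value))
    if (is.na(v) || !v %in% 1:5) {
      out <- c(out, list(.msg(state, "reprompt", day)))
    } else {
      state$confidence[[day]] <- as.integer(v)
      out <- c(out, list(.msg(
        state, if (v < 4) "support_low" else "support_high", day
      )))
    }
  } else if (tpl == "max_prompt") {
    v <- suppressWarnings(as.numeric(resp$value))
    if (is.na(v) || v < 0 || v != floor(v)) {
      out <- c(out, list(.msg(state, "reprompt", day)))
    } else {
      state$history_week <- c(state$history_week, state$week)
      state$history_max <- c(state$history_max, as.integer(v))
      state$history_resp <- c(state$history_resp, TRUE)
      if (state$phase == "run_in") {
        if (isTRUE(resp$in_window)) state$runin_answered <- state$runin_answered + 1L
        out <- c(out, list(.msg(state, "ack", day)))
      } else if (!is.null(state$committed_goal)) {
        met <- goal_met(state$committed_goal$limit, as.integer(v))
        out <- c(out, list(.msg(
          state, if (met) "feedback_success" else "feedback_failure", day,
          payload = v, limit = state$committed_goal$limit
        )))
      } else {
        out <- c(out, list(.msg(state, "feedback_consumption", day, payload = v)))
      }
    }
  } else if (tpl == "enroll_invite") {
    state$enroll_opt_in <- .is_go(resp$value)
  } else if (tpl == "block_invite") {
    state$block_opt_in <- .is_go(resp$value)
  } else {
    rlang::warn(sprintf("response to non-reply template '%s' ignored.", tpl))
  }
  list(state = state, events = out)
}

#' Voluntary 4-week block transition
#'
#' At the end of each 4-week block, participants choose whether to re-enroll
#' (by texting "Go") for another block, up to a maximum of six blocks. Opting
#' in below the cap advances to the next block; declining, or finishing the
#' sixth block, completes the study.
#'
#' @param state A `participant_state` whose `week` is at a block boundary
#'   (a positive multiple of 4).
#' @param opted_in Logical: did the participant opt in to another block?
#' @return The updated `participant_state`.
#' @export
block_transition <- function(state, opted_in) {
  if (!state$phase %in% c("active", "between_blocks")) {
    rlang::abort("block_transition requires an active participant.")
  }
  if (state$week < 4L || state$week %% 4L != 0L) {
    rlang::abort(sprintf(
      "block_transition requested off-boundary (week %d).", state$week
    ))
  }
  if (isTRUE(opted_in) && state$block_index < 6L) {
    state$block_index <- state$block_index + 1L
    state$phase <- "active"
  } else {
    state$phase <- "completed"
  }
  state
}

# -- weekly driver ----------------------------------------------------------

# respond_fn(state, msg) -> NULL (no reply) or list(value =, in_window = TRUE)
.engine_day <- function(state, day, respond_fn) {
  em <- .emit(state, day)
  state <- em$state
  events <- list()
  queue <- em$events
  while (length(queue) > 0L) {
    msg <- queue[[1L]]
    queue <- queue[-1L]
    events <- c(events, list(msg))
    if (isTRUE(.expects_reply(msg$template_id))) {
      r <- respond_fn(state, msg)
      if (!is.null(r)) {
        resp <- .resp(state, msg, r$value, r$in_window %||% TRUE)
        events <- c(events, list(resp))
        h <- .handle(state, resp)
        state <- h$state
        queue <- c(queue, h$events)
      }
    }
  }
  list(state = state, events = events)
}

.week_rollover <- function(state, respond_fn) {
  events <- list()
  # record an unanswered weekend
  if (!state$week %in% state$history_week) {
    state$history_week <- c(state$history_week, state$week)
    state$history_max <- c(state$history_max, NA_integer_)
    state$history_resp <- c(state$history_resp, FALSE)
  }
  state$plan_to_drink <- NA
  state$offered_goal <- NULL
  state$committed_goal <- NULL
  state$confidence <- c(Fri = NA_integer_, Sat = NA_integer_)

  if (state$phase == "run_in") {
    if (state$week == -1L) {
      eligible <- state$runin_issued > 0L &&
        state$runin_answered / state$runin_issued >= 0.5
      if (!eligible) {
        state$phase <- "excluded"
      } else {
        msg <- .msg(state, "enroll_invite", "Sun")
        events <- c(events, list(msg))
        state$enroll_opt_in <- FALSE
        r <- respond_fn(state, msg)
        if (!is.null(r)) {
          resp <- .resp(state, msg, r$value, r$in_window %||% TRUE)
          events <- c(events, list(resp))
          h <- .handle(state, resp)
          state <- h$state
        }
        if (isTRUE(state$enroll_opt_in)) {
          state$phase <- "active"
          state$week <- 1L
        } else {
          state$phase <- "excluded"
        }
      }
      if (state$phase != "active") state$week <- state$week + 1L
    } else {
      state$week <- state$week + 1L
    }
  } else if (state$phase == "active") {
    if (state$week %% 4L == 0L) {
      msg <- .msg(state, "block_invite", "Sun")
      events <- c(events, list(msg))
      state$block_opt_in <- FALSE
      r <- respond_fn(state, msg)
      if (!is.null(r)) {
        resp <- .resp(state, msg, r$value, r$in_window %||% TRUE)
        events <- c(events, list(resp))
        h <- .handle(state, resp)
        state <- h$state
      }
      state <- block_transition(state, isTRUE(state$block_opt_in))
    }
    if (state$phase == "active") state$week <- state$week + 1L
  }
  list(state = state, events = events)
}

.run_week <- function(state, respond_fn) {
  events <- list()
  for (day in .days) {
    st <- .engine_day(state, day, respond_fn)
    state <- st$state
    events <- c(events, st$events)
  }
  ro <- .week_rollover(state, respond_fn)
  list(state = ro$state, events = c(events, ro$events))
}

.run_participant <- function(state, respond_fn, max_weeks = 24L) {
  events <- list()
  while (state$phase %in% c("run_in", "active") && state$week <= max_weeks) {
    wk <- .run_week(state, respond_fn)
    state <- wk$state
    events <- c(events, wk$events)
  }
  list(state = state, events = events)
}

# -- public wrappers --------------------------------------------------------

#' Scheduled EMA prompts for one day
#'
#' Emits the message events the schedule calls for on a given day. During the
#' run-in only the Thursday drinking-plan prompt (5 pm) and Sunday
#' maximum-drinks prompt (1 pm) are sent. During active intervention weeks,
#' Thursday carries the plan prompt (the goal-commitment prompt follows a
#' "yes" plan reply via [handle_response()]), Friday and Saturday evening
#' (8 pm) carry a goal reminder plus confidence query only when a goal is
#' committed, and Sunday carries the maximum-drinks prompt.
#'
#' @param state A `participant_state`.
#' @param day `"Thu"`, `"Fri"`, `"Sat"` or `"Sun"`.
#' @return A tibble of message events (zero rows, with a warning, for
#'   completed/excluded participants).
#' @export
emit_prompts <- function(state, day) {
  day <- match.arg(day, .days)
  .events_tibble(.emit(state, day)$events)
}

#' Ingest one EMA response
#'
#' Applies the tailoring rules to a participant reply: a "yes" drinking-plan
#' reply triggers the adaptive goal-commitment prompt (when a running average
#' exists); a "yes" commitment stores the goal; confidence replies below 4
#' trigger the support template and 4-5 the reinforcement template; the Sunday
#' maximum-drinks reply appends a weekend record and triggers success,
#' failure-reframing or consumption feedback. Out-of-range values (negative
#' drinks, confidence outside 1..5) yield a re-prompt event rather than an
#' error.
#'
#' @param state A `participant_state`.
#' @param event A one-row data frame (or named list) with at least
#'   `template_id` and `value`; optional `day` (default from the template's
#'   schedule) and `in_window` (default `TRUE`).
#' @return A list with elements `state` (updated `participant_state`) and
#'   `messages` (tibble of tailored messages emitted in reaction).
#' @export
handle_response <- function(state, event) {
  if (is.data.frame(event)) event <- as.list(event[1, , drop = FALSE])
  tpl <- event$template_id
  day <- event$day %||% strsplit(
    ema_templates()$days[ema_templates()$template_id == tpl], ","
  )[[1]][1]
  resp <- list(
    template_id = tpl, value = as.character(event$value), day = day,
    week_index = state$week, in_window = event$in_window %||% TRUE
  )
  h <- .handle(state, resp)
  list(state = h$state, messages = .events_tibble(h$events))
}

#' Run-in EMA compliance and intervention eligibility
#'
#' Participants who answer at least half of the EMA prompts issued during the
#' 2-week assessment-only run-in are eligible to enroll in the intervention.
#' Only in-window responses count.
#'
#' @param log An event-log tibble (messages and responses).
#' @param threshold Minimum answered/issued proportion (default 0.5).
#' @return A tibble with one row per participant: `participant_id`, `issued`,
#'   `answered` and `eligible`.
#' @export
run_in_eligible <- function(log, threshold = 0.5) {
  runin <- dplyr::filter(
    log, .data$week_index < 0,
    .data$template_id %in% c("plan_prompt", "max_prompt")
  )
  prompts <- dplyr::count(
    dplyr::filter(runin, .data$type == "message"),
    .data$participant_id, name = "issued"
  )
  answers <- dplyr::count(
    dplyr::filter(runin, .data$type == "response", .data$in_window),
    .data$participant_id, name = "answered"
  )
  prompts |>
    dplyr::left_join(answers, by = "participant_id") |>
    tidyr::replace_na(list(answered = 0L)) |>
    dplyr::mutate(eligible = .data$answered / .data$issued >= threshold)
}

#' Deterministically replay an event log through the engine
#'
#' Reconstructs each participant's trajectory from the recorded responses:
#' the engine re-emits every scheduled and tailored message, consuming the
#' logged replies in schedule order. Replaying the same log always yields
#' identical final states and an identical event stream, which makes the
#' intervention fully auditable.
#'
#' @param log An event-log tibble (the `events` element of
#'   [simulate_cohort()], or read with [read_event_log()]).
#' @param participants A data frame with columns `participant_id` and `sex`.
#' @param max_weeks Safety cap on simulated weeks (default 24, i.e. six
#'   4-week blocks).
#' @return A list with `events` (the replayed event-log tibble) and `states`
#'   (a tibble of final participant states: phase, block, weeks on study).
#' @export
replay_log <- function(log, participants, max_weeks = 24L) {
  stopifnot(all(c("participant_id", "sex") %in% names(participants)))
  responses <- dplyr::filter(log, .data$type == "response")
  lookup <- split(responses, responses$in_reply_to)
  all_events <- list()
  states <- vector("list", nrow(participants))
  for (i in seq_len(nrow(participants))) {
    pid <- participants$participant_id[[i]]
    state <- new_participant(pid, participants$sex[[i]])
    respond_fn <- function(state, msg) {
      r <- lookup[[msg$event_id]]
      if (is.null(r) || nrow(r) == 0L) {
        return(NULL)
      }
      list(value = r$value[[1]], in_window = r$in_window[[1]])
    }
    run <- .run_participant(state, respond_fn, max_weeks = max_weeks)
    all_events <- c(all_events, run$events)
    s <- run$state
    states[[i]] <- tibble::tibble(
      participant_id = s$participant_id, sex = s$sex, phase = s$phase,
      block_index = s$block_index, weeks_observed = length(s$history_week)
    )
  }
  list(
    events = .events_tibble(all_events),
    states = dplyr::bind_rows(states)
  )
}
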