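#' AUDIT-C score
#'
#' Sum of the three AUDIT-C consumption items, each scored 0-4 (total 0-12).
#'
#' @param items Numeric vector of length 3, or a matrix/data frame with three
#'   columns (one row per respondent), each entry in 0..4.
#' @return Integer vector of scores in 0..12.
#' @examples
#' audit_c_score(c(4, 3, 3))
#' @export
audit_c_score <- function(items) {
  m <- if (is.data.frame(items) || is.matrix(items)) as.matrix(items) else matrix(items, nrow = 1)
  if (ncol(m) != 3L) rlang::abort("AUDIT-C has exactly 3 items.")
  if (any(is.na(m)) || any(m < 0) || any(m > 4) || any(m != floor(m))) {
    rlang::abort("AUDIT-C items must be integers in 0..4.")
  }
  as.integer(rowSums(m))
}

#' Study eligibility filter
#'
#' Eligibility requires recent hazardous drinking (AUDIT-C >= 3 for women,
#' >= 4 for men), at least one binge drinking episode in the prior month, age
#' 18-25, and none of the exclusion flags (past treatment for drug or alcohol
#' use, current psychiatric treatment, no SMS-capable phone).
#'
#' @param sex Character vector (`"female"`/`"male"`).
#' @param auditc_score Integer vector of AUDIT-C totals (0..12).
#' @param binge_days Integer vector, binge drinking days in the prior month.
#' @param age Numeric vector of ages in years.
#' @param past_treatment,psychiatric_treatment,no_sms_phone Logical exclusion
#'   flags (default all `FALSE`).
#' @return Logical vector.
#' @export
screen_eligible <- function(sex, auditc_score, binge_days, age,
                            past_treatment = FALSE, psychiatric_treatment = FALSE,
                            no_sms_phone = FALSE) {
  cutoff <- ifelse(sex == "female", 3L, 4L)
  auditc_score >= cutoff & binge_days >= 1 & age >= 18 & age <= 25 &
    !past_treatment & !psychiatric_treatment & !no_sms_phone
}

#' B-YAACQ consequence count
#'
#' The Brief Young Adult Alcohol Consequences Questionnaire is 24 dichotomous
#' (no/yes) items, summed.
#'
#' @param items Logical (or 0/1) vector of length 24, or a 24-column
#'   matrix/data frame with one row per respondent.
#' @return Integer vector of sums in 0..24.
#' @export
byaacq_sum <- function(items) {
  m <- if (is.data.frame(items) || is.matrix(items)) as.matrix(items) else matrix(items, nrow = 1)
  if (ncol(m) != 24L) rlang::abort("B-YAACQ has exactly 24 items.")
  if (any(is.na(m)) || !all(m %in% c(0, 1))) {
    rlang::abort("B-YAACQ items must be complete and dichotomous (0/1 or logical).")
  }
  as.integer(rowSums(m))
}

#' Alcohol Ladder rung to stage of change
#'
#' The Alcohol Ladder is a 10-rung visual analog scale of motivation to change
#' drinking. Rungs are coded onto the stage-of-change continuum two rungs per
#' stage: 1-2 precontemplation, 3-4 contemplation, 5-6 preparation, 7-8 action,
#' 9-10 maintenance.
#'
#' @param rung Integer vector in 1..10.
#' @return Character vector of stages.
#' @examples
#' ladder_to_stage(c(1, 5, 10))
#' @export
ladder_to_stage <- function(rung) {
  if (any(is.na(rung)) || any(rung < 1) || any(rung > 10) || any(rung != floor(rung))) {
    rlang::abort("`rung` must be an integer in 1..10.")
  }
  stages <- c("precontemplation", "contemplation", "preparation", "action", "maintenance")
  stages[ceiling(rung / 2)]
}

#' Maximum drinks on any weekend day from a DDQ grid
#'
#' The Daily Drinking Questionnaire records drinks per weekday (Monday through
#' Sunday). The weekend is defined as Thursday-Sunday, matching the EMA
#' observation window ("Between Thursday and today").
#'
#' @param grid Numeric vector of length 7 (Mon..Sun), or a 7-column
#'   matrix/data frame with one row per respondent.
#' @return Integer vector: maximum over Thu, Fri, Sat, Sun.
#' @examples
#' ddq_weekend_max(c(0, 0, 0, 2, 8, 6, 1)) # 8
#' @export
ddq_weekend_max <- function(grid) {
  m <- if (is.data.frame(grid) || is.matrix(grid)) as.matrix(grid) else matrix(grid, nrow = 1)
  if (ncol(m) != 7L) rlang::abort("DDQ grid has exactly 7 days (Mon..Sun).")
  if (any(is.na(m)) || any(m < 0)) rlang::abort("DDQ entries must be non-negative.")
  as.integer(apply(m[, 4:7, drop = FALSE], 1, max))
}

#' Dichotomize NM-ASSIST frequency codes
#'
#' Past-3-month frequency codes (0 never, 1 once or twice, 2 monthly,
#' 3 weekly, 4 daily or almost daily) are recoded as used in the analysis:
#' cigarette use to less-than-daily = 0 / at-least-daily = 1; cannabis and
#' opioid use to none = 0 / any = 1.
#'
#' @param cigarettes,cannabis,opioids Integer frequency codes in 0..4
#'   (vectors of equal length).
#' @return A tibble with integer 0/1 columns `cig_daily`, `cannabis_any`,
#'   `opioid_any`.
#' @export
nm_assist_recode <- function(cigarettes, cannabis, opioids) {
  chk <- function(x, nm) {
    if (any(is.na(x)) || !all(x %in% 0:4)) {
      rlang::abort(paste0("`", nm, "` must be frequency codes in 0..4."))
    }
  }
  chk(cigarettes, "cigarettes"); chk(cannabis, "cannabis"); chk(opioids, "opioids")
  tibble::tibble(
    cig_daily = as.integer(cigarettes >= 4),
    cannabis_any = as.integer(cannabis > 0),
    opioid_any = as.integer(opioids > 0)
  )
}

#' Score a screening table
#'
#' Takes a screening data frame (one row per respondent, the column layout
#' written by [generate_screening()] / read by [read_screening()]) and appends
#' the derived columns: `auditc_score`, `byaacq_total`, `stage`,
#' `ddq_typical_weekend_max`, `ddq_heavy_weekend_max`, `cig_daily`,
#' `cannabis_any`, `opioid_any` and `eligible`.
#'
#' @param screening Data frame with columns `participant_id`, `age`, `sex`,
#'   `auditc_1`..`auditc_3`, `binge_days_past_month`, logical/0-1 flags
#'   `past_substance_treatment`, `psychiatric_treatment`, `no_sms_phone`,
#'   `ladder_rung`, `byaacq_1`..`byaacq_24`, `cig_freq`, `cannabis_freq`,
#'   `opioid_freq`, `ddq_typical_mon`..`ddq_typical_sun`,
#'   `ddq_heavy_mon`..`ddq_heavy_sun`.
#' @return The input as a tibble with the derived columns appended.
#' @export
score_screening <- function(screening) {
  s <- tibble::as_tibble(screening)
  days <- c("mon", "tue", "wed", "thu", "fri", "sat", "sun")
  drug <- nm_assist_recode(s$cig_freq, s$cannabis_freq, s$opioid_freq)
  s |>
    dplyr::mutate(
      auditc_score = audit_c_score(dplyr::pick(paste0("auditc_", 1:3))),
      byaacq_total = byaacq_sum(dplyr::pick(paste0("byaacq_", 1:24))),
      stage = ladder_to_stage(.data$ladder_rung),
      ddq_typical_weekend_max = ddq_weekend_max(dplyr::pick(paste0("ddq_typical_", days))),
      ddq_heavy_weekend_max = ddq_weekend_max(dplyr::pick(paste0("ddq_heavy_", days))),
      cig_daily = drug$cig_daily,
      cannabis_any = drug$cannabis_any,
      opioid_any = drug$opioid_any,
      eligible = screen_eligible(
        .data$sex, .data$auditc_score, .data$binge_days_past_month, .data$age,
        as.logical(.data$past_substance_treatment),
        as.logical(.data$psychiatric_treatment),
        as.logical(.data$no_sms_phone)
      )
    )
}
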