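# ggplot2 displays for the result types.

#' Plot EMA response rates
#'
#' @param object A `compliance_table` from [response_rates()] (grouped by
#'   block and slot type).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.compliance_table <- function(object, ...) {
  x <- names(object)[1]
  colour <- if ("slot_type" %in% names(object)) "slot_type" else NULL
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[x]], y = .data$rate,
    colour = if (is.null(colour)) NULL else .data[[colour]],
    group = if (is.null(colour)) 1 else .data[[colour]]
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "EMA response rate", colour = "Slot") +
    ggplot2::theme_minimal()
  p
}

#' Plot goal metrics
#'
#' Shows the share of goal prompts above the binge threshold by week, the
#' signature of the step-down policy converging onto non-binge limits.
#'
#' @param object A `goal_metrics` object from [goal_summary()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.goal_metrics <- function(object, ...) {
  ggplot2::ggplot(object$above_binge_by_week, ggplot2::aes(
    x = .data$week_index, y = .data$proportion
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(
      x = "Intervention week",
      y = "Goal prompts above binge threshold"
    ) +
    ggplot2::theme_minimal()
}

#' Plot fitted weekend-maxima trends
#'
#' Fitted mean maximum drinks per week, per stratum, from the Poisson
#' random-intercept model (population-level curve).
#'
#' @param object A `weekend_trend` object from [fit_weekend_trend()].
#' @param weeks Week range to display (default 1..12).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.weekend_trend <- function(object, weeks = 1:12, ...) {
  td <- tidy.weekend_trend(object)
  curves <- td |>
    tidyr::pivot_wider(
      id_cols = "stratum", names_from = "term", values_from = "estimate"
    ) |>
    dplyr::reframe(
      week_index = weeks,
      mean_max = exp(.data$intercept + .data$slope * (weeks - 1)),
      .by = "stratum"
    )
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$week_index, y = .data$mean_max, colour = .data$stratum
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Intervention week", y = "Fitted mean maximum drinks",
      colour = "Stratum"
    ) +
    ggplot2::theme_minimal()
}

#' Median weekend maxima by week and stratum
#'
#' Plots the median reported maximum drinks on any weekend day across weeks,
#' per enrollment-length stratum, including run-in weekends (weeks -2, -1) to
#' show assessment reactivity before the intervention starts.
#'
#' @param log Event-log tibble.
#' @param participants Data frame with `participant_id` and `stratum`.
#' @return A ggplot.
#' @export
plot_weekend_medians <- function(log, participants) {
  maxima <- log |>
    dplyr::filter(.data$type == "response", .data$template_id == "max_prompt") |>
    dplyr::mutate(max_drinks = suppressWarnings(as.numeric(.data$value))) |>
    dplyr::inner_join(participants[, c("participant_id", "stratum")],
                      by = "participant_id") |>
    dplyr::summarise(
      median_max = stats::median(.data$max_drinks),
      .by = c("week_index", "stratum")
    )
  ggplot2::ggplot(maxima, ggplot2::aes(
    x = .data$week_index, y = .data$median_max, colour = .data$stratum
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "Week (run-in weeks negative)", y = "Median maximum drinks",
      colour = "Stratum"
    ) +
    ggplot2::theme_minimal()
}
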