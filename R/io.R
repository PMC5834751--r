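# Event-log (JSON-Lines), screening (CSV) and configuration (YAML) I/O.

.day_order <- function(day) match(day, .days)

#' Canonical ordering of an event log
#'
#' Stable ordering by participant, week, day (Thu < Fri < Sat < Sun), slot
#' time, and emission order within a slot (messages before their responses).
#'
#' @param events Event-log tibble.
#' @return The tibble reordered.
#' @export
arrange_event_log <- function(events) {
  events |>
    dplyr::mutate(.day_ord = .day_order(.data$day)) |>
    dplyr::arrange(.data$participant_id, .data$week_index, .data$.day_ord,
                   .data$slot_time) |>
    dplyr::select(-".day_ord")
}

#' Write an event log as JSON-Lines
#'
#' One JSON object per line (`NA` as `null`), each carrying
#' `schema_version`. Lines are written in canonical order
#' (see [arrange_event_log()]), so identical logs produce identical files.
#'
#' @param events Event-log tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  events <- arrange_event_log(events)
  events$schema_version <- ENGINE_SCHEMA_VERSION
  con <- file(path, open = "wb")
  on.exit(close(con))
  jsonlite::stream_out(as.data.frame(events), con, verbose = FALSE, na = "null")
  invisible(path)
}

#' Read a JSON-Lines event log
#'
#' Each line is parsed independently; malformed lines either abort with an
#' error naming the line number (`on_error = "abort"`, the default) or are
#' skipped with a message reporting how many were dropped
#' (`on_error = "skip"`).
#'
#' @param path Input file path.
#' @param on_error `"abort"` or `"skip"`.
#' @return An event-log tibble.
#' @export
read_event_log <- function(path, on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parsed <- vector("list", length(lines))
  bad <- integer()
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) NULL)
    if (is.null(rec) || is.null(rec$type)) {
      if (on_error == "abort") {
        rlang::abort(sprintf("Malformed event-log line %d in '%s'.", i, path))
      }
      bad <- c(bad, i)
    } else {
      parsed[[i]] <- lapply(rec, function(x) if (is.null(x)) NA else x)
    }
  }
  if (length(bad) > 0L) {
    rlang::inform(sprintf("Skipped %d malformed line(s) in '%s'.", length(bad), path))
    parsed <- parsed[-bad]
  }
  out <- dplyr::bind_rows(parsed)
  if (nrow(out) > 0L) {
    out$schema_version <- NULL
    out$week_index <- as.integer(out$week_index)
    out$limit <- as.integer(out$limit)
    out$payload <- as.numeric(out$payload)
  }
  tibble::as_tibble(out)
}

#' Write/read a screening table as CSV
#'
#' Plain CSV with a documented header row; [read_screening()] returns a
#' tibble ready for [score_screening()].
#'
#' @param screening Screening tibble.
#' @param path File path.
#' @return `path` invisibly / a tibble.
#' @export
write_screening <- function(screening, path) {
  utils::write.csv(as.data.frame(screening), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_screening
#' @export
read_screening <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Run configuration
#'
#' Assembles (and validates) the configuration of a reproducible run:
#' thresholds, schedule times, simulation parameters and the RNG seed.
#' `read_run_config()` loads a YAML file whose keys override these defaults;
#' a `sim` block is passed to [sim_params()].
#'
#' @param seed Integer RNG seed.
#' @param runin_threshold Minimum run-in response proportion (default 0.5).
#' @param confidence_split Scores below this are "low" confidence (default 4).
#' @param schedule_times Named character vector of prompt times.
#' @param sim A [sim_params()] object (built with `seed` if omitted).
#' @param output_dir Directory for outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, runin_threshold = 0.5, confidence_split = 4,
                       schedule_times = .slot_times, sim = NULL,
                       output_dir = ".") {
  if (is.null(sim)) sim <- sim_params(seed = seed)
  cfg <- structure(
    list(
      seed = as.integer(seed), runin_threshold = runin_threshold,
      confidence_split = confidence_split, schedule_times = schedule_times,
      sim = sim, output_dir = output_dir
    ),
    class = "run_config"
  )
  if (cfg$runin_threshold < 0 || cfg$runin_threshold > 1) {
    rlang::abort("`runin_threshold` must lie in [0, 1].")
  }
  cfg
}

#' @rdname run_config
#' @param path Path to a YAML configuration file.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  seed <- raw$seed %||% 1L
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  run_config(
    seed = seed,
    runin_threshold = raw$runin_threshold %||% 0.5,
    confidence_split = raw$confidence_split %||% 4,
    sim = do.call(sim_params, sim_args),
    output_dir = raw$output_dir %||% "."
  )
}

#' Hash of a run configuration
#'
#' @param config A `run_config` object.
#' @return A character hash, embedded in output metadata so identical
#'   (config, inputs) runs are verifiably identical.
#' @export
config_hash <- function(config) {
  rlang::hash(config)
}

#' Write a result table with reproducibility metadata
#'
#' CSV preceded by `#`-prefixed metadata lines (seed, config hash, package
#' version); [read_result_table()] skips them.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param config Optional `run_config` whose seed and hash are recorded.
#' @return `path` invisibly / a tibble.
#' @export
write_result_table <- function(x, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  meta <- c(
    sprintf("# goalstep %s", as.character(utils::packageVersion("goalstep"))),
    if (!is.null(config)) sprintf("# seed: %d", config$seed),
    if (!is.null(config)) sprintf("# config_hash: %s", config_hash(config))
  )
  writeLines(meta, con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}
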