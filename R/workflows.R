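#' Write detected behaviour changes to CSV
#'
#' Columns `day_hour` (ISO-8601 to the hour), `step_difference`, `type`.
#'
#' @param changes The `changes` tibble of [detect_batch()].
#' @param path Output path; written atomically.
#' @return `path`, invisibly.
#' @export
write_changes_csv <- function(changes, path) {
  df <- data.frame(
    day_hour = sprintf("%sT%02d:00", format(changes$day), changes$hour),
    step_difference = changes$step_difference,
    type = changes$type
  )
  atomic_write(path, function(p) utils::write.csv(df, p, row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' Write confirmed habits to CSV
#'
#' Columns `first_day_hour` (ISO-8601 to the hour), `last_day`, `type`.
#'
#' @param habits The `habits` tibble of [detect_batch()].
#' @param path Output path; written atomically.
#' @return `path`, invisibly.
#' @export
write_habits_csv <- function(habits, path) {
  df <- data.frame(
    first_day_hour = sprintf("%sT%02d:00", format(habits$first_day), habits$hour),
    last_day = format(habits$last_day),
    type = habits$type
  )
  atomic_write(path, function(p) utils::write.csv(df, p, row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' Detect workflow: hourly CSV in, change/habit CSVs out
#'
#' @param input Path to an hourly CSV (columns `day_hour`, `steps`).
#' @param changes_out,habits_out Output CSV paths (written atomically);
#'   `NULL` skips the file.
#' @param config A [detector_config()].
#' @return Invisibly, the [detect_batch()] result.
#' @export
run_detect <- function(input, changes_out = NULL, habits_out = NULL,
                       config = detector_config()) {
  series <- read_hourly_csv(input)
  res <- detect_batch(series, config)
  if (!is.null(changes_out)) write_changes_csv(res$changes, changes_out)
  if (!is.null(habits_out)) write_habits_csv(res$habits, habits_out)
  invisible(res)
}

#' Simulate workflow: write surrogate baseline series to a directory
#'
#' @param group Cohort group (see [cohort_spec()]).
#' @param n Number of participants; `NULL` for the group default.
#' @param days Days per baseline.
#' @param seed Integer seed fixing cohort and noise.
#' @param out_dir Directory receiving one hourly CSV per participant.
#' @return Invisibly, the written file paths.
#' @export
run_simulate <- function(group = "children", n = NULL, days = 9, seed = 42,
                         out_dir = ".") {
  spec <- cohort_spec(group, n = n, n_days = days)
  set.seed(seed)
  cohort <- generate_cohort(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(cohort))
  for (p in seq_along(cohort)) {
    base <- build_baseline(cohort[[p]], spec$n_days)
    paths[p] <- file.path(out_dir, sprintf("%s.csv", cohort[[p]]$id))
    write_hourly_csv(base, paths[p])
  }
  invisible(paths)
}

#' Evaluate workflow: accuracy curves to CSV
#'
#' @param group Cohort group (see [cohort_spec()]).
#' @param magnitudes Injected magnitudes in steps/hour.
#' @param kinds Event kinds to evaluate.
#' @param n_reps Noise replicates per magnitude.
#' @param seed Integer seed.
#' @param out Optional CSV path (columns `group`, `event_kind`, `sign`,
#'   `magnitude`, `n`, `detected`, `accuracy`); written atomically.
#' @param config A [detector_config()].
#' @return The combined accuracy tibble.
#' @export
run_evaluate <- function(group = "children", magnitudes = seq(0, 2000, by = 100),
                         kinds = c("change", "habit"), n_reps = 10, seed = 1,
                         out = NULL, config = detector_config()) {
  spec <- cohort_spec(group)
  res <- do.call(rbind, lapply(seq_along(kinds), function(i) {
    evaluate_accuracy(spec, magnitudes, kinds[i], cfg = config,
                      n_reps = n_reps, seed = seed + i - 1L)
  }))
  if (!is.null(out)) {
    atomic_write(out, function(p) utils::write.csv(res, p, row.names = FALSE))
  }
  res
}
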