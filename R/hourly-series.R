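#' Hourly step-count series
#'
#' Container for one participant's grid of hourly step totals, indexed by
#' calendar day and hour of day. A cell is either a non-negative step total or
#' `NA`, meaning the hour is missing (e.g. non-wear time): missing hours are
#' skipped by the detector, never treated as zero steps.
#'
#' @param values Numeric matrix, days in rows and hours of day in columns.
#'   `NA` marks a missing hour. Values must be non-negative; step totals are
#'   conventionally whole numbers.
#' @param days Vector coercible to `Date`, one per row, strictly increasing.
#' @param hours Integer hours of day (0-23), one per column, strictly
#'   increasing.
#' @param participant_id Optional identifier carried through outputs.
#'
#' @return An object of class `hourly_series` with fields `participant_id`,
#'   `days`, `hours` and the `values` matrix.
#' @seealso [aggregate_hourly()], [read_hourly_csv()], [detect_batch()]
#' @export
hourly_series <- function(values, days, hours, participant_id = NA_character_) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  days <- as.Date(days)
  hours <- as.integer(hours)
  if (nrow(values) != length(days)) {
    stop("`values` must have one row per day", call. = FALSE)
  }
  if (ncol(values) != length(hours)) {
    stop("`values` must have one column per hour", call. = FALSE)
  }
  if (anyNA(days) || is.unsorted(days, strictly = TRUE)) {
    stop("`days` must be strictly increasing calendar days", call. = FALSE)
  }
  if (anyNA(hours) || any(hours < 0L | hours > 23L) ||
      is.unsorted(hours, strictly = TRUE)) {
    stop("`hours` must be strictly increasing hours of day in 0-23", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("step counts must be non-negative", call. = FALSE)
  }
  dimnames(values) <- list(format(days), hours)
  structure(
    list(participant_id = participant_id, days = days, hours = hours,
         values = values),
    class = "hourly_series"
  )
}

#' @export
print.hourly_series <- function(x, ...) {
  cat(sprintf(
    "<hourly_series> %s: %d day(s) x %d hour(s), %d missing hour(s)\n",
    if (is.na(x$participant_id)) "(unnamed)" else x$participant_id,
    length(x$days), length(x$hours), sum(is.na(x$values))
  ))
  cat(sprintf("  days  %s .. %s\n", format(x$days[1]), format(x$days[length(x$days)])))
  cat(sprintf("  hours %02d:00 .. %02d:00\n", x$hours[1], x$hours[length(x$hours)]))
  invisible(x)
}

#' @export
as.data.frame.hourly_series <- function(x, ...) {
  grid <- expand.grid(hour = seq_along(x$hours), day = seq_along(x$days))
  data.frame(
    day = x$days[grid$day],
    hour = x$hours[grid$hour],
    steps = x$values[cbind(grid$day, grid$hour)]
  )
}

#' Aggregate a raw timestamped step stream into hourly totals
#'
#' Sums step samples within clock-aligned, half-open hours `[h:00, h+1:00)`.
#' An hour is stored only when a full hour's worth of samples was observed
#' (sample count equal to `expected_samples_per_hour`); any partially covered
#' or empty hour is stored as missing, not as zero.
#'
#' @param samples Data frame with columns `timestamp` (`POSIXct` or parseable
#'   date-time strings, strictly increasing) and `steps` (non-negative counts).
#' @param expected_samples_per_hour Number of samples the device nominally
#'   emits per hour (60 for per-minute data, 1 for already-hourly data).
#' @param hours Hours of day forming the output grid. Defaults to the 18
#'   waking hours 06:00-23:59.
#' @param participant_id Optional identifier.
#'
#' @return An [hourly_series()] spanning the calendar days observed.
#' @export
aggregate_hourly <- function(samples, expected_samples_per_hour, hours = 6:23,
                             participant_id = NA_character_) {
  if (!is.data.frame(samples) || !all(c("timestamp", "steps") %in% names(samples))) {
    stop("`samples` must be a data frame with columns `timestamp` and `steps`",
         call. = FALSE)
  }
  expected_samples_per_hour <- as.integer(expected_samples_per_hour)
  if (length(expected_samples_per_hour) != 1L || is.na(expected_samples_per_hour) ||
      expected_samples_per_hour < 1L) {
    stop("`expected_samples_per_hour` must be a positive integer", call. = FALSE)
  }
  ts <- samples$timestamp
  if (!inherits(ts, "POSIXt")) ts <- parse_timestamp(as.character(ts))
  steps <- samples$steps
  if (!is.numeric(steps) || anyNA(steps)) {
    stop("`steps` must be numeric with no missing values", call. = FALSE)
  }
  if (any(steps < 0)) stop("negative step value in input stream", call. = FALSE)
  if (anyDuplicated(ts)) stop("duplicate timestamp in input stream", call. = FALSE)
  if (is.unsorted(ts, strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }

  # local clock components as recorded; no timezone arithmetic
  day <- as.Date(format(ts, "%Y-%m-%d"))
  hr <- as.integer(format(ts, "%H"))
  days <- seq(min(day), max(day), by = "day")
  values <- matrix(NA_real_, length(days), length(hours))

  key <- paste(format(day), hr)
  counts <- tapply(steps, key, length)
  sums <- tapply(steps, key, sum)
  complete <- names(counts)[counts == expected_samples_per_hour]
  for (kk in complete) {
    parts <- strsplit(kk, " ", fixed = TRUE)[[1]]
    i <- match(as.Date(parts[1]), days)
    j <- match(as.integer(parts[2]), hours)
    if (!is.na(j)) values[i, j] <- sums[[kk]]
  }
  hourly_series(values, days, hours, participant_id)
}

#' Read an hourly step series from CSV
#'
#' Expects one row per (day, hour) with columns `day_hour` and `steps`; an
#' empty steps cell marks a missing hour. Day-hours may be ISO-8601
#' (`2021-11-01T08:00`) or the long display form `1 November 2021 08:00`.
#' Round-trips losslessly with [write_hourly_csv()] for integer-valued series.
#'
#' @param path CSV file path.
#' @param participant_id Optional identifier.
#' @return An [hourly_series()].
#' @export
read_hourly_csv <- function(path, participant_id = NA_character_) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  canon <- gsub("[^a-z]", "", tolower(names(df)))
  dh_col <- match(TRUE, canon %in% c("dayhour", "dayandhour"))
  st_col <- match(TRUE, canon %in% c("steps", "totalnumberofsteps"))
  if (is.na(dh_col) || is.na(st_col)) {
    stop("CSV must have columns `day_hour` and `steps`", call. = FALSE)
  }
  dh <- parse_day_hour(df[[dh_col]])
  raw <- trimws(df[[st_col]])
  missing <- is.na(raw) | raw == ""
  bad <- !missing & !grepl("^[0-9]+$", raw)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("non-integer steps value '%s' at row %d", raw[i], i), call. = FALSE)
  }
  steps <- ifelse(missing, NA_real_, suppressWarnings(as.numeric(raw)))
  if (anyDuplicated(paste(dh$day, dh$hour))) {
    stop("duplicate (day, hour) row in CSV", call. = FALSE)
  }
  days <- seq(min(dh$day), max(dh$day), by = "day")
  hours <- sort(unique(dh$hour))
  values <- matrix(NA_real_, length(days), length(hours))
  values[cbind(match(dh$day, days), match(dh$hour, hours))] <- steps
  hourly_series(values, days, hours, participant_id)
}

#' Write an hourly step series to CSV
#'
#' One row per grid cell in (day, hour) order, columns `day_hour`
#' (ISO-8601 to the hour) and `steps` (empty when the hour is missing).
#'
#' @param series An [hourly_series()].
#' @param path Output path; the file is written atomically.
#' @return `path`, invisibly.
#' @export
write_hourly_csv <- function(series, path) {
  stopifnot(inherits(series, "hourly_series"))
  grid <- expand.grid(hour = seq_along(series$hours), day = seq_along(series$days))
  steps <- series$values[cbind(grid$day, grid$hour)]
  df <- data.frame(
    day_hour = sprintf("%sT%02d:00", format(series$days)[grid$day],
                       series$hours[grid$hour]),
    steps = ifelse(is.na(steps), "", format(steps, scientific = FALSE, trim = TRUE))
  )
  atomic_write(path, function(p) utils::write.csv(df, p, row.names = FALSE, quote = FALSE))
  invisible(path)
}

parse_day_hour <- function(x) {
  x <- trimws(x)
  out <- parse_datetime_multi(
    x,
    c("%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%dT%H:%M:%S",
      "%Y-%m-%d %H:%M:%S", "%d %B %Y %H:%M")
  )
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    stop(sprintf("malformed day-hour value '%s' at row %d", x[i], i), call. = FALSE)
  }
  list(day = as.Date(format(out, "%Y-%m-%d")),
       hour = as.integer(format(out, "%H")))
}

parse_timestamp <- function(x) {
  out <- parse_datetime_multi(
    x,
    c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M",
      "%Y-%m-%d %H:%M")
  )
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    stop(sprintf("malformed timestamp '%s' at row %d", x[i], i), call. = FALSE)
  }
  out
}

parse_datetime_multi <- function(x, formats) {
  old <- Sys.getlocale("LC_TIME")
  on.exit(suppressWarnings(Sys.setlocale("LC_TIME", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_TIME", "C"))  # English month names
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (f in formats) {
    idx <- which(is.na(out))
    if (length(idx) == 0L) break
    out[idx] <- as.POSIXct(strptime(x[idx], f, tz = "UTC"))
  }
  out
}

atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = ".tmpwrite", tmpdir = dirname(path))
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop(sprintf("cannot write '%s'", path), call. = FALSE)
  ok <- TRUE
  invisible(path)
}
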