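#' Derive a participant profile from an hourly series
#'
#' Summarises a participant's recorded activity as the per-hour-of-day mean
#' step vector together with the mean hourly coefficient of variation
#' (mean over hours of per-hour sample SD / per-hour mean, hours with zero
#' mean excluded). These two quantities parameterise the synthetic baseline
#' generator.
#'
#' @param series An [hourly_series()].
#' @return A list of class `participant_profile` with fields `id`,
#'   `hourly_means` (named by hour) and `cv`.
#' @export
derive_profile <- function(series) {
  stopifnot(inherits(series, "hourly_series"))
  V <- series$values
  all_missing <- colSums(!is.na(V)) == 0L
  if (any(all_missing)) {
    stop(sprintf("no data at hour %02d:00", series$hours[which(all_missing)[1]]),
         call. = FALSE)
  }
  m <- colMeans(V, na.rm = TRUE)
  s <- apply(V, 2, stats::sd, na.rm = TRUE)
  ratio <- (s / m)[m > 0 & !is.na(s)]
  cv <- if (length(ratio)) mean(ratio) else 0
  new_profile(series$participant_id, stats::setNames(m, series$hours), cv)
}

new_profile <- function(id, hourly_means, cv) {
  if (any(hourly_means < 0)) stop("hourly means must be non-negative", call. = FALSE)
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  structure(list(id = id, hourly_means = hourly_means, cv = cv),
            class = "participant_profile")
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf("<participant_profile> %s: %d active hours, mean %0.f steps/h, cv %.2f\n",
              if (is.na(x$id)) "(unnamed)" else x$id, length(x$hourly_means),
              mean(x$hourly_means), x$cv))
  invisible(x)
}

# common diurnal template: commute peak at 08:00, lunchtime peak at noon,
# evening taper; relative weights over the 18 waking hours
diurnal_template <- function(hours) {
  w <- c("6" = 0.40, "7" = 0.80, "8" = 1.40, "9" = 1.00, "10" = 0.90,
         "11" = 1.00, "12" = 1.50, "13" = 1.20, "14" = 0.90, "15" = 1.00,
         "16" = 1.10, "17" = 1.20, "18" = 1.00, "19" = 0.80, "20" = 0.60,
         "21" = 0.50, "22" = 0.35, "23" = 0.25)
  out <- w[as.character(hours)]
  out[is.na(out)] <- 1
  stats::setNames(as.numeric(out), hours)
}

#' Specify a surrogate cohort
#'
#' Study-condition parameters for the synthetic cohort generator. The two
#' named groups reproduce the printed summary statistics of the evaluation
#' cohorts: `"children"` (n = 30, median hourly steps 320, mean hourly CV
#' 50%) and `"adults"` (n = 49, median hourly steps 218, mean hourly CV
#' 140%).
#'
#' @param group `"children"`, `"adults"` or `"custom"`.
#' @param n Number of participants (defaulted by group).
#' @param median_hourly_steps Target cohort-pooled median of the hourly mean
#'   step values (defaulted by group).
#' @param cv Per-participant hourly coefficient of variation, the scale of
#'   the baseline noise (defaulted by group).
#' @param n_days Days per simulated baseline; default 9 (6 baseline days for
#'   a w = 3 detector plus 3 injection days).
#' @param active_hours Hours of day simulated; default the 18 waking hours.
#' @param sdlog_participant Log-scale SD of the participant-level activity
#'   factor of the profile generator.
#' @param sdlog_hour Log-scale SD of the participant-specific hour-of-day
#'   deviation around the shared diurnal template.
#' @param diurnal_shape Optional named vector of relative hour-of-day
#'   weights; defaults to the built-in diurnal template.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group = c("children", "adults", "custom"), n = NULL,
                        median_hourly_steps = NULL, cv = NULL, n_days = 9,
                        active_hours = 6:23, sdlog_participant = 0.4,
                        sdlog_hour = 0.25, diurnal_shape = NULL) {
  group <- match.arg(group)
  defaults <- switch(group,
    children = list(n = 30L, median = 320, cv = 0.5),
    adults = list(n = 49L, median = 218, cv = 1.4),
    custom = list(n = NULL, median = NULL, cv = NULL)
  )
  n <- as.integer(if (is.null(n)) defaults$n else n)
  median_hourly_steps <- if (is.null(median_hourly_steps)) defaults$median else median_hourly_steps
  cv <- if (is.null(cv)) defaults$cv else cv
  if (is.null(n) || is.na(n) || n < 0L) stop("`n` must be a non-negative integer", call. = FALSE)
  if (is.null(median_hourly_steps) || median_hourly_steps <= 0) {
    stop("`median_hourly_steps` must be positive", call. = FALSE)
  }
  if (is.null(cv) || cv < 0) stop("`cv` must be non-negative", call. = FALSE)
  active_hours <- sort(unique(as.integer(active_hours)))
  if (is.null(diurnal_shape)) diurnal_shape <- diurnal_template(active_hours)
  structure(
    list(group = group, n = n, median_hourly_steps = median_hourly_steps,
         cv = cv, n_days = as.integer(n_days), active_hours = active_hours,
         sdlog_participant = sdlog_participant, sdlog_hour = sdlog_hour,
         diurnal_shape = diurnal_shape),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %s: n = %d, target median %g steps/h, cv = %g, %d days x %d hours\n",
    x$group, x$n, x$median_hourly_steps, x$cv, x$n_days, length(x$active_hours)
  ))
  invisible(x)
}

#' Generate a surrogate cohort of participant profiles
#'
#' Draws per-participant hour-of-day mean step vectors from a right-skewed
#' (log-normal) model: a participant-level activity factor times a
#' participant-specific hour effect times a shared diurnal template. The
#' whole cohort is then rescaled so that the pooled median of all hourly
#' means equals the target cohort median exactly. Every profile carries the
#' cohort coefficient of variation.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed; when given, fixes all randomness of the
#'   draw. When `NULL` the current RNG state is used.
#' @return A list of [participant_profile][derive_profile()] objects with the
#'   spec attached as attribute `"spec"`.
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  H <- length(spec$active_hours)
  shape <- spec$diurnal_shape
  profiles <- vector("list", spec$n)
  raw <- matrix(NA_real_, spec$n, H)
  for (p in seq_len(spec$n)) {
    a <- stats::rnorm(1, 0, spec$sdlog_participant)
    b <- stats::rnorm(H, 0, spec$sdlog_hour)
    raw[p, ] <- shape * exp(a + b)
  }
  if (spec$n > 0L) {
    fac <- spec$median_hourly_steps / stats::median(raw)
    for (p in seq_len(spec$n)) {
      profiles[[p]] <- new_profile(
        sprintf("%s_%02d", spec$group, p),
        stats::setNames(raw[p, ] * fac, spec$active_hours),
        spec$cv
      )
    }
  }
  structure(profiles, spec = spec, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("<cohort> %s: %d participant profiles\n", spec$group, length(x)))
  invisible(x)
}

#' Build a noisy baseline series from a profile
#'
#' Replicates the participant's mean day `n_days` times and perturbs each
#' hour independently with Gaussian noise of SD `cv * hourly_mean`, emulating
#' natural day-to-day activity variability. Draws are zero-truncated
#' (negative values resampled, leaving no point mass at zero steps) and
#' rounded to whole steps; the baseline contains no deliberate behaviour
#' changes and no missing hours.
#'
#' @param profile A [participant_profile][derive_profile()].
#' @param n_days Number of replicated days.
#' @param start_day First calendar day of the series.
#' @return An [hourly_series()].
#' @export
build_baseline <- function(profile, n_days = 9,
                           start_day = as.Date("2021-11-01")) {
  stopifnot(inherits(profile, "participant_profile"))
  n_days <- as.integer(n_days)
  hours <- as.integer(names(profile$hourly_means))
  m <- unname(profile$hourly_means)
  H <- length(m)
  mu <- rep(m, each = n_days)
  sds <- rep(profile$cv * m, each = n_days)
  draw <- stats::rnorm(n_days * H, mu, sds)
  # zero-truncated: resample negative draws so that low-mean hours do not
  # acquire a point mass of zero-step hours (which would plant spurious
  # negative changes/habits in a baseline meant to contain none)
  bad <- which(draw < 0)
  while (length(bad) > 0L) {
    draw[bad] <- stats::rnorm(length(bad), mu[bad], sds[bad])
    bad <- bad[draw[bad] < 0]
  }
  V <- matrix(round(draw), n_days, H)
  hourly_series(V, start_day + seq_len(n_days) - 1L, hours, profile$id)
}

#' Specify an injected behaviour change or habit
#'
#' @param kind `"change"` (a single day) or `"habit"` (consecutive days with
#'   identical magnitude).
#' @param sign `"add"` (positive change) or `"remove"` (negative change;
#'   step counts are floored at zero).
#' @param magnitude Steps per hour added or removed.
#' @param hour Hour of day of the injection; defaults to 8 (08:00) for
#'   additions and 12 (noon) for removals, the times used in the evaluation
#'   design.
#' @param days Day indices into the target series; defaults to day 7 for a
#'   change and days 7-9 for a habit.
#' @return An object of class `injection_spec`.
#' @export
injection_spec <- function(kind = c("change", "habit"),
                           sign = c("add", "remove"), magnitude,
                           hour = NULL, days = NULL) {
  kind <- match.arg(kind)
  sign <- match.arg(sign)
  if (!is.numeric(magnitude) || length(magnitude) != 1L || magnitude < 0) {
    stop("`magnitude` must be a single non-negative number", call. = FALSE)
  }
  if (is.null(hour)) hour <- if (sign == "add") 8L else 12L
  if (is.null(days)) days <- if (kind == "change") 7L else 7:9
  structure(
    list(kind = kind, sign = sign, magnitude = magnitude,
         hour = as.integer(hour), days = as.integer(days)),
    class = "injection_spec"
  )
}

#' Inject a controlled behaviour change into a series
#'
#' Adds (or removes, floored at zero) a fixed number of steps at one clock
#' hour on the specified days; all other cells are untouched.
#'
#' @param series An [hourly_series()].
#' @param spec An [injection_spec()].
#' @return The modified [hourly_series()].
#' @export
inject_steps <- function(series, spec) {
  stopifnot(inherits(series, "hourly_series"), inherits(spec, "injection_spec"))
  j <- match(spec$hour, series$hours)
  if (is.na(j)) stop("injection hour outside the series grid", call. = FALSE)
  if (any(spec$days < 1L | spec$days > length(series$days))) {
    stop("injection day outside the series grid", call. = FALSE)
  }
  v <- series$values[spec$days, j]
  series$values[spec$days, j] <- if (spec$sign == "add") {
    v + spec$magnitude
  } else {
    pmax(0, v - spec$magnitude)
  }
  series
}
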