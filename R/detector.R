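#' Detector configuration
#'
#' Tuning parameters of the behaviour-change detector.
#'
#' @param w Rolling window width in days defining "recent behaviour" for both
#'   the mean profile and the IQR limits. Default 3.
#' @param k IQR multiplier of the outlier fences
#'   (`UL = p75 + k*IQR`, `LL = p25 - k*IQR`). Default 1.5, the conventional
#'   Tukey fence.
#' @param active_hours Hours of day pooled when computing the daily limits.
#'   Default 6:23, the 18 waking hours.
#' @param habit_min_days Total consecutive days (including the detection day)
#'   a change must persist to be confirmed as a habit. Default 3.
#' @param quantile_type Percentile definition passed to [stats::quantile()];
#'   the default 7 interpolates linearly between order statistics.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(w = 3, k = 1.5, active_hours = 6:23,
                            habit_min_days = 3, quantile_type = 7) {
  w <- as.integer(w)
  habit_min_days <- as.integer(habit_min_days)
  if (length(w) != 1L || is.na(w) || w < 1L) {
    stop("`w` must be a positive integer number of days", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stop("`k` must be a positive IQR multiplier", call. = FALSE)
  }
  active_hours <- sort(unique(as.integer(active_hours)))
  if (length(active_hours) == 0L || any(active_hours < 0L | active_hours > 23L)) {
    stop("`active_hours` must be hours of day in 0-23", call. = FALSE)
  }
  if (length(habit_min_days) != 1L || is.na(habit_min_days) || habit_min_days < 2L) {
    stop("`habit_min_days` must be at least 2", call. = FALSE)
  }
  structure(
    list(w = w, k = k, active_hours = active_hours,
         habit_min_days = habit_min_days, quantile_type = as.integer(quantile_type)),
    class = "detector_config"
  )
}

#' @export
print.detector_config <- function(x, ...) {
  cat(sprintf(
    "<detector_config> w = %d days, k = %.2f, active hours %02d-%02d, habit >= %d consecutive days\n",
    x$w, x$k, min(x$active_hours), max(x$active_hours), x$habit_min_days
  ))
  invisible(x)
}

#' Rolling mean step profile
#'
#' For each day `d` beyond the first `w` days and each hour `h`, the mean of
#' the step totals at hour `h` over the `w` days immediately preceding `d`.
#' The mean is undefined (`NA`) while the window has fewer than `w` prior days
#' or whenever any value in the window is missing.
#'
#' @param series An [hourly_series()].
#' @param cfg A [detector_config()].
#' @return Numeric matrix of the same shape as `series$values`.
#' @export
mean_profile <- function(series, cfg = detector_config()) {
  stopifnot(inherits(series, "hourly_series"))
  V <- series$values
  n <- nrow(V)
  w <- cfg$w
  P <- matrix(NA_real_, n, ncol(V), dimnames = dimnames(V))
  if (n > w) {
    for (d in (w + 1L):n) {
      P[d, ] <- colMeans(V[(d - w):(d - 1L), , drop = FALSE])  # NA propagates
    }
  }
  P
}

#' Hourly step differences from the rolling mean
#'
#' `DS[d, h] = S[d, h] - AvgSteps[d, h]`: positive when the participant did
#' more steps in that hour than their recent mean, negative when fewer.
#' Undefined where either operand is missing.
#'
#' @inheritParams mean_profile
#' @param profile Optionally a precomputed [mean_profile()] matrix.
#' @return Numeric matrix of signed steps/hour.
#' @export
step_differences <- function(series, cfg = detector_config(),
                             profile = mean_profile(series, cfg)) {
  series$values - profile
}

#' IQR outlier limits of a pool of step differences
#'
#' @param x Numeric pool of step differences. Any `NA` (or an empty pool)
#'   leaves the limits undefined.
#' @param k IQR multiplier.
#' @param quantile_type Percentile definition (see [stats::quantile()]).
#' @return Named vector `c(ll, ul, iqr)`.
#' @export
iqr_limits <- function(x, k = 1.5, quantile_type = 7) {
  if (length(x) == 0L || anyNA(x)) {
    return(c(ll = NA_real_, ul = NA_real_, iqr = NA_real_))
  }
  q <- stats::quantile(x, c(0.25, 0.75), type = quantile_type, names = FALSE)
  iqr <- q[2] - q[1]
  c(ll = q[1] - k * iqr, ul = q[2] + k * iqr, iqr = iqr)
}

#' Daily outlier limits from pooled hourly differences
#'
#' For each day `d`, pools the hourly step differences of the `w` preceding
#' days across the active hours (`w * length(active_hours)` values) and
#' derives the lower/upper fences `p25 - k*IQR` and `p75 + k*IQR`. Limits are
#' undefined whenever any value in the pool is undefined, in which case
#' detection is skipped for that whole day.
#'
#' @inheritParams mean_profile
#' @param diffs Optionally a precomputed [step_differences()] matrix.
#' @return A tibble with columns `day`, `ll`, `ul`, `iqr`.
#' @export
day_limits <- function(series, cfg = detector_config(),
                       diffs = step_differences(series, cfg)) {
  stopifnot(inherits(series, "hourly_series"))
  hcols <- which(series$hours %in% cfg$active_hours)
  n <- nrow(diffs)
  out <- matrix(NA_real_, n, 3L)
  for (d in seq_len(n)) {
    if (d <= cfg$w) next
    pool <- as.vector(diffs[(d - cfg$w):(d - 1L), hcols, drop = FALSE])
    out[d, ] <- iqr_limits(pool, cfg$k, cfg$quantile_type)
  }
  tibble::tibble(day = series$days, ll = out[, 1], ul = out[, 2], iqr = out[, 3])
}

#' Classify step differences against daily limits
#'
#' Strict comparisons: a difference above the upper limit is a `"Positive"`
#' behaviour change, below the lower limit `"Negative"`, otherwise `"None"`.
#' A difference exactly on a limit is not a change. Undefined inputs give
#' `NA`.
#'
#' @param ds Signed step differences (steps/hour).
#' @param ll,up Lower and upper limits, recycled along `ds`.
#' @return Character vector in `{"Positive", "Negative", "None", NA}`.
#' @export
classify_change <- function(ds, ll, up) {
  n <- max(length(ds), length(ll), length(up))
  ds <- rep_len(ds, n); ll <- rep_len(ll, n); up <- rep_len(up, n)
  out <- rep(NA_character_, n)
  def <- !is.na(ds) & !is.na(ll) & !is.na(up)
  out[def] <- "None"
  out[def & ds > up] <- "Positive"
  out[def & ds < ll] <- "Negative"
  out
}

#' Batch detection of behaviour changes and habits
#'
#' Replays the full hourly detection cycle over a series: rolling mean
#' profile, hourly differences, pooled moving-IQR limits, strict outlier
#' classification, and consecutive-outlier habit confirmation. Missing hours
#' and days with undefined limits are skipped and break any habit streak at
#' the affected hour.
#'
#' Each behaviour change opens a habit candidate whose mean profile and
#' limits are frozen at the detection hour; on each subsequent consecutive
#' day at the same clock hour, the difference from the frozen mean must stay
#' strictly beyond the frozen limit (same sign) for the streak to continue.
#' A streak reaching `habit_min_days` days (detection day included) is a
#' confirmed habit; its `last_day` extends while the streak continues and the
#' habit is finalised when the streak breaks or the series ends.
#'
#' @inheritParams mean_profile
#' @return A list with two tibbles:
#'   * `changes`: columns `day`, `hour`, `step_difference`, `type`
#'     (`"Positive"`/`"Negative"`), sorted by day then hour.
#'   * `habits`: columns `first_day`, `hour`, `last_day`, `type`, sorted by
#'     first day then hour.
#' @examples
#' # a flat 200-steps/hour week with one +800 spike on day 7 at 08:00
#' V <- matrix(200, 9, 4)
#' s <- hourly_series(V, as.Date("2021-11-01") + 0:8, 8:11)
#' s$values[7, 1] <- 1000
#' detect_batch(s, detector_config(active_hours = 8:11))$changes
#' @export
detect_batch <- function(series, cfg = detector_config()) {
  stopifnot(inherits(series, "hourly_series"))
  n <- length(series$days)
  if (n <= cfg$w) {
    stop(sprintf("series must span more than w days (w = %d, got %d)", cfg$w, n),
         call. = FALSE)
  }
  V <- series$values
  prof <- mean_profile(series, cfg)
  DS <- V - prof
  lim <- day_limits(series, cfg, DS)
  lim_ok <- !is.na(lim$ul)

  ch_d <- integer(); ch_j <- integer(); ch_ds <- numeric(); ch_ty <- character()
  for (d in seq_len(n)) {
    if (!lim_ok[d]) next
    for (j in seq_along(series$hours)) {
      ds <- DS[d, j]
      if (is.na(ds)) next
      ty <- if (ds > lim$ul[d]) "Positive" else if (ds < lim$ll[d]) "Negative" else NA_character_
      if (!is.na(ty)) {
        ch_d <- c(ch_d, d); ch_j <- c(ch_j, j); ch_ds <- c(ch_ds, ds); ch_ty <- c(ch_ty, ty)
      }
    }
  }

  hb_first <- integer(); hb_j <- integer(); hb_last <- integer(); hb_ty <- character()
  for (i in seq_along(ch_d)) {
    d0 <- ch_d[i]; j <- ch_j[i]; ty <- ch_ty[i]
    frozen_mean <- prof[d0, j]
    frozen_ul <- lim$ul[d0]; frozen_ll <- lim$ll[d0]
    streak <- 1L; last <- d0; dd <- d0 + 1L
    while (dd <= n) {
      s <- V[dd, j]
      if (is.na(s) || !lim_ok[dd]) break    # missing hour or skipped day
      dsp <- s - frozen_mean
      ok <- if (ty == "Positive") dsp > frozen_ul else dsp < frozen_ll
      if (!ok) break
      streak <- streak + 1L; last <- dd; dd <- dd + 1L
    }
    if (streak >= cfg$habit_min_days) {
      hb_first <- c(hb_first, d0); hb_j <- c(hb_j, j)
      hb_last <- c(hb_last, last); hb_ty <- c(hb_ty, ty)
    }
  }

  list(
    changes = tibble::tibble(
      day = series$days[ch_d],
      hour = series$hours[ch_j],
      step_difference = ch_ds,
      type = ch_ty
    ),
    habits = tibble::tibble(
      first_day = series$days[hb_first],
      hour = series$hours[hb_j],
      last_day = series$days[hb_last],
      type = hb_ty
    )
  )
}
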