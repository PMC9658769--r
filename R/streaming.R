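#' Streaming detector state
#'
#' Mutable state for the hour-by-hour detection cycle. Feed hours in
#' chronological order with [run_cycle()] and collect the accumulated event
#' tables with [finalize_detector()]. Replaying a whole series through the
#' streaming cycle yields exactly the events of [detect_batch()].
#'
#' @param cfg A [detector_config()].
#' @return An environment of class `detector_state`.
#' @export
detector_state <- function(cfg = detector_config()) {
  stopifnot(inherits(cfg, "detector_config"))
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st$values <- list()   # day key -> named numeric vector (hour -> steps)
  st$ds <- list()       # day key -> named numeric vector (hour -> DS)
  st$limits <- list()   # day key -> c(ll, ul, iqr), cached once per day
  st$first_day <- NA_integer_
  st$last_day <- NA_integer_
  st$last_hour <- NA_integer_
  st$cands <- list()
  st$changes <- list()
  st$habits <- list()
  st$finalized <- FALSE
  class(st) <- c("detector_state", "environment")
  st
}

#' Run one hourly detection cycle
#'
#' Processes a single new hour of data: updates habit candidates tracked at
#' this clock hour, then classifies the hour's step difference against the
#' day's pooled-IQR limits, opening a new habit candidate for every detected
#' change. A missing value, or a day whose limit pool is incomplete, skips
#' detection for the hour and closes any habit candidate tracked at it.
#'
#' @param state A [detector_state()].
#' @param day Calendar day of the observation (`Date` or coercible).
#' @param hour Hour of day, 0-23.
#' @param steps Step total for the hour, or `NA` when the hour is missing.
#' @return Invisibly, a list with `change` (a one-row tibble or `NULL`) and
#'   `habits` (habit events finalised during this cycle).
#' @export
run_cycle <- function(state, day, hour, steps) {
  stopifnot(inherits(state, "detector_state"))
  if (state$finalized) stop("detector state has been finalized", call. = FALSE)
  cfg <- state$cfg
  d <- as.integer(as.Date(day))
  h <- as.integer(hour)
  if (!is.na(state$last_day) &&
      (d < state$last_day || (d == state$last_day && h <= state$last_hour))) {
    stop("run_cycle called out of chronological order", call. = FALSE)
  }
  state$last_day <- d; state$last_hour <- h
  if (is.na(state$first_day)) state$first_day <- d

  s <- if (length(steps) != 1L || is.na(steps)) NA_real_ else as.numeric(steps)
  if (!is.na(s) && s < 0) stop("step counts must be non-negative", call. = FALSE)
  key <- as.character(d)
  hk <- as.character(h)
  v <- state$values[[key]]
  if (is.null(v)) v <- numeric(0)
  v[hk] <- s
  state$values[[key]] <- v

  # Step 1: rolling mean over the w days preceding d at this hour
  avg <- NA_real_
  if (d - state$first_day >= cfg$w) {
    prev <- vapply((d - cfg$w):(d - 1L), function(i) {
      vi <- state$values[[as.character(i)]]
      if (is.null(vi) || !(hk %in% names(vi))) NA_real_ else vi[[hk]]
    }, numeric(1))
    if (!anyNA(prev)) avg <- mean(prev)
  }
  # Step 2: hourly difference
  dsv <- if (!is.na(s) && !is.na(avg)) s - avg else NA_real_
  dv <- state$ds[[key]]
  if (is.null(dv)) dv <- numeric(0)
  dv[hk] <- dsv
  state$ds[[key]] <- dv

  # Step 3: daily limits from the pooled DS of the previous w days
  lim <- streaming_limits(state, d)
  lim_ok <- !is.na(lim[["ul"]])

  change <- NULL
  emitted <- list()
  if (is.na(s) || !lim_ok) {
    emitted <- close_candidates(state, at_hour = h)
  } else {
    # Step 5 (continuation): candidates tracked at this clock hour
    keep <- rep(TRUE, length(state$cands))
    for (i in seq_along(state$cands)) {
      cd <- state$cands[[i]]
      if (cd$hour != h) next
      if (d == cd$last_day + 1L) {
        dsp <- s - cd$frozen_mean
        ok <- if (cd$type == "Positive") dsp > cd$frozen_ul else dsp < cd$frozen_ll
        if (ok) {
          cd$streak <- cd$streak + 1L
          cd$last_day <- d
          state$cands[[i]] <- cd
        } else {
          emitted <- c(emitted, emit_if_confirmed(state, cd))
          keep[i] <- FALSE
        }
      } else if (d > cd$last_day + 1L) {  # a day was skipped: non-consecutive
        emitted <- c(emitted, emit_if_confirmed(state, cd))
        keep[i] <- FALSE
      }
    }
    state$cands <- state$cands[keep]

    # Step 4: classification, opening a fresh candidate on detection
    if (!is.na(dsv)) {
      ty <- if (dsv > lim[["ul"]]) "Positive"
            else if (dsv < lim[["ll"]]) "Negative"
            else NA_character_
      if (!is.na(ty)) {
        change <- tibble::tibble(
          day = as.Date(d, origin = "1970-01-01"), hour = h,
          step_difference = dsv, type = ty
        )
        state$changes[[length(state$changes) + 1L]] <-
          list(day = d, hour = h, step_difference = dsv, type = ty)
        state$cands[[length(state$cands) + 1L]] <- list(
          hour = h, origin = d, last_day = d, streak = 1L, type = ty,
          frozen_mean = avg, frozen_ul = lim[["ul"]], frozen_ll = lim[["ll"]]
        )
      }
    }
  }
  invisible(list(change = change, habits = emitted))
}

streaming_limits <- function(state, d) {
  key <- as.character(d)
  cached <- state$limits[[key]]
  if (!is.null(cached)) return(cached)
  cfg <- state$cfg
  hk <- as.character(cfg$active_hours)
  pool <- unlist(lapply((d - cfg$w):(d - 1L), function(i) {
    di <- state$ds[[as.character(i)]]
    if (is.null(di)) rep(NA_real_, length(hk)) else unname(di[hk])
  }))
  lim <- iqr_limits(pool, cfg$k, cfg$quantile_type)
  state$limits[[key]] <- lim
  lim
}

emit_if_confirmed <- function(state, cd) {
  if (cd$streak < state$cfg$habit_min_days) return(list())
  ev <- list(first_day = cd$origin, hour = cd$hour, last_day = cd$last_day,
             type = cd$type)
  state$habits[[length(state$habits) + 1L]] <- ev
  list(ev)
}

close_candidates <- function(state, at_hour = NULL) {
  emitted <- list()
  keep <- rep(TRUE, length(state$cands))
  for (i in seq_along(state$cands)) {
    cd <- state$cands[[i]]
    if (!is.null(at_hour) && cd$hour != at_hour) next
    emitted <- c(emitted, emit_if_confirmed(state, cd))
    keep[i] <- FALSE
  }
  state$cands <- state$cands[keep]
  emitted
}

#' Finalise a streaming detector
#'
#' Closes all open habit candidates (a streak cut short by the end of the
#' stream still counts if it already reached `habit_min_days`) and returns
#' the accumulated event tables in the [detect_batch()] layout.
#'
#' @param state A [detector_state()].
#' @return A list with tibbles `changes` and `habits`.
#' @export
finalize_detector <- function(state) {
  stopifnot(inherits(state, "detector_state"))
  if (!state$finalized) {
    close_candidates(state)
    state$finalized <- TRUE
  }
  chg <- state$changes
  hbs <- state$habits
  changes <- tibble::tibble(
    day = as.Date(vapply(chg, `[[`, numeric(1), "day"), origin = "1970-01-01"),
    hour = vapply(chg, `[[`, integer(1), "hour"),
    step_difference = vapply(chg, `[[`, numeric(1), "step_difference"),
    type = vapply(chg, `[[`, character(1), "type")
  )
  habits <- tibble::tibble(
    first_day = as.Date(vapply(hbs, `[[`, integer(1), "first_day"), origin = "1970-01-01"),
    hour = vapply(hbs, `[[`, integer(1), "hour"),
    last_day = as.Date(vapply(hbs, `[[`, integer(1), "last_day"), origin = "1970-01-01"),
    type = vapply(hbs, `[[`, character(1), "type")
  )
  ord <- order(changes$day, changes$hour)
  changes <- changes[ord, ]
  ord <- order(habits$first_day, habits$hour)
  habits <- habits[ord, ]
  list(changes = changes, habits = habits)
}

#' Stream a whole series through the hourly cycle
#'
#' Convenience replay of [run_cycle()] over every grid cell of a series in
#' chronological order, followed by [finalize_detector()].
#'
#' @inheritParams mean_profile
#' @return A list with tibbles `changes` and `habits`.
#' @export
detect_stream <- function(series, cfg = detector_config()) {
  stopifnot(inherits(series, "hourly_series"))
  st <- detector_state(cfg)
  for (d in seq_along(series$days)) {
    for (j in seq_along(series$hours)) {
      run_cycle(st, series$days[d], series$hours[j], series$values[d, j])
    }
  }
  finalize_detector(st)
}
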