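# Independent brute-force reimplementation of the detection rules, written
# as naive loops with its own percentile routine. Shares no code with the
# package; used as the oracle in equivalence tests.

oracle_pctl <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  pos <- (n - 1) * p + 1
  lo <- floor(pos)
  hi <- ceiling(pos)
  x[lo] + (pos - lo) * (x[hi] - x[lo])
}

oracle_detect <- function(V, hours, w = 3, k = 1.5, active_hours = 6:23,
                          habit_min = 3) {
  n <- nrow(V)
  nh <- ncol(V)
  avg <- matrix(NA_real_, n, nh)
  ds <- matrix(NA_real_, n, nh)
  for (d in seq_len(n)) {
    for (j in seq_len(nh)) {
      if (d > w) {
        win <- V[(d - w):(d - 1), j]
        if (!anyNA(win)) avg[d, j] <- sum(win) / w
      }
      if (!is.na(V[d, j]) && !is.na(avg[d, j])) ds[d, j] <- V[d, j] - avg[d, j]
    }
  }
  act <- which(hours %in% active_hours)
  ll <- ul <- rep(NA_real_, n)
  for (d in seq_len(n)) {
    if (d <= w) next
    pool <- c()
    ok <- TRUE
    for (i in (d - w):(d - 1)) {
      for (j in act) {
        if (is.na(ds[i, j])) ok <- FALSE else pool <- c(pool, ds[i, j])
      }
    }
    if (ok && length(pool) > 0) {
      q1 <- oracle_pctl(pool, 0.25)
      q3 <- oracle_pctl(pool, 0.75)
      ll[d] <- q1 - k * (q3 - q1)
      ul[d] <- q3 + k * (q3 - q1)
    }
  }
  changes <- data.frame(day = integer(), hour = integer(),
                        step_difference = numeric(), type = character())
  habits <- data.frame(first_day = integer(), hour = integer(),
                       last_day = integer(), type = character())
  for (d in seq_len(n)) {
    if (is.na(ul[d])) next
    for (j in seq_len(nh)) {
      if (is.na(ds[d, j])) next
      ty <- NA_character_
      if (ds[d, j] > ul[d]) ty <- "Positive"
      if (ds[d, j] < ll[d]) ty <- "Negative"
      if (is.na(ty)) next
      changes <- rbind(changes, data.frame(
        day = d, hour = hours[j], step_difference = ds[d, j], type = ty))
      # follow the frozen limits forward on consecutive days
      streak <- 1
      last <- d
      dd <- d + 1
      while (dd <= n) {
        if (is.na(V[dd, j]) || is.na(ul[dd])) break
        dsp <- V[dd, j] - avg[d, j]
        good <- if (ty == "Positive") dsp > ul[d] else dsp < ll[d]
        if (!good) break
        streak <- streak + 1
        last <- dd
        dd <- dd + 1
      }
      if (streak >= habit_min) {
        habits <- rbind(habits, data.frame(
          first_day = d, hour = hours[j], last_day = last, type = ty))
      }
    }
  }
  list(changes = changes, habits = habits)
}

# normalise package output to the oracle's day-index representation
as_oracle_events <- function(res, series) {
  ch <- data.frame(day = match(res$changes$day, series$days),
                   hour = res$changes$hour,
                   step_difference = res$changes$step_difference,
                   type = res$changes$type)
  hb <- data.frame(first_day = match(res$habits$first_day, series$days),
                   hour = res$habits$hour,
                   last_day = match(res$habits$last_day, series$days),
                   type = res$habits$type)
  rownames(ch) <- rownames(hb) <- NULL
  list(changes = ch, habits = hb)
}
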