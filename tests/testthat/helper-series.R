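# fixture builders: small hourly series assembled in code

make_series <- function(values, hours = 6:(5 + ncol(as.matrix(values))),
                        start = as.Date("2021-11-01"), id = "p1") {
  values <- as.matrix(values)
  hourly_series(values, start + seq_len(nrow(values)) - 1L, hours, id)
}

# random integer series with optional missing hours
random_series <- function(n_days, hours, miss_prob = 0, max_steps = 500) {
  V <- matrix(sample(0:max_steps, n_days * length(hours), replace = TRUE),
              n_days, length(hours))
  if (miss_prob > 0) {
    V[stats::runif(length(V)) < miss_prob] <- NA_real_
  }
  make_series(V, hours)
}

# per-minute sample stream for one day covering the given hours
minute_stream <- function(day = as.Date("2021-11-01"), hours = 8,
                          steps_per_min = 5, minutes = 0:59) {
  ts <- as.POSIXct(paste(day, "00:00:00"), tz = "UTC")
  grid <- expand.grid(min = minutes, hour = hours)
  data.frame(
    timestamp = ts + grid$hour * 3600 + grid$min * 60,
    steps = rep_len(steps_per_min, nrow(grid))
  )
}
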