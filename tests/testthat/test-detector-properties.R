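test_that("batch detection matches the brute-force oracle on random series", {
  set.seed(4021)
  for (i in 1:25) {
    n_days <- sample(5:10, 1)
    hours <- 8:11
    w <- sample(2:3, 1)
    hmin <- sample(2:3, 1)
    s <- random_series(n_days, hours, miss_prob = c(0, 0.1)[1 + (i %% 2)])
    cfg <- detector_config(w = w, active_hours = hours, habit_min_days = hmin)
    got <- as_oracle_events(detect_batch(s, cfg), s)
    want <- oracle_detect(s$values, hours, w = w, active_hours = hours,
                          habit_min = hmin)
    expect_equal(got$changes, want$changes, ignore_attr = TRUE)
    expect_equal(got$habits, want$habits, ignore_attr = TRUE)
  }
})

test_that("hour-by-hour streaming reproduces batch detection exactly", {
  set.seed(991)
  for (i in 1:15) {
    s <- random_series(sample(4:10, 1), 6:10, miss_prob = 0.15)
    cfg <- detector_config(w = sample(2:3, 1), active_hours = 6:10,
                           habit_min_days = 2)
    batch <- detect_batch(s, cfg)
    stream <- detect_stream(s, cfg)
    expect_equal(as.data.frame(stream$changes), as.data.frame(batch$changes))
    expect_equal(as.data.frame(stream$habits), as.data.frame(batch$habits))
  }
})

test_that("detection is invariant to adding a constant to every hour", {
  set.seed(77)
  s <- random_series(9, 6:9, miss_prob = 0.05)
  cfg <- detector_config(w = 3, active_hours = 6:9, habit_min_days = 2)
  base <- detect_batch(s, cfg)
  shifted <- s
  shifted$values <- s$values + 250
  res <- detect_batch(shifted, cfg)
  expect_equal(res$changes, base$changes)
  expect_equal(res$habits, base$habits)
})

test_that("detection is equivariant to positive rescaling of every hour", {
  set.seed(78)
  s <- random_series(9, 6:9, miss_prob = 0.05)
  cfg <- detector_config(w = 3, active_hours = 6:9, habit_min_days = 2)
  base <- detect_batch(s, cfg)
  scaled <- s
  scaled$values <- s$values * 3
  res <- detect_batch(scaled, cfg)
  expect_equal(res$changes$day, base$changes$day)
  expect_equal(res$changes$hour, base$changes$hour)
  expect_equal(res$changes$type, base$changes$type)
  expect_equal(res$changes$step_difference, 3 * base$changes$step_difference)
  expect_equal(res$habits, base$habits)
  lim <- day_limits(s, cfg)
  lim3 <- day_limits(scaled, cfg)
  expect_equal(lim3$ul, 3 * lim$ul)
  expect_equal(lim3$ll, 3 * lim$ll)
})

test_that("every habit originates from a change event of the same direction", {
  set.seed(402)
  for (i in 1:10) {
    s <- random_series(10, 7:10, miss_prob = 0.1)
    cfg <- detector_config(w = 2, active_hours = 7:10, habit_min_days = 2)
    res <- detect_batch(s, cfg)
    if (nrow(res$habits) == 0) next
    key_h <- paste(res$habits$first_day, res$habits$hour, res$habits$type)
    key_c <- paste(res$changes$day, res$changes$hour, res$changes$type)
    expect_true(all(key_h %in% key_c))
    expect_true(all(res$habits$last_day >= res$habits$first_day +
                      (cfg$habit_min_days - 1)))
  }
})

test_that("no event is emitted in the first w days or on days with an incomplete pool", {
  set.seed(55)
  for (i in 1:10) {
    s <- random_series(9, 6:8, miss_prob = 0.2)
    cfg <- detector_config(w = 3, active_hours = 6:8)
    lim <- day_limits(s, cfg)
    res <- detect_batch(s, cfg)
    expect_true(all(res$changes$day %in% lim$day[!is.na(lim$ul)]))
    expect_false(any(res$changes$day <= s$days[cfg$w]))
    # missing hours never carry events
    miss <- which(is.na(s$values), arr.ind = TRUE)
    if (nrow(miss) > 0) {
      key_m <- paste(s$days[miss[, 1]], s$hours[miss[, 2]])
      expect_false(any(paste(res$changes$day, res$changes$hour) %in% key_m))
    }
  }
})
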