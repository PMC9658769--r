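test_that("the rolling mean covers the w preceding days and propagates missingness", {
  V <- matrix(c(100, 200, 300, 0), 4, 1)
  s <- make_series(V, hours = 8)
  cfg <- detector_config(w = 3, active_hours = 8)
  P <- mean_profile(s, cfg)
  expect_true(all(is.na(P[1:3, ])))
  expect_equal(P[4, 1][[1]], 200)

  s$values[2, 1] <- NA
  expect_true(is.na(mean_profile(s, cfg)[4, 1]))

  # constant series: mean profile equals the constant wherever defined
  sc <- make_series(matrix(7, 6, 3), hours = 8:10)
  Pc <- mean_profile(sc, detector_config(w = 3, active_hours = 8:10))
  expect_true(all(Pc[4:6, ] == 7))
})

test_that("step differences subtract the rolling mean and propagate missingness", {
  V <- matrix(c(100, 200, 300, 1000), 4, 1)
  s <- make_series(V, hours = 8)
  cfg <- detector_config(w = 3, active_hours = 8)
  D <- step_differences(s, cfg)
  expect_equal(D[4, 1][[1]], 800)
  s$values[4, 1] <- NA
  expect_true(is.na(step_differences(s, cfg)[4, 1]))
  sc <- make_series(matrix(50, 5, 2), hours = 8:9)
  Dc <- step_differences(sc, detector_config(w = 3))
  expect_true(all(Dc[4:5, ] == 0))
})

test_that("IQR limits match hand-computed percentiles and scale with the pool", {
  lim <- iqr_limits(c(-20, -10, 0, 10, 20, 30), k = 1.5)
  expect_equal(unname(lim), c(-45, 55, 25))

  # degenerate pool: zero spread collapses both limits onto the value
  lim0 <- iqr_limits(rep(4, 10), k = 1.5)
  expect_equal(unname(lim0), c(4, 4, 0))

  # positive homogeneity
  x <- c(-31, -5, 2, 8, 40, 100, 7)
  expect_equal(unname(iqr_limits(3 * x)), 3 * unname(iqr_limits(x)))

  # any missing value leaves the limits undefined
  expect_true(all(is.na(iqr_limits(c(1, NA, 3)))))
})

test_that("daily limits pool all active hours of the preceding w days", {
  set.seed(5)
  s <- random_series(7, 6:9)
  cfg <- detector_config(w = 3, active_hours = 6:9)
  D <- step_differences(s, cfg)
  lim <- day_limits(s, cfg, D)
  expect_true(all(is.na(lim$ul[1:6])))  # pool includes undefined DS until day 7
  pool <- as.vector(D[4:6, ])
  expect_equal(lim$ul[7], unname(iqr_limits(pool)["ul"]))
  expect_equal(lim$ll[7], unname(iqr_limits(pool)["ll"]))
  expect_true(all(lim$ll <= lim$ul, na.rm = TRUE))
})

test_that("classification is strict: boundary differences are not changes", {
  expect_equal(classify_change(c(800, 0, -956), ll = -45, up = 55),
               c("Positive", "None", "Negative"))
  expect_equal(classify_change(c(55, -45), ll = -45, up = 55), c("None", "None"))
  expect_true(is.na(classify_change(NA_real_, -45, 55)))
})

test_that("a single spike over a flat baseline is detected exactly once as positive", {
  s <- make_series(matrix(200, 9, 4), hours = 8:11)
  s$values[7, 1] <- 1000
  res <- detect_batch(s, detector_config(w = 3, active_hours = 8:11))
  pos <- res$changes[res$changes$type == "Positive", ]
  expect_equal(nrow(pos), 1L)
  expect_equal(pos$day, s$days[7])
  expect_equal(pos$hour, 8L)
  expect_equal(pos$step_difference, 800)
})

test_that("a sustained spike is confirmed as a habit against the frozen limits", {
  s <- make_series(matrix(200, 9, 4), hours = 8:11)
  s$values[7:9, 1] <- c(1000, 900, 850)   # DS' = 700, 650 vs frozen UL = 0
  res <- detect_batch(s, detector_config(w = 3, active_hours = 8:11))
  hb <- res$habits[res$habits$type == "Positive", ]
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$first_day, s$days[7])
  expect_equal(hb$hour, 8L)
  expect_equal(hb$last_day, s$days[9])
})

test_that("a streak broken on the first follow-up yields no habit", {
  s <- make_series(matrix(200, 9, 4), hours = 8:11)
  s$values[7, 1] <- 1000
  s$values[8, 1] <- 210    # DS' = 10, inside the frozen limits
  res <- detect_batch(s, detector_config(w = 3, active_hours = 8:11))
  expect_equal(nrow(res$habits), 0L)
})

test_that("a missing follow-up hour breaks the habit streak", {
  s <- make_series(matrix(200, 9, 4), hours = 8:11)
  s$values[7, 1] <- 1000
  s$values[8, 1] <- NA
  s$values[9, 1] <- 1000
  res <- detect_batch(s, detector_config(w = 3, active_hours = 8:11,
                                         habit_min_days = 2))
  expect_false(any(res$habits$first_day == s$days[7] & res$habits$last_day == s$days[9]))
})

test_that("short, all-missing and zero-variance series produce no events", {
  expect_error(detect_batch(make_series(matrix(1, 3, 2), hours = 8:9)),
               "more than w days")
  s_na <- make_series(matrix(NA_real_, 9, 3), hours = 8:10)
  res <- detect_batch(s_na, detector_config(active_hours = 8:10))
  expect_equal(nrow(res$changes), 0L)
  expect_equal(nrow(res$habits), 0L)
  s_const <- make_series(matrix(300, 9, 3), hours = 8:10)
  res <- detect_batch(s_const, detector_config(active_hours = 8:10))
  expect_equal(nrow(res$changes), 0L)
})

test_that("streaming cycles enforce chronological order and finalisation", {
  st <- detector_state(detector_config(active_hours = 8:9))
  run_cycle(st, "2021-11-01", 8, 100)
  run_cycle(st, "2021-11-01", 9, 100)
  expect_error(run_cycle(st, "2021-11-01", 8, 100), "order")
  expect_error(run_cycle(st, "2021-10-31", 9, 100), "order")
  res <- finalize_detector(st)
  expect_named(res, c("changes", "habits"))
  expect_error(run_cycle(st, "2021-11-02", 8, 100), "finalized")
})
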