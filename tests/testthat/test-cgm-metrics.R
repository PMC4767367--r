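test_that("window means handle constants, contrasts and the window gap", {
  const <- make_daily_series(rep(5, 288), 3)
  for (w in default_windows()) expect_equal(window_mean(const, w), 5)

  # nocturnal slots at 4, everything else at 6
  day <- rep(6, 288)
  day[(180 / 5 + 1):(360 / 5)] <- 4
  s <- make_daily_series(day, 3)
  expect_equal(window_mean(s, clock_window(3, 6)), 4)
  expect_equal(window_mean(s, clock_window(6, 24)), 6)
  # 00:00-03:00 belongs to neither analysis window
  wins <- default_windows()
  noct_n <- sum(s$clock_min >= 180 & s$clock_min < 360)
  diur_n <- sum(s$clock_min >= 360)
  expect_equal(noct_n + diur_n, 3 * 288 - 3 * 36)

  # midnight-wrapping window
  expect_equal(window_mean(s, clock_window(22, 2)), 6)
})

test_that("window mean respects the coverage threshold", {
  day <- rep(5.5, 288)
  s <- make_daily_series(day, 3)
  # knock out half the nocturnal slots -> below 70% coverage
  noct <- which(s$clock_min >= 180 & s$clock_min < 360)
  s$glucose[noct[seq(1, length(noct), by = 2)]] <- NA
  expect_message(
    res <- window_mean(s, clock_window(3, 6)),
    "coverage")
  expect_true(is.na(res))
  expect_equal(window_mean(s, clock_window(3, 6), min_coverage = 0.4), 5.5)
})

test_that("sd_24h matches hand values and the per-day variant", {
  expect_equal(sd_24h(make_series(c(4, 5, 6))), 1)
  expect_equal(sd_24h(make_daily_series(rep(5, 288), 3)), 0)
  expect_true(is.na(sd_24h(make_series(c(5, NA, NA)))))

  # per-day average of identical days equals the daily SD, which is below
  # the pooled SD when days differ in level
  day1 <- rep(c(4, 6), 144)
  s <- make_series(c(day1, day1 + 2), interval = 5)
  expect_equal(sd_24h(s, per_day = TRUE), sd(day1))
  expect_gt(sd_24h(s), sd_24h(s, per_day = TRUE))
})

test_that("conga reproduces the hand-computed lag-2 golden value", {
  s <- make_series(c(5, 6, 5, 7, 6), interval = 60)
  # differences at lag 2 h: 0, 1, 1 -> SD = 0.5774
  expect_equal(conga(s, lag_hours = 2), sd(c(0, 1, 1)))
  expect_equal(round(conga(s, lag_hours = 2), 4), 0.5774)
  expect_equal(conga(make_daily_series(rep(5, 288), 3)), 0)
  # missing partner pairs are skipped; a single surviving pair is not enough
  s2 <- make_series(c(5, 6, NA, 7, 6), interval = 60)
  expect_true(is.na(conga(s2, lag_hours = 2)))
  s3 <- make_series(c(5, 6, NA, 7, 6, 7), interval = 60)
  expect_equal(conga(s3, lag_hours = 2), sd(c(7 - 6, 7 - 7)))
})

test_that("conga agrees with a numeric oracle on a sampled 24-h sinusoid", {
  clock <- (0:863) * 5 / 60
  vals <- 6 + 1.5 * sin(2 * pi * clock / 24)
  s <- make_series(vals, interval = 5)
  d <- vals[49:864] - vals[1:816]
  expect_equal(conga(s, lag_hours = 4), sd(d), tolerance = 1e-12)
  # magnitude check against the analytic SD of a sinusoid difference:
  # current minus 4-h-lagged sinusoid has amplitude 2*A*sin(pi*4/24)
  expect_equal(conga(s, lag_hours = 4),
               2 * 1.5 * sin(pi * 4 / 24) / sqrt(2),
               tolerance = 0.05)
})

test_that("modd matches the two-day toy and identical-day cases", {
  s <- make_series(c(5, 6, 7, 5.5, 6.5, 6.5), interval = 480)
  expect_equal(modd(s), 0.5)
  same <- make_daily_series(rep(c(4, 7), 144), 2)
  expect_equal(modd(same), 0)
  # day pair with no overlapping valid slot -> missing
  v <- c(5, NA, NA, 6)
  expect_true(is.na(modd(make_series(v, interval = 720))))
})

test_that("glucose_range matches hand values", {
  expect_equal(glucose_range(make_series(c(3.9, 5.0, 8.9))), 5.0)
  expect_equal(glucose_range(make_daily_series(rep(5, 288), 3)), 0)
  v <- c(4, 9, NA, 5, 3.2)
  expect_equal(glucose_range(make_series(v)), naive_range(v))
})

test_that("trimming drops exactly the first and last calendar day", {
  s5 <- make_daily_series(rep(5, 288), 5)
  t5 <- trim_to_analysis_days(s5)
  expect_length(t5$glucose, 3 * 288)
  expect_equal(unique(t5$day_index), 1:3)
  expect_equal(format(t5$start, "%Y-%m-%d"), "2015-03-03")

  # idempotence on the retained span is not expected (it trims again), but
  # a 5-day trim equals trimming the days directly
  expect_equal(t5$glucose, s5$glucose[289:1152])

  # a mid-day start spans six calendar dates; trimming keeps the four
  # interior whole days
  s <- make_series(rep(5, 1440), interval = 5,
                   start = MIDNIGHT + 12 * 3600)
  tt <- trim_to_analysis_days(s)
  expect_equal(unique(format(series_times(tt), "%Y-%m-%d")),
               c("2015-03-03", "2015-03-04", "2015-03-05", "2015-03-06"))
  expect_length(tt$glucose, 4 * 288)

  expect_warning(t3 <- trim_to_analysis_days(make_daily_series(rep(5, 288), 3)),
                 "one analysis day")
  expect_length(t3$glucose, 288)
  expect_error(trim_to_analysis_days(make_daily_series(rep(5, 288), 2)),
               "insufficient monitoring data")
})

test_that("read_cgm_csv snaps, deduplicates, gap-fills and validates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant_id,timestamp,glucose",
    "A,2015-03-02T00:00:00,5.0",
    "A,2015-03-02T00:05:02,5.2",   # snaps to slot 1
    "A,2015-03-02T00:15:00,5.4",   # 10-min gap -> slot 2 missing
    "B,2015-03-02T00:00:00,6.0",
    "B,2015-03-02T00:05:00,6.1",
    "B,2015-03-02T00:10:00,6.2"), path)
  ser <- read_cgm_csv(path)
  expect_length(ser, 2)
  expect_equal(ser[["A"]]$glucose, c(5.0, 5.2, NA, 5.4))
  expect_equal(ser[["B"]]$glucose, c(6.0, 6.1, 6.2))

  # duplicate slot: first kept with warning
  writeLines(c(
    "participant_id,timestamp,glucose",
    "A,2015-03-02T00:00:00,5.0",
    "A,2015-03-02T00:00:30,9.9",
    "A,2015-03-02T00:05:00,5.2"), path)
  expect_warning(ser2 <- read_cgm_csv(path), "duplicate")
  expect_equal(ser2[["A"]]$glucose, c(5.0, 5.2))

  # out-of-range glucose dropped with warning; bad timestamp is fatal
  writeLines(c(
    "participant_id,timestamp,glucose",
    "A,2015-03-02T00:00:00,5.0",
    "A,2015-03-02T00:05:00,55.0"), path)
  expect_warning(ser3 <- read_cgm_csv(path), "outside")
  expect_equal(ser3[["A"]]$glucose, 5.0)
  writeLines(c(
    "participant_id,timestamp,glucose",
    "A,not-a-time,5.0"), path)
  expect_error(read_cgm_csv(path), "malformed timestamp.*1")
})

test_that("cgm_summary populates all fields and degrades gracefully", {
  const <- make_daily_series(rep(5, 288), 3)
  s <- cgm_summary(const)
  expect_equal(s$mean_24h, 5)
  expect_equal(s$mean_nocturnal, 5)
  expect_equal(s$mean_diurnal, 5)
  expect_equal(s$sd_24h, 0)
  expect_equal(s$conga4, 0)
  expect_equal(s$modd, 0)
  expect_equal(s$range, 0)
  expect_equal(s$n_valid_samples, 864L)
  expect_equal(s$fraction_missing, 0)

  # whole nocturnal window missing: that metric NA, the others present
  gap <- make_daily_series(rep(5, 288), 3)
  gap$glucose[gap$clock_min >= 180 & gap$clock_min < 360] <- NA
  expect_message(sg <- cgm_summary(gap), "coverage")
  expect_true(is.na(sg$mean_nocturnal))
  expect_false(is.na(sg$mean_24h))
  expect_false(is.na(sg$mean_diurnal))
  expect_false(is.na(sg$modd))
})

test_that("series constructor enforces the physiologic glucose range", {
  expect_error(make_series(c(5, 41)), "outside")
  expect_error(make_series(c(-1, 5)), "outside")
  expect_silent(make_series(c(NA, 5)))
})
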