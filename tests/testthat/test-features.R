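test_that("window statistics match hand-computed values", {
  t0 <- ts_utc("2019-03-05 09:10")
  st <- make_stream("P01", format(t0 - (9:0) * 60, "%Y-%m-%d %H:%M", tz = "UTC"),
                    heart_rate = rep(c(70, 90), each = 5))
  ws <- window_stats(st, t0, 10, "heart_rate")
  expect_equal(ws[["mean"]], 80)
  expect_equal(ws[["variance"]], 100)  # population variance
  expect_equal(ws[["coverage"]], 1)
  # sample variance alternative
  ws2 <- window_stats(st, t0, 10, "heart_rate", var_type = "sample")
  expect_equal(ws2[["variance"]], var(rep(c(70, 90), each = 5)))
})

test_that("windows are half-open (t - w, t]", {
  t0 <- ts_utc("2019-03-05 09:10")
  st <- make_stream("P01",
                    format(t0 - c(10, 9, 0) * 60, "%Y-%m-%d %H:%M", tz = "UTC"),
                    heart_rate = c(999, 70, 80))
  ws <- window_stats(st, t0, 10, "heart_rate", min_coverage = 0)
  # the minute exactly w before t is excluded, the task minute included
  expect_equal(ws[["mean"]], 75)
  expect_equal(ws[["coverage"]], 0.2)
})

test_that("low coverage yields missing statistics", {
  t0 <- ts_utc("2019-03-05 09:10")
  st <- make_stream("P01", format(t0 - (3:0) * 60, "%Y-%m-%d %H:%M", tz = "UTC"),
                    heart_rate = c(70, 72, 74, 76))
  ws <- window_stats(st, t0, 10, "heart_rate")
  expect_equal(ws[["coverage"]], 0.4)
  expect_true(is.na(ws[["mean"]]))
  expect_true(is.na(ws[["variance"]]))
})

test_that("a 60-minute mean is the coverage-weighted mean of its 10-minute parts", {
  set.seed(5)
  t0 <- ts_utc("2019-03-05 12:00")
  present <- sort(sample(0:59, 45))
  st <- make_stream("P01",
                    format(t0 - present * 60, "%Y-%m-%d %H:%M", tz = "UTC"),
                    heart_rate = round(rnorm(45, 75, 6)))
  w60 <- window_stats(st, t0, 60, "heart_rate")
  parts <- lapply(0:5, function(k)
    window_stats(st, t0 - k * 600, 10, "heart_rate", min_coverage = 0))
  ns <- vapply(parts, function(p) p[["coverage"]] * 10, 0)
  ms <- vapply(parts, function(p) p[["mean"]], 0)
  expect_equal(w60[["mean"]], sum(ns * ms, na.rm = TRUE) / sum(ns))
  expect_equal(w60[["coverage"]], sum(ns) / 60)
})

test_that("momentary_features agrees with window_stats and resolves current HR", {
  set.seed(9)
  t0 <- ts_utc("2019-03-05 08:00")
  n <- 360
  st <- rbind(
    make_stream("P01", format(t0 + (0:(n - 1)) * 60, "%Y-%m-%d %H:%M", tz = "UTC"),
                heart_rate = round(rnorm(n, 72, 5)),
                calories = round(runif(n, 1, 3), 2),
                steps = rpois(n, 4), distance = round(runif(n, 0, 0.1), 4),
                resting_hr = 64),
    make_stream("P02", format(t0 + (0:(n - 1)) * 60, "%Y-%m-%d %H:%M", tz = "UTC"),
                heart_rate = round(rnorm(n, 80, 5)),
                calories = 1.5, steps = 0, distance = 0, resting_hr = 71))
  tasks <- data.frame(participant_id = c("P01", "P01", "P02"),
                      timestamp = c(t0 + 90 * 60, t0 + 300 * 60, t0 + 200 * 60))
  mf <- momentary_features(tasks, st)
  for (i in seq_len(nrow(tasks))) {
    sub <- st[st$participant_id == tasks$participant_id[i], ]
    for (ch in c("heart_rate", "calories", "steps", "distance")) {
      for (w in c(10, 60)) {
        ws <- window_stats(sub, tasks$timestamp[i], w, ch)
        expect_equal(mf[[paste0(ch, "_mean_", w)]][i], unname(ws["mean"]))
        expect_equal(mf[[paste0(ch, "_var_", w)]][i], unname(ws["variance"]))
      }
    }
    # current HR is the stream value at the task minute
    expect_equal(mf$current_hr[i],
                 sub$heart_rate[sub$timestamp == tasks$timestamp[i]])
  }
  expect_equal(mf$resting_hr, c(64, 64, 71))
})

test_that("current HR falls back to the nearest minute within tolerance", {
  t0 <- ts_utc("2019-03-05 09:00")
  st <- make_stream("P01", format(t0 + c(0, 4, 30) * 60,
                                  "%Y-%m-%d %H:%M", tz = "UTC"),
                    heart_rate = c(70, 75, 90))
  tasks <- data.frame(participant_id = "P01",
                      timestamp = c(t0 + 3 * 60, t0 + 15 * 60))
  mf <- momentary_features(tasks, st)
  expect_equal(mf$current_hr[1], 75)        # 1 min away beats 3 min away
  expect_true(is.na(mf$current_hr[2]))      # nothing within 5 minutes
})
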