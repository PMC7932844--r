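# A seven-night construction with known chronotype arithmetic:
# five work nights of 420 min (mid-sleep 03:30) and two free nights of
# 540 min (mid-sleep 05:00). Then
#   MSF_uc = 05:00, SD_w = 420, SD_f = 540, SN = 3180/7 = 454.2857 min,
#   MSF = 5 - 0.5 * (540 - 454.2857)/60 = 4.2857143 h (04:17).
msf_example <- function() {
  work_dates <- as.Date("2019-03-05") + 0:4
  free_dates <- as.Date("2019-03-10") + 0:1
  sleep <- rbind(
    make_sleep("P01", paste(work_dates, "00:00"), paste(work_dates, "07:00")),
    make_sleep("P01", paste(free_dates, "00:30"), paste(free_dates, "09:30")))
  sleep <- finish_sleep(sleep)
  schedule <- make_schedule("P01", c(work_dates, free_dates),
                            rep(c("work", "free"), c(5, 2)))
  list(sleep = sleep, schedule = schedule)
}

test_that("mid-sleep handles sessions crossing midnight", {
  expect_equal(mid_sleep_time(ts_utc("2019-03-04 23:00"),
                              ts_utc("2019-03-05 07:00")), 3)
  expect_equal(mid_sleep_time(ts_utc("2019-03-05 01:00"),
                              ts_utc("2019-03-05 09:00")), 5)
  # day sleep after a night shift stays in the afternoon
  expect_equal(mid_sleep_time(ts_utc("2019-03-05 08:30"),
                              ts_utc("2019-03-05 15:30")), 12)
})

test_that("nightly_sessions keeps the longest session per wake date", {
  sleep <- suppressWarnings(make_sleep(
    "P01",
    c("2019-03-04 23:00", "2019-03-05 14:00"),
    c("2019-03-05 07:00", "2019-03-05 15:00")))
  nights <- nightly_sessions(sleep)
  expect_equal(nrow(nights), 1L)
  expect_equal(nights$duration, 480)
})

test_that("chronotype arithmetic matches the worked example", {
  ex <- msf_example()
  pr <- chronotype_msf(ex$sleep, ex$schedule)
  expect_equal(pr$msf_uc, 5)
  expect_equal(pr$mean_dur_work, 420)
  expect_equal(pr$mean_dur_free, 540)
  expect_equal(pr$sleep_need, 3180 / 7)
  expect_equal(pr$msf, 5 - 0.5 * (540 - 3180 / 7) / 60)
  expect_equal(format_hhmm(pr$msf), "04:17")
  expect_equal(pr$n_work, 5L)
  expect_equal(pr$n_free, 2L)
  # free-day oversleep always corrects MSF earlier
  expect_lt(pr$msf, pr$msf_uc)
  # the linear averaging alternative agrees here (all times on one side)
  pr_lin <- chronotype_msf(ex$sleep, ex$schedule, mean_method = "linear")
  expect_equal(pr_lin$msf, pr$msf)
})

test_that("chronotype is undefined without free-day nights", {
  ex <- msf_example()
  ex$schedule$day_type <- "work"
  expect_error(chronotype_msf(ex$sleep, ex$schedule), "chronotype undefined")
})

test_that("internal time re-anchors clock time at MSF", {
  expect_equal(internal_time(15 + 34 / 60, 4 + 1 / 60), 11 + 33 / 60)
  expect_equal(format_hhmm(internal_time(15 + 34 / 60, 4 + 1 / 60)), "11:33")
  expect_equal(internal_time(2, 5), 21)
  expect_equal(internal_time(ts_utc("2019-03-05 04:00"), 4), 0)
})

test_that("sleep shift is anchored on the wake date", {
  d <- as.Date("2019-03-05")
  # MSF 04:00 -> reference instant 04:00 on the wake date
  expect_equal(sleep_shift(ts_utc("2019-03-04 23:30"), ts_utc("2019-03-05 09:30"),
                           d, msf = 4), 30)
  expect_equal(sleep_shift(ts_utc("2019-03-04 22:00"), ts_utc("2019-03-05 08:00"),
                           d, msf = 4), -60)
  # late MSF (after noon) anchors on the evening before
  expect_equal(sleep_shift(ts_utc("2019-03-04 20:00"), ts_utc("2019-03-05 02:00"),
                           d, msf = 23), 0)
  # displaced day sleep can legitimately exceed 12 h of shift
  expect_equal(sleep_shift(ts_utc("2019-03-05 08:00"), ts_utc("2019-03-05 16:00"),
                           d, msf = 4), 8 * 60)
  # vectorised call: each night is anchored on its own wake date
  expect_equal(
    sleep_shift(ts_utc(c("2019-03-04 23:30", "2019-03-05 23:30")),
                ts_utc(c("2019-03-05 09:30", "2019-03-06 09:30")),
                as.Date(c("2019-03-05", "2019-03-06")), msf = 4),
    c(30, 30))
})

test_that("sleep need and debt satisfy the zero-mean identity", {
  snd <- sleep_need_and_debt(c(420, 420, 420, 420, 420, 540, 540))
  expect_equal(snd$sleep_need, 3180 / 7)
  expect_equal(snd$debt[1], 1 - 420 / (3180 / 7))
  expect_equal(snd$debt[6], 1 - 540 / (3180 / 7))
  expect_equal(mean(snd$debt), 0)
  set.seed(3)
  snd2 <- sleep_need_and_debt(runif(42, 300, 550))
  expect_lt(abs(mean(snd2$debt)), 1e-12)
  expect_error(sleep_need_and_debt(numeric(0)), "at least one")
})

test_that("night metrics assemble the per-night feature table", {
  ex <- msf_example()
  pr <- chronotype_msf(ex$sleep, ex$schedule)
  nm <- night_metrics(ex$sleep, pr)
  expect_equal(nrow(nm), 7L)
  expect_equal(mean(nm$sleep_debt), 0)
  expect_equal(nm$duration, ex$sleep$duration[order(ex$sleep$wake_date)])
  # work nights mid-sleep 03:30 vs MSF 04:17.14: shift = -47.142857 min
  work_shift <- (3.5 - pr$msf) * 60
  expect_equal(nm$sleep_shift[1], work_shift)
  expect_equal(nm$sleep_end[1], 7)
})

test_that("weekly aggregates impute missing nights with the running mean", {
  d0 <- as.Date("2019-03-05")
  sleep <- make_sleep("P01",
                      paste(c(d0, d0 + 1) - 1, "23:00"),
                      c(paste(d0, "05:40"), paste(d0 + 1, "06:20")))
  pr <- data.frame(participant_id = "P01", msf = 3, stringsAsFactors = FALSE)
  nm <- night_metrics(sleep, pr)
  expect_equal(nm$duration, c(400, 440))
  wk <- weekly_aggregates(nm, d0 + 6)
  # nights 3..7 are each imputed with mean(400, 440) = 420
  expect_equal(wk$imputed_nights, 5L)
  expect_equal(wk$wk_duration, 420)
  # no prior night available -> aggregate undefined
  wk0 <- weekly_aggregates(nm, d0 - 1)
  expect_true(is.na(wk0$wk_duration))
  expect_true(is.na(wk0$imputed_nights))
})

test_that("tasks link to the most recent prior night within the horizon", {
  d0 <- as.Date("2019-03-05")
  sleep <- make_sleep("P01",
                      paste(c(d0, d0 + 1) - 1, "23:00"),
                      paste(c(d0, d0 + 1), "07:00"))
  pr <- data.frame(participant_id = "P01", msf = 3, stringsAsFactors = FALSE)
  nm <- night_metrics(sleep, pr)
  expect_equal(link_previous_sleep(ts_utc("2019-03-05 09:00"), nm), 1L)
  expect_equal(link_previous_sleep(ts_utc("2019-03-06 08:00"), nm), 2L)
  # before any wake: no link
  expect_true(is.na(link_previous_sleep(ts_utc("2019-03-05 06:00"), nm)))
  # beyond the 36 h horizon of the last night: no link
  expect_true(is.na(link_previous_sleep(ts_utc("2019-03-08 12:00"), nm)))
  expect_equal(time_since_wake(ts_utc("2019-03-05 09:30"), nm), 150)
  expect_true(time_since_wake(ts_utc("2019-03-06 07:01"), nm) >= 0)
})

test_that("MSF is translation-equivariant under a rigid time shift", {
  ex <- msf_example()
  pr <- chronotype_msf(ex$sleep, ex$schedule)
  shifted <- ex$sleep
  shifted$start <- shifted$start + 3600
  shifted$end <- shifted$end + 3600
  shifted <- finish_sleep(shifted[, setdiff(names(shifted),
                                            c("wake_date", "stages_valid"))])
  pr2 <- chronotype_msf(shifted, ex$schedule)
  expect_equal(pr2$msf_uc, wrap24(pr$msf_uc + 1), tolerance = 1e-9)
  expect_equal(pr2$msf, wrap24(pr$msf + 1), tolerance = 1e-9)
  expect_equal(pr2$sleep_need, pr$sleep_need)
})
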