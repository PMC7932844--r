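test_that("the two-process components behave as specified", {
  # homeostatic buildup: monotone, bounded, continuous at the transition
  expect_equal(homeostatic_value(0, s0 = 0.3), 0.3)
  expect_lt(homeostatic_value(16 * 60, s0 = 0), 1)
  m <- homeostatic_value(seq(0, 1200, by = 10), s0 = 0.2)
  expect_true(all(diff(m) > 0))
  # recovery: exponential decay from the onset level
  expect_equal(homeostatic_recovery(0, s0 = 0.8), 0.8)
  expect_equal(homeostatic_recovery(4.2 * 60, s0 = 0.8), 0.8 * exp(-1))
  r <- homeostatic_recovery(seq(0, 600, by = 10), s0 = 0.9)
  expect_true(all(diff(r) < 0))
  # circadian component peaks exactly `offset` hours after MSF
  msf <- 4.25
  peak <- ts_utc("2019-03-05 00:00") + (msf + 13.5) * 3600
  expect_equal(circadian_value(peak, msf, amplitude = 3), 3, tolerance = 1e-9)
  expect_equal(circadian_value(peak + 12 * 3600, msf, amplitude = 3), -3,
               tolerance = 1e-9)
  expect_true(all(abs(circadian_value(runif(50, 0, 24), msf)) <= 1))
})

test_that("simulation is bit-for-bit reproducible for a given seed", {
  cfg <- small_sim_config()
  a <- simulate_cohort(cfg, seed = 7)
  b <- simulate_cohort(cfg, seed = 7)
  expect_identical(a$sleep, b$sleep)
  expect_identical(a$minutes, b$minutes)
  expect_identical(a$tasks, b$tasks)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(cfg, seed = 8)
  expect_false(identical(a$sleep, c2$sleep))
})

test_that("zeroed noise and couplings pin task outcomes at baseline", {
  cfg <- small_sim_config(
    coupling = c(sleep_duration = 0, rem_duration = 0, light_duration = 0,
                 sleep_shift = 0, sleep_end = 0, time_since_wake = 0,
                 hr = 0, activity = 0),
    circ_amplitude = 0, rrt_noise = 0, raa_noise = 0,
    m0_sd = 0, n0_sd = 0, pvt_stim_sd = 0, false_start_rate = 0)
  co <- simulate_cohort(cfg, seed = 3, with_streams = FALSE)
  expect_true(all(co$truth$mrt_target == 355))
  expect_true(all(co$truth$naa_target == 18))
  expect_true(all(co$tasks$add_attempts == 18L))
  mrt <- vapply(co$tasks$pvt, median_response_time, 0)
  expect_true(all(mrt == 355))
})

test_that("task batteries respect the minimum gap", {
  co <- simulate_cohort(small_sim_config(tasks_per_day = 5), seed = 4,
                        with_streams = FALSE)
  for (p in unique(co$tasks$participant_id)) {
    t <- sort(co$tasks$timestamp[co$tasks$participant_id == p])
    expect_true(all(diff(as.numeric(t)) / 60 >= 120))
  }
})

test_that("shift workers sleep at far more variable times than regular workers", {
  co <- simulate_cohort(sim_config(n_regular = 3, n_shift = 3, n_student = 0,
                                   days = 21), seed = 6, with_streams = FALSE)
  sd_shift <- tapply(co$truth$night_shift, co$truth$participant_id,
                     sd)[co$participants$participant_id]
  by_group <- tapply(sd_shift, co$participants$group, mean)
  expect_gt(by_group[["shift"]], 2 * by_group[["regular"]])
  # the shift group's schedule carries the worked shift type
  expect_true(all(is.na(co$schedule$shift_type[
    co$schedule$participant_id %in%
      co$participants$participant_id[co$participants$group == "regular"]])))
  expect_true(all(co$schedule$shift_type[
    co$schedule$participant_id %in%
      co$participants$participant_id[co$participants$group == "shift"]] %in%
      c("day", "evening", "night", "off")))
})

test_that("streams are physiologically coherent", {
  cfg <- sim_config(n_regular = 2, n_shift = 0, n_student = 0, days = 7)
  co <- simulate_cohort(cfg, seed = 5)
  st <- co$minutes
  # no steps while asleep
  for (i in seq_len(nrow(co$sleep))) {
    sl <- co$sleep[i, ]
    inside <- st$participant_id == sl$participant_id &
      st$timestamp >= sl$start & st$timestamp < sl$end
    expect_true(all(st$steps[inside] == 0))
  }
  expect_true(all(st$heart_rate >= 40 & st$heart_rate <= 190))
  expect_true(all(st$calories >= 0))
  # per-participant resting HR stays near its latent value
  for (k in seq_len(nrow(co$participants))) {
    pp <- co$participants[k, ]
    obs <- st$resting_hr[st$participant_id == pp$participant_id]
    expect_lt(abs(mean(obs) - pp$resting_hr), 1.5)
  }
})

test_that("simulated nights have plausible durations and stages", {
  co <- simulate_cohort(small_sim_config(), seed = 9,
                        with_streams = FALSE, with_tasks = FALSE)
  expect_true(all(co$sleep$duration >= 181 & co$sleep$duration <= 779))
  staged <- co$sleep[co$sleep$stages_valid, ]
  stage_sum <- staged$rem_min + staged$light_min + staged$deep_min +
    staged$awake_min
  expect_equal(stage_sum, staged$duration)
  expect_true(all(staged$rem_min > 0 & staged$light_min > 0 &
                    staged$deep_min > 0))
})

test_that("a written cohort reads back through the package formats", {
  co <- simulate_cohort(sim_config(n_regular = 2, n_shift = 1, n_student = 0,
                                   days = 7), seed = 10)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("tasks.jsonl", "sleep.csv", "minutes.csv", "schedule.csv", "truth.csv")))))
  tasks <- read_task_sessions(file.path(dir, "tasks.jsonl"))
  expect_equal(nrow(tasks), nrow(co$tasks))
  expect_equal(sort(tasks$timestamp), sort(co$tasks$timestamp))
  sleep <- read_sleep_sessions(file.path(dir, "sleep.csv"))
  expect_equal(sleep$duration, co$sleep$duration)
  expect_equal(sleep$wake_date, co$sleep$wake_date)
  sched <- read_schedule(file.path(dir, "schedule.csv"))
  expect_equal(nrow(sched), nrow(co$schedule))
  minutes <- read_minute_stream(file.path(dir, "minutes.csv"))
  expect_equal(nrow(minutes), nrow(co$minutes))
  expect_equal(minutes$heart_rate, co$minutes$heart_rate)
  unlink(dir, recursive = TRUE)
})

test_that("cohort printing summarises the components", {
  co <- simulate_cohort(small_sim_config(), seed = 2,
                        with_streams = FALSE, with_tasks = FALSE)
  expect_output(print(co), "Synthetic study cohort")
  expect_output(print(co), "no tasks")
  expect_s3_class(co, "sim_cohort")
})
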