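#' Synthetic cohort configuration
#'
#' Bundles every parameter of the two-process synthetic study generator.
#' The defaults emulate the study conditions the pipeline is designed for:
#' sixteen participants drawn from three population groups (regular
#' workers, shift workers, graduate students), six weeks of nightly sleep
#' whose duration and stage composition are calibrated to the descriptive
#' sleep distribution (work nights ~425 min, free nights ~455 min, ~27%
#' free days pooling to ~433 min; stage fractions 18.2% REM / 52.9% light /
#' 15.9% deep of session time with the awake remainder), task batteries at
#' a mean rate of 2.81 per day with at least two hours between consecutive
#' sessions, and minute-level heart-rate/activity streams.
#'
#' Task outcomes follow a two-process performance model: a circadian
#' component `C` peaking `circ_offset` hours (default 13.5) after the
#' individual's MSF, a homeostatic pressure `H` that builds as a
#' saturating exponential during wakefulness (time constant `tau_wake`)
#' and decays during sleep (`tau_sleep`), plus configurable couplings from
#' night features (sleep duration, REM/light duration, sleep shift, wake
#' time), time since waking, and recent heart rate / activity onto latent
#' alertness and throughput. Latent alertness maps to session median
#' response time through a decreasing link `MRT = m0 (1 - alert/100)` and
#' latent throughput to additions attempted through
#' `NAA = round(n0 (1 + thr/100))`.
#'
#' @param n_regular,n_shift,n_student participants per group (default 6/5/5).
#' @param days nights simulated per participant (default 42).
#' @param start_date first calendar date of the span (a Monday by default).
#' @param msf_mean,msf_sd named numeric (`regular`, `shift`, `student`)
#'   chronotype distributions, fractional hours.
#' @param dur_work_mean,dur_free_mean,dur_sd,dur_between_sd nightly sleep
#'   duration model, minutes (within-night SD and between-participant SD).
#' @param stage_mean,stage_sd named numeric (`rem`, `light`, `deep`)
#'   stage fractions of session time.
#' @param tasks_per_day mean completed task batteries per day (default 2.81).
#' @param min_gap minimum minutes between consecutive tasks (default 120).
#' @param circ_amplitude circadian amplitude on the percent score scale.
#' @param circ_offset acrophase offset after MSF, hours (default 13.5).
#' @param tau_wake,tau_sleep homeostatic time constants in minutes
#'   (defaults 18.2 h and 4.2 h).
#' @param coupling named numeric of effect sizes in percent score per SD of
#'   the feature: `sleep_duration`, `rem_duration`, `light_duration`
#'   (alertness), `sleep_shift`, `sleep_end` (throughput),
#'   `time_since_wake` (alertness), `hr`, `activity` (both). Signs follow
#'   the directions the analysis is meant to recover.
#' @param feature_scale named list of `c(center, scale)` standardisers used
#'   by the couplings.
#' @param rrt_noise,raa_noise latent score noise SDs (percent).
#' @param m0,m0_sd,n0,n0_sd baseline MRT (ms) and NAA with
#'   between-participant SDs.
#' @param pvt_n_stimuli,pvt_stim_sd,false_start_rate per-stimulus response
#'   generation around the session MRT.
#' @param resting_hr_mean,resting_hr_sd,resting_hr_day_sd resting heart
#'   rate model (bpm).
#' @param hr_wake_elev,hr_diurnal_amp,hr_noise,hr_step_gain heart-rate
#'   stream parameters.
#' @param bout_prob,steps_per_min,walk_prob,walk_steps activity bout model
#'   (10-minute blocks during wakefulness).
#' @param kcal_sleep,kcal_wake,kcal_per_step,km_per_step calorie/distance
#'   links.
#' @param night_drop_rate,stream_gap_rate opt-in missingness rates
#'   (default 0: complete data).
#' @return an object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_regular = 6, n_shift = 5, n_student = 5,
                       days = 42,
                       start_date = as.Date("2019-03-04"),
                       msf_mean = c(regular = 3.5, shift = 4.3, student = 4.6),
                       msf_sd = c(regular = 0.5, shift = 1.0, student = 0.8),
                       dur_work_mean = 425, dur_free_mean = 455,
                       dur_sd = 55, dur_between_sd = 25,
                       stage_mean = c(rem = 0.1818, light = 0.5292, deep = 0.1592),
                       stage_sd = c(rem = 0.053, light = 0.0695, deep = 0.051),
                       tasks_per_day = 2.81, min_gap = 120,
                       circ_amplitude = 3, circ_offset = 13.5,
                       tau_wake = 18.2 * 60, tau_sleep = 4.2 * 60,
                       coupling = c(sleep_duration = 3, rem_duration = 1.5,
                                    light_duration = 2, sleep_shift = -3,
                                    sleep_end = -2, time_since_wake = -3,
                                    hr = 2, activity = 1.5),
                       feature_scale = list(
                         sleep_duration = c(433, 60), rem_duration = c(79, 26),
                         light_duration = c(229, 42), sleep_shift = c(0, 120),
                         sleep_end = c(7.5, 1.5), homeostatic = c(0.6, 0.2),
                         hr = c(75, 6), activity = c(6, 8)),
                       rrt_noise = 8, raa_noise = 12,
                       m0 = 355, m0_sd = 60, n0 = 18, n0_sd = 3,
                       pvt_n_stimuli = 25, pvt_stim_sd = 40,
                       false_start_rate = 0.02,
                       resting_hr_mean = 67, resting_hr_sd = 9,
                       resting_hr_day_sd = 1.5,
                       hr_wake_elev = 8, hr_diurnal_amp = 3, hr_noise = 3.5,
                       hr_step_gain = 0.1,
                       bout_prob = 0.07, steps_per_min = 70,
                       walk_prob = 0.15, walk_steps = 8,
                       kcal_sleep = 0.95, kcal_wake = 1.15,
                       kcal_per_step = 0.004, km_per_step = 0.00075,
                       night_drop_rate = 0, stream_gap_rate = 0) {
  cfg <- as.list(environment())
  stopifnot(days >= 7, min_gap >= 0, tasks_per_day > 0,
            all(c(msf_sd, dur_sd, dur_between_sd, stage_sd, rrt_noise,
                  raa_noise, pvt_stim_sd, m0_sd, n0_sd) >= 0),
            all(names(stage_mean) == c("rem", "light", "deep")),
            night_drop_rate >= 0, night_drop_rate < 1,
            stream_gap_rate >= 0, stream_gap_rate < 1)
  structure(cfg, class = "sim_config")
}

#' Circadian performance component
#'
#' `amplitude * cos(2 pi (InT - offset) / 24)` where `InT` is internal
#' time; maximal exactly `offset` hours after the individual's MSF.
#'
#' @param t `POSIXct` timestamp(s) or fractional clock hours.
#' @param msf individual MSF, fractional hours.
#' @param offset acrophase offset after MSF, hours.
#' @param amplitude nonnegative amplitude.
#' @return signed level in `[-amplitude, amplitude]`.
#' @export
circadian_value <- function(t, msf, offset = 13.5, amplitude = 1) {
  stopifnot(amplitude >= 0)
  amplitude * cos(2 * pi * (internal_time(t, msf) - offset) / 24)
}

#' Homeostatic sleep pressure during wakefulness
#'
#' Saturating-exponential buildup toward 1:
#' `1 - (1 - s0) exp(-minutes_awake / tau_wake)`; strictly increasing in
#' wake duration and continuous at the sleep/wake transition.
#'
#' @param minutes_awake nonnegative minutes since waking.
#' @param s0 pressure at wake (0-1).
#' @param tau_wake buildup time constant, minutes (default 18.2 h).
#' @return pressure in \[0, 1).
#' @export
homeostatic_value <- function(minutes_awake, s0 = 0, tau_wake = 18.2 * 60) {
  stopifnot(tau_wake > 0)
  1 - (1 - s0) * exp(-minutes_awake / tau_wake)
}

#' Homeostatic pressure decay during sleep
#'
#' `s0 * exp(-minutes_asleep / tau_sleep)`: the saturating-exponential
#' release of sleep pressure over a recovery sleep episode.
#'
#' @param minutes_asleep nonnegative minutes of sleep.
#' @param s0 pressure at sleep onset.
#' @param tau_sleep decay time constant, minutes (default 4.2 h).
#' @return pressure in \[0, `s0`\].
#' @export
homeostatic_recovery <- function(minutes_asleep, s0, tau_sleep = 4.2 * 60) {
  stopifnot(tau_sleep > 0)
  s0 * exp(-minutes_asleep / tau_sleep)
}

#' Simulate a complete synthetic study cohort
#'
#' Generates schedules, nightly sleep sessions with stages, task batteries
#' with per-stimulus PVT responses, minute-level heart-rate/activity
#' streams, and the latent ground truth behind every task outcome. Output
#' is bit-for-bit reproducible given `(config, seed)` and the same
#' component flags.
#'
#' @param config a [sim_config()] object.
#' @param seed integer RNG seed.
#' @param with_streams generate minute-level streams (and let the heart
#'   rate / activity couplings act on task outcomes). Turning streams off
#'   speeds up sleep-only experiments; the arousal couplings then
#'   contribute nothing.
#' @param with_tasks generate task batteries.
#' @return a list of class `"sim_cohort"`: `schedule`, `sleep`, `tasks`,
#'   `minutes`, `truth` (per-task latent components) and `participants`
#'   (per-participant ground truth incl. true MSF).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1,
                            with_streams = TRUE, with_tasks = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  groups <- rep(c("regular", "shift", "student"),
                c(config$n_regular, config$n_shift, config$n_student))
  ids <- sprintf("P%02d", seq_along(groups))
  participants <- data.frame(
    participant_id = ids, group = groups,
    msf_true = stats::rnorm(length(ids), config$msf_mean[groups],
                            config$msf_sd[groups]),
    dur_offset = stats::rnorm(length(ids), 0, config$dur_between_sd),
    m0 = stats::rnorm(length(ids), config$m0, config$m0_sd),
    n0 = stats::rnorm(length(ids), config$n0, config$n0_sd),
    resting_hr = stats::rnorm(length(ids), config$resting_hr_mean,
                              config$resting_hr_sd),
    stringsAsFactors = FALSE)
  participants$m0 <- pmax(participants$m0, 220)
  participants$n0 <- pmax(participants$n0, 8)
  participants$resting_hr <- pmin(pmax(participants$resting_hr, 45), 95)

  sched <- list(); sleeps <- list(); streams <- list()
  tasks <- list(); truths <- list()
  for (k in seq_along(ids)) {
    pp <- participants[k, ]
    ps <- sim_schedule_one(pp, config)
    night <- sim_nights_one(pp, ps, config)
    stream <- if (with_streams) sim_stream_one(pp, night$sleep, config) else NULL
    if (with_tasks) {
      tk <- sim_tasks_one(pp, night, stream, config)
      tasks[[k]] <- tk$tasks
      truths[[k]] <- tk$truth
    }
    sched[[k]] <- ps
    sleeps[[k]] <- night$sleep
    streams[[k]] <- stream
  }
  out <- list(
    schedule = do.call(rbind, sched),
    sleep = finish_sleep(do.call(rbind, sleeps)),
    tasks = if (with_tasks) rbind_tasks(tasks) else NULL,
    minutes = if (with_streams) do.call(rbind, streams) else NULL,
    truth = if (with_tasks) do.call(rbind, truths) else NULL,
    participants = participants,
    seed = as.integer(seed))
  rownames(out$schedule) <- NULL
  if (!is.null(out$minutes)) rownames(out$minutes) <- NULL
  if (!is.null(out$truth)) rownames(out$truth) <- NULL
  structure(out, class = "sim_cohort")
}

rbind_tasks <- function(tasks) {
  tasks <- tasks[!vapply(tasks, is.null, TRUE)]
  base <- do.call(rbind, lapply(tasks, function(t) t[, setdiff(names(t), "pvt")]))
  base$pvt <- I(do.call(c, lapply(tasks, `[[`, "pvt")))
  rownames(base) <- NULL
  base
}

# work/free calendar for one participant
sim_schedule_one <- function(pp, config) {
  dates <- seq(config$start_date, config$start_date + config$days, by = "day")
  wd <- as.POSIXlt(as.POSIXct(paste(dates, "12:00"), tz = "UTC"))$wday
  if (pp$group == "regular") {
    type <- ifelse(wd %in% 1:5, "work", "free")
  } else if (pp$group == "student") {
    type <- ifelse(wd %in% 1:5, "work", "free")
    wk <- which(type == "free")
    type[wk][stats::runif(length(wk)) < 0.2] <- "work"
    wkd <- which(type == "work" & wd %in% 1:5)
    type[wkd][stats::runif(length(wkd)) < 0.05] <- "free"
  } else {
    cycle <- c("day", "day", "evening", "evening", "night", "night", "off", "off")
    phase <- sample.int(8, 1)
    shift_type <- cycle[((seq_along(dates) + phase - 1) %% 8) + 1]
    type <- ifelse(shift_type == "off", "free", "work")
    attr(type, "shift_type") <- shift_type
  }
  out <- data.frame(participant_id = pp$participant_id, date = dates,
                    day_type = as.character(type), stringsAsFactors = FALSE)
  out$shift_type <- if (pp$group == "shift") attr(type, "shift_type") else NA_character_
  out
}

# nightly sleep sessions + homeostat state at wake for one participant
sim_nights_one <- function(pp, ps, config) {
  days <- config$days
  wake_dates <- ps$date[-1]                  # nights end on dates 2..days+1
  day_type <- ps$day_type[-1]
  jw <- if (pp$group == "student") 0.6 else 0.4
  jf <- if (pp$group == "student") 0.9 else 0.6
  mid <- numeric(days)
  for (i in seq_len(days)) {
    if (pp$group == "shift") {
      prev_shift <- ps$shift_type[i]         # the shift worked on the day before waking
      mid[i] <- switch(prev_shift,
        night = 12 + stats::rnorm(1, 0, 0.7),
        evening = pp$msf_true + 2 + stats::rnorm(1, 0, 0.7),
        pp$msf_true + stats::rnorm(1, 0, 0.6))
    } else if (day_type[i] == "work") {
      mid[i] <- pp$msf_true - 0.4 + stats::rnorm(1, 0, jw)
    } else {
      mid[i] <- pp$msf_true + stats::rnorm(1, 0, jf)
    }
  }
  dmean <- ifelse(day_type == "work", config$dur_work_mean, config$dur_free_mean)
  dur <- round(pmin(pmax(stats::rnorm(days, dmean + pp$dur_offset,
                                      config$dur_sd), 181), 779))
  mid_instant <- as.POSIXct(paste(wake_dates, "00:00"), tz = "UTC") +
    (mid - ifelse(mid > 18, 24, 0)) * 3600
  start <- round_minute(mid_instant - dur * 30)   # dur/2 minutes in seconds
  end <- start + dur * 60

  staged <- dur > 180
  fr <- matrix(NA_real_, days, 3, dimnames = list(NULL, c("rem", "light", "deep")))
  for (j in 1:3) {
    fr[, j] <- pmax(stats::rnorm(days, config$stage_mean[j], config$stage_sd[j]), 0.02)
  }
  s <- rowSums(fr)
  over <- s > 0.97
  fr[over, ] <- fr[over, , drop = FALSE] * (0.97 / s[over])
  stage_min <- round(fr * dur)
  awake <- dur - rowSums(stage_min)
  asleep <- rowSums(stage_min)

  sleep <- data.frame(
    participant_id = pp$participant_id, start = start, end = end,
    duration = dur, minutes_asleep = asleep,
    rem_min = ifelse(staged, stage_min[, "rem"], NA_real_),
    light_min = ifelse(staged, stage_min[, "light"], NA_real_),
    deep_min = ifelse(staged, stage_min[, "deep"], NA_real_),
    awake_min = ifelse(staged, awake, NA_real_),
    efficiency = round(100 * asleep / dur, 1),
    awakenings_gt5min = stats::rpois(days, 3),
    onset_latency = stats::rpois(days, 8) + 2,
    stringsAsFactors = FALSE)

  # homeostat state at each wake
  s_wake <- numeric(days)
  s_wake[1] <- 0.3
  for (i in seq_len(days - 1)) {
    wake_min <- max(diff_minutes(start[i + 1], end[i]), 0)
    s_onset <- homeostatic_value(wake_min, s_wake[i], config$tau_wake)
    s_wake[i + 1] <- homeostatic_recovery(dur[i + 1], s_onset, config$tau_sleep)
  }

  keep <- stats::runif(days) >= config$night_drop_rate
  list(sleep = sleep[keep, , drop = FALSE],
       all_sleep = sleep, s_wake = s_wake, mid = mid, keep = keep)
}

round_minute <- function(t) {
  as.POSIXct(round(as.numeric(t) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

# minute-level HR/activity streams for one participant
sim_stream_one <- function(pp, sleep, config) {
  t0 <- round_minute(min(sleep$start)) - 3600
  t1 <- round_minute(max(sleep$end)) + 16 * 3600
  ts <- seq(t0, t1, by = 60)
  n <- length(ts)
  tnum <- as.numeric(ts)
  asleep <- rep(FALSE, n)
  for (i in seq_len(nrow(sleep))) {
    asleep[tnum >= as.numeric(sleep$start[i]) & tnum < as.numeric(sleep$end[i])] <- TRUE
  }
  block <- (seq_len(n) - 1L) %/% 10L
  nb <- max(block) + 1L
  active_block <- stats::runif(nb) < config$bout_prob
  active <- active_block[block + 1L] & !asleep
  steps <- integer(n)
  steps[active] <- stats::rpois(sum(active), config$steps_per_min)
  idle <- which(!active & !asleep)
  walk <- idle[stats::runif(length(idle)) < config$walk_prob]
  steps[walk] <- stats::rpois(length(walk), config$walk_steps)

  date <- local_date(ts)
  udate <- unique(date)
  rhr_day <- pp$resting_hr + stats::rnorm(length(udate), 0, config$resting_hr_day_sd)
  resting <- rhr_day[match(date, udate)]
  diurnal <- config$hr_diurnal_amp *
    cos(2 * pi * (internal_time(clock_hour(ts), pp$msf_true) - 10) / 24)
  hr <- resting + ifelse(asleep, -3, config$hr_wake_elev) + diurnal +
    config$hr_step_gain * steps + stats::rnorm(n, 0, config$hr_noise)
  hr <- round(pmin(pmax(hr, 40), 190))
  kcal <- round(ifelse(asleep, config$kcal_sleep, config$kcal_wake) +
                config$kcal_per_step * steps +
                pmax(stats::rnorm(n, 0, 0.05), -0.1), 2)
  out <- data.frame(
    participant_id = pp$participant_id, timestamp = ts,
    heart_rate = hr, calories = kcal, steps = steps,
    distance = round(steps * config$km_per_step, 4),
    floors = stats::rpois(n, 0.002) * as.integer(!asleep),
    resting_hr = round(resting), stringsAsFactors = FALSE)
  if (config$stream_gap_rate > 0) {
    out <- out[stats::runif(n) >= config$stream_gap_rate, , drop = FALSE]
  }
  out
}

# task batteries + latent truth for one participant
sim_tasks_one <- function(pp, night, stream, config) {
  allsl <- night$all_sleep
  days <- nrow(allsl)
  cp <- config$coupling
  fs <- config$feature_scale
  zval <- function(x, key) (x - fs[[key]][1]) / fs[[key]][2]

  # precompute stream cumulative sums for 60-min window means
  if (!is.null(stream)) {
    st_num <- as.numeric(stream$timestamp)
    cs_hr <- cumsum(stream$heart_rate)
    cs_steps <- cumsum(stream$steps)
  }

  rows <- list(); truth <- list()
  for (i in seq_len(days)) {
    w_start <- allsl$end[i] + 30 * 60
    w_end <- if (i < days) allsl$start[i + 1] - 30 * 60
             else allsl$end[i] + 16 * 3600
    avail <- diff_minutes(w_end, w_start)
    if (avail <= 0) next
    n_t <- stats::rpois(1, config$tasks_per_day)
    gap <- config$min_gap + 1
    n_max <- floor(avail / gap) + 1
    n_t <- min(n_t, n_max)
    if (n_t == 0) next
    slack <- avail - (n_t - 1) * gap
    u <- sort(stats::runif(n_t, 0, slack))
    t_task <- round_minute(w_start + (u + (seq_len(n_t) - 1) * gap) * 60)

    tsw <- diff_minutes(t_task, allsl$end[i])
    C <- circadian_value(t_task, pp$msf_true, config$circ_offset,
                         config$circ_amplitude)
    H <- homeostatic_value(tsw, night$s_wake[i], config$tau_wake)
    shift_i <- sleep_shift(allsl$start[i], allsl$end[i],
                           local_date(allsl$end[i]), pp$msf_true)
    rem_i <- ifelse(is.na(allsl$rem_min[i]),
                    config$stage_mean["rem"] * allsl$duration[i], allsl$rem_min[i])
    light_i <- ifelse(is.na(allsl$light_min[i]),
                      config$stage_mean["light"] * allsl$duration[i], allsl$light_min[i])

    hr_term <- 0; act_term <- 0
    if (!is.null(stream) && (cp[["hr"]] != 0 || cp[["activity"]] != 0)) {
      hr60 <- numeric(n_t); act60 <- numeric(n_t)
      for (j in seq_len(n_t)) {
        hi <- findInterval(as.numeric(t_task[j]), st_num)
        lo <- findInterval(as.numeric(t_task[j]) - 60 * 60, st_num)
        if (hi > lo) {
          hr60[j] <- (cs_hr[hi] - cs_hr[lo]) / (hi - lo)
          act60[j] <- (cs_steps[hi] - cs_steps[lo]) / (hi - lo)
        } else {
          hr60[j] <- fs$hr[1]; act60[j] <- fs$activity[1]
        }
      }
      hr_term <- cp[["hr"]] * zval(hr60, "hr")
      act_term <- cp[["activity"]] * zval(act60, "activity")
    }

    alert <- C +
      cp[["time_since_wake"]] * zval(H, "homeostatic") +
      cp[["sleep_duration"]] * zval(allsl$duration[i], "sleep_duration") +
      cp[["rem_duration"]] * zval(rem_i, "rem_duration") +
      cp[["light_duration"]] * zval(light_i, "light_duration") +
      hr_term + act_term +
      stats::rnorm(n_t, 0, config$rrt_noise)
    thr <- C +
      cp[["sleep_shift"]] * zval(shift_i, "sleep_shift") +
      cp[["sleep_end"]] * zval(clock_hour(allsl$end[i]), "sleep_end") +
      hr_term + act_term +
      stats::rnorm(n_t, 0, config$raa_noise)

    mrt <- pmin(pmax(pp$m0 * (1 - alert / 100), 200), 790)
    naa <- pmax(round(pp$n0 * (1 + thr / 100)), 0)

    pvt <- vector("list", n_t)
    for (j in seq_len(n_t)) {
      rts <- pmax(mrt[j] + stats::rnorm(config$pvt_n_stimuli, 0,
                                        config$pvt_stim_sd), 150)
      nfs <- stats::rbinom(1, config$pvt_n_stimuli, config$false_start_rate)
      rt_all <- c(rts, if (nfs > 0) stats::runif(nfs, 80, 140))
      flag <- c(rep(FALSE, length(rts)), rep(TRUE, nfs))
      ord <- sample.int(length(rt_all))
      pvt[[j]] <- data.frame(rt = round(rt_all[ord], 1),
                             false_start = flag[ord])
    }
    d <- data.frame(participant_id = pp$participant_id, timestamp = t_task,
                    add_attempts = as.integer(naa), kss = sample.int(9, n_t, TRUE),
                    caffeine_last_hour = stats::runif(n_t) < 0.2,
                    stringsAsFactors = FALSE)
    d$pvt <- I(pvt)
    rows[[i]] <- d
    truth[[i]] <- data.frame(participant_id = pp$participant_id,
                             timestamp = t_task, C = C, H = H, tsw = tsw,
                             alert_latent = alert, thr_latent = thr,
                             mrt_target = mrt, naa_target = naa,
                             night_duration = allsl$duration[i],
                             night_shift = shift_i,
                             stringsAsFactors = FALSE)
  }
  list(tasks = rbind_tasks(rows), truth = do.call(rbind, truth))
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic study cohort\n")
  cat(sprintf("  %d participants, %d sleep sessions, %s tasks, %s stream minutes\n",
              nrow(x$participants), nrow(x$sleep),
              if (is.null(x$tasks)) "no" else nrow(x$tasks),
              if (is.null(x$minutes)) "no" else nrow(x$minutes)))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes `tasks.jsonl`, `sleep.csv`, `minutes.csv`, `schedule.csv` and
#' `truth.csv` into a directory using the package's on-disk formats.
#'
#' @param cohort a `"sim_cohort"` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_schedule(cohort$schedule[, c("participant_id", "date", "day_type")],
                 file.path(dir, "schedule.csv"))
  write_sleep_sessions(cohort$sleep, file.path(dir, "sleep.csv"))
  if (!is.null(cohort$tasks)) {
    write_task_sessions(cohort$tasks, file.path(dir, "tasks.jsonl"))
  }
  if (!is.null(cohort$minutes)) {
    write_minute_stream(cohort$minutes, file.path(dir, "minutes.csv"))
  }
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    tr$timestamp <- format_iso_minute(tr$timestamp)
    utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}
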