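# Small builders shared by the unit tests. Everything is built in memory;
# no fixture files are read from disk.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

make_pvt <- function(rt, false_start = rep(FALSE, length(rt))) {
  data.frame(rt = rt, false_start = false_start)
}

# one task battery per element of `mrt`, a single stimulus each so the
# session median equals the given value exactly
make_tasks <- function(participant_id, timestamps, mrt,
                       naa = rep(20L, length(mrt))) {
  out <- data.frame(participant_id = participant_id,
                    timestamp = ts_utc(timestamps),
                    add_attempts = as.integer(naa),
                    kss = NA_integer_, caffeine_last_hour = NA,
                    stringsAsFactors = FALSE)
  out$pvt <- I(lapply(mrt, make_pvt))
  out
}

make_sleep <- function(participant_id, start, end,
                       rem = NA_real_, light = NA_real_, deep = NA_real_,
                       awake = NA_real_) {
  start <- ts_utc(start); end <- ts_utc(end)
  dur <- as.numeric(difftime(end, start, units = "mins"))
  finish_sleep(data.frame(
    participant_id = participant_id, start = start, end = end,
    duration = dur, minutes_asleep = dur,
    rem_min = rem, light_min = light, deep_min = deep, awake_min = awake,
    efficiency = 95, awakenings_gt5min = 0, onset_latency = 5,
    stringsAsFactors = FALSE))
}

make_schedule <- function(participant_id, dates, day_type) {
  data.frame(participant_id = participant_id, date = as.Date(dates),
             day_type = day_type, stringsAsFactors = FALSE)
}

make_stream <- function(participant_id, timestamps, heart_rate = NA_real_,
                        calories = NA_real_, steps = NA_real_,
                        distance = NA_real_, resting_hr = NA_real_) {
  data.frame(participant_id = participant_id, timestamp = ts_utc(timestamps),
             heart_rate = heart_rate, calories = calories, steps = steps,
             distance = distance, floors = 0, resting_hr = resting_hr,
             stringsAsFactors = FALSE)
}

# a reduced-scale simulation configuration for pipeline tests
small_sim_config <- function(...) {
  sim_config(n_regular = 3, n_shift = 2, n_student = 2, days = 14, ...)
}
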