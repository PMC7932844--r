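#' Chronotype, sleep debt and sleep shift
#'
#' Chronotype is quantified as the corrected mid-sleep point on free days:
#'
#' \deqn{MSF = MSF_{uc} - 0.5\,(SD_f - \frac{N_w SD_w + N_f SD_f}{N_w + N_f})}
#'
#' where \eqn{MSF_{uc}} is the average mid-sleep clock time over free-day
#' nights, \eqn{SD_w}/\eqn{SD_f} are the mean sleep durations on work and
#' free days and \eqn{N_w}/\eqn{N_f} the counts of such days. The
#' correction removes the oversleep that compensates for work-week sleep
#' debt; when \eqn{SD_f} exceeds the weighted mean duration it always moves
#' MSF earlier.
#'
#' Internal time is clock time re-anchored at the individual's MSF
#' (`InT = ExT - MSF`, wrapped onto \[0, 24)). Sleep need
#' \eqn{SN = (N_w SD_w + N_f SD_f)/(N_w + N_f)} is the duration-weighted
#' mean nightly sleep, and nightly sleep debt is
#' \eqn{1 - duration/SN}; the mean debt over the nights that enter SN is
#' zero by algebra. Sleep shift is the signed difference, in minutes,
#' between a night's actual mid-sleep instant and the MSF instant expected
#' for that wake date; anchoring on the wake date (rather than taking a
#' minimal circular difference) lets shift-worker nights exceed twelve
#' hours in either direction.
#'
#' A night is classified work/free by the schedule label of its wake-up
#' date, and when several sessions share a wake date only the longest one
#' is the "night" (naps are excluded from nightly metrics).
#'
#' @name chronobiology
NULL

#' Mid-sleep time of a session
#'
#' Clock time of the midpoint of the absolute sleep interval; sessions
#' crossing midnight are handled by the midpoint of the interval itself.
#'
#' @param start,end `POSIXct` session bounds.
#' @return mid-sleep as fractional hours in \[0, 24).
#' @export
mid_sleep_time <- function(start, end) {
  clock_hour(start + as.numeric(difftime(end, start, units = "secs")) / 2)
}

#' Reduce sleep sessions to one night per wake date
#'
#' Keeps the longest session per `(participant, wake_date)`; shorter
#' same-day sessions (naps) are dropped for nightly metrics and linking.
#'
#' @param sleep sleep-session data.frame (see [read_sleep_sessions()]).
#' @return the filtered data.frame, sorted by participant and wake date.
#' @export
nightly_sessions <- function(sleep) {
  if (nrow(sleep) == 0L) return(sleep)
  o <- order(sleep$participant_id, sleep$wake_date, -sleep$duration)
  s <- sleep[o, , drop = FALSE]
  s <- s[!duplicated(s[, c("participant_id", "wake_date")]), , drop = FALSE]
  s <- s[order(s$participant_id, s$wake_date), , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Chronotype profile per participant
#'
#' Computes the uncorrected and corrected mid-sleep on free days, sleep
#' need and the work/free counts and mean durations for every participant
#' with at least one free-day night and one work-day night.
#'
#' @param sleep sleep-session data.frame; reduced internally to one night
#'   per wake date.
#' @param schedule schedule data.frame (see [read_schedule()]).
#' @param mean_method `"circular"` mean of mid-sleep clock times (default)
#'   or the naive `"linear"` mean anchored at 12:00.
#' @return data.frame with one row per participant: `participant_id`,
#'   `msf_uc`, `msf` (fractional hours), `sleep_need` (minutes), `n_work`,
#'   `n_free`, `mean_dur_work`, `mean_dur_free` (minutes).
#' @export
chronotype_msf <- function(sleep, schedule, mean_method = c("circular", "linear")) {
  mean_method <- match.arg(mean_method)
  nights <- nightly_sessions(sleep)
  nights$day_type <- schedule_lookup(schedule, nights$participant_id, nights$wake_date)
  res <- list()
  for (p in unique(nights$participant_id)) {
    s <- nights[nights$participant_id == p, , drop = FALSE]
    free <- s$day_type == "free"
    work <- s$day_type == "work"
    if (!any(free)) stop(sprintf("participant %s: chronotype undefined (no free-day nights)", p))
    n_f <- sum(free); n_w <- sum(work)
    sd_f <- mean(s$duration[free])
    sd_w <- if (n_w > 0) mean(s$duration[work]) else NA_real_
    sn <- if (n_w > 0) (n_w * sd_w + n_f * sd_f) / (n_w + n_f) else sd_f
    msf_uc <- circular_mean_hours(mid_sleep_time(s$start[free], s$end[free]),
                                  method = mean_method)
    msf <- wrap24(msf_uc - 0.5 * (sd_f - sn) / 60)
    res[[p]] <- data.frame(participant_id = p, msf_uc = msf_uc, msf = msf,
                           sleep_need = sn, n_work = n_w, n_free = n_f,
                           mean_dur_work = sd_w, mean_dur_free = sd_f,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

schedule_lookup <- function(schedule, participant_id, date) {
  key <- paste(schedule$participant_id, schedule$date)
  idx <- match(paste(participant_id, date), key)
  if (anyNA(idx)) stop("schedule does not label every observed wake date")
  schedule$day_type[idx]
}

#' Internal time of an external timestamp
#'
#' `InT = ExT - MSF` on the circular 24 h clock: the number of hours since
#' the individual's mid-sleep point, wrapped onto \[0, 24).
#'
#' @param t `POSIXct` timestamp(s) or fractional clock hours.
#' @param msf the individual's MSF in fractional hours.
#' @return internal time in fractional hours, \[0, 24).
#' @export
internal_time <- function(t, msf) {
  h <- if (inherits(t, "POSIXct")) clock_hour(t) else t
  wrap24(h - msf)
}

#' Sleep shift of a night
#'
#' Signed minutes between the night's actual mid-sleep instant and the MSF
#' instant expected for its wake date (MSF clock times before 12:00 fall in
#' the early morning of the wake date, later ones on the evening before).
#' Positive values mean mid-sleep later than the individual's MSF.
#'
#' @param start,end `POSIXct` session bounds.
#' @param wake_date `Date` of the session end.
#' @param msf the individual's MSF in fractional hours.
#' @return signed shift in minutes (magnitudes beyond 12 h are legitimate
#'   for strongly displaced sleep, e.g. day sleep after a night shift).
#' @export
sleep_shift <- function(start, end, wake_date, msf) {
  mid <- as.POSIXct(start, tz = "UTC") +
    as.numeric(difftime(end, start, units = "secs")) / 2
  # vectorised over nights: subtracting the day offset from the Date vector
  # keeps full length even when msf is a scalar
  anchor_date <- as.Date(wake_date) - ifelse(wrap24(msf) < 12, 0L, 1L)
  ref <- as.POSIXct(paste(anchor_date, "00:00"), tz = "UTC") + msf * 3600
  diff_minutes(mid, ref)
}

#' Sleep need and nightly sleep debt
#'
#' Sleep need is the duration-weighted mean nightly sleep over all
#' recorded nights (summing the work/free group totals and dividing by the
#' total night count reduces to the overall mean); nightly debt is
#' `1 - duration/SN`. The mean debt over the nights entering SN is exactly
#' zero.
#'
#' @param duration numeric vector of nightly sleep durations (minutes).
#' @return list with `sleep_need` (minutes) and `debt` (per-night vector).
#' @export
sleep_need_and_debt <- function(duration) {
  if (length(duration) == 0L) stop("at least one recorded night is required")
  sn <- mean(duration)
  list(sleep_need = sn, debt = 1 - duration / sn)
}

#' Per-night chronobiological metrics
#'
#' Builds the nightly feature table: duration, stage durations and
#' percentages (of elapsed session time), sleep debt, sleep shift, wake
#' clock time, efficiency and awakenings.
#'
#' @param sleep sleep-session data.frame; reduced to one night per wake
#'   date internally.
#' @param profile chronotype profile from [chronotype_msf()].
#' @return data.frame with one row per night.
#' @export
night_metrics <- function(sleep, profile) {
  nights <- nightly_sessions(sleep)
  res <- list()
  for (p in unique(nights$participant_id)) {
    s <- nights[nights$participant_id == p, , drop = FALSE]
    pr <- profile[profile$participant_id == p, , drop = FALSE]
    if (nrow(pr) == 0L) next
    snd <- sleep_need_and_debt(s$duration)
    res[[p]] <- data.frame(
      participant_id = p,
      wake_date = s$wake_date,
      duration = s$duration,
      rem_min = s$rem_min, light_min = s$light_min, deep_min = s$deep_min,
      rem_pct = 100 * s$rem_min / s$duration,
      light_pct = 100 * s$light_min / s$duration,
      deep_pct = 100 * s$deep_min / s$duration,
      sleep_debt = snd$debt,
      sleep_shift = sleep_shift(s$start, s$end, s$wake_date, pr$msf),
      sleep_end = clock_hour(s$end),
      end = s$end,
      efficiency = s$efficiency,
      awakenings = s$awakenings_gt5min,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Weekly sleep aggregates
#'
#' Mean sleep metrics over the seven-night window ending with the night
#' whose wake date is `as_of_date`. A missing night is imputed, metric by
#' metric, with the running mean of the participant's recorded nights
#' strictly before that night; if an imputation has no prior nights the
#' aggregate is missing.
#'
#' @param nights night-metric data.frame for one participant
#'   (see [night_metrics()]).
#' @param as_of_date `Date` the window ends on.
#' @return one-row data.frame: `date`, 7-night means `wk_duration`,
#'   `wk_rem_min`, `wk_light_min`, `wk_deep_min`, `wk_sleep_debt`,
#'   `wk_sleep_shift`, and `imputed_nights`.
#' @export
weekly_aggregates <- function(nights, as_of_date) {
  metrics <- c("duration", "rem_min", "light_min", "deep_min",
               "sleep_debt", "sleep_shift")
  window <- seq(as_of_date - 6, as_of_date, by = "day")
  vals <- matrix(NA_real_, nrow = 7, ncol = length(metrics),
                 dimnames = list(NULL, metrics))
  imputed <- 0L
  ok <- TRUE
  for (j in seq_along(window)) {
    d <- window[j]
    hit <- which(nights$wake_date == d)
    if (length(hit) == 1L) {
      vals[j, ] <- as.numeric(nights[hit, metrics])
    } else {
      prior <- nights[nights$wake_date < d, metrics, drop = FALSE]
      if (nrow(prior) == 0L) { ok <- FALSE; break }
      vals[j, ] <- colMeans(prior, na.rm = TRUE)
      imputed <- imputed + 1L
    }
  }
  means <- if (ok) colMeans(vals) else rep(NA_real_, length(metrics))
  out <- data.frame(date = as_of_date, imputed_nights = if (ok) imputed else NA_integer_)
  for (j in seq_along(metrics)) out[[paste0("wk_", metrics[j])]] <- means[j]
  out
}

#' Link a task to its preceding night
#'
#' Index of the most recent night ending before the task timestamp and
#' within `horizon_hours` of it; `NA` when none qualifies.
#'
#' @param task_time `POSIXct` task timestamp.
#' @param nights night-metric data.frame for the same participant, with an
#'   `end` column.
#' @param horizon_hours maximum staleness of the linked night (default 36).
#' @return integer row index into `nights`, or `NA`.
#' @export
link_previous_sleep <- function(task_time, nights, horizon_hours = 36) {
  if (nrow(nights) == 0L) return(NA_integer_)
  dt <- diff_minutes(task_time, nights$end)
  ok <- which(dt > 0 & dt <= horizon_hours * 60)
  if (length(ok) == 0L) return(NA_integer_)
  ok[which.min(dt[ok])]
}

#' Minutes awake at task time
#'
#' Task timestamp minus the end of the linked previous sleep session;
#' `NA` when no night links.
#'
#' @inheritParams link_previous_sleep
#' @return nonnegative minutes, or `NA`.
#' @export
time_since_wake <- function(task_time, nights, horizon_hours = 36) {
  i <- link_previous_sleep(task_time, nights, horizon_hours)
  if (is.na(i)) return(NA_real_)
  diff_minutes(task_time, nights$end[i])
}
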