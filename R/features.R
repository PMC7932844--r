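#' Momentary physiological features at task time
#'
#' For each task the pipeline extracts the current heart rate (the stream
#' value at the task's minute, or the nearest within a small tolerance),
#' the day's resting heart rate, and the mean and variance of heart rate,
#' calories, distance and steps over the last 10 and 60 minutes.
#'
#' Windows are half-open intervals `(t - w, t]` including the task minute;
#' variances are population variances (ddof 0) by default; a window whose
#' coverage (present minutes / window length) falls below
#' `min_coverage` yields missing statistics.
#'
#' @name momentary-features
NULL

#' Windowed statistics of one stream channel
#'
#' @param stream minute-stream data.frame (see [read_minute_stream()]),
#'   one participant.
#' @param t `POSIXct` window end (task time).
#' @param window window length in minutes.
#' @param channel channel column name (`"heart_rate"`, `"calories"`,
#'   `"steps"`, `"distance"`).
#' @param min_coverage minimum fraction of present minutes (default 0.5).
#' @param var_type `"population"` (default) or `"sample"`.
#' @return named numeric vector `c(mean, variance, coverage)`; mean and
#'   variance are `NA` below the coverage threshold.
#' @export
window_stats <- function(stream, t, window, channel,
                         min_coverage = 0.5,
                         var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  dt <- diff_minutes(t, stream$timestamp)
  v <- stream[[channel]][dt >= 0 & dt < window]
  v <- v[!is.na(v)]
  cov <- length(v) / window
  if (cov < min_coverage) {
    return(c(mean = NA_real_, variance = NA_real_, coverage = cov))
  }
  m <- mean(v)
  s2 <- if (var_type == "population") mean((v - m)^2)
        else if (length(v) > 1L) stats::var(v) else 0
  c(mean = m, variance = s2, coverage = cov)
}

#' Momentary feature vectors for a set of tasks
#'
#' @param tasks task-session data.frame (or any data.frame with
#'   `participant_id` and `timestamp`).
#' @param stream minute-stream data.frame covering the tasks' participants.
#' @param windows window lengths in minutes (default `c(10, 60)`).
#' @param hr_tolerance nearest-minute tolerance for the current heart rate
#'   (default 5 minutes).
#' @param min_coverage,var_type see [window_stats()].
#' @return data.frame with one row per task: `participant_id`,
#'   `timestamp`, `current_hr`, `resting_hr`, and for every channel in
#'   heart rate, calories, distance, steps and window `w`, columns
#'   `<channel>_mean_<w>` and `<channel>_var_<w>`.
#' @export
momentary_features <- function(tasks, stream, windows = c(10, 60),
                               hr_tolerance = 5, min_coverage = 0.5,
                               var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  channels <- c("heart_rate", "calories", "distance", "steps")
  out <- data.frame(participant_id = tasks$participant_id,
                    timestamp = tasks$timestamp, stringsAsFactors = FALSE)
  n_out <- nrow(out)
  acc <- new.env(parent = emptyenv())
  acc$current_hr <- rep(NA_real_, n_out)
  acc$resting_hr <- rep(NA_real_, n_out)
  for (ch in channels) for (w in windows) {
    acc[[paste0(ch, "_mean_", w)]] <- rep(NA_real_, n_out)
    acc[[paste0(ch, "_var_", w)]] <- rep(NA_real_, n_out)
    acc[[paste0(ch, "_cov_", w)]] <- rep(NA_real_, n_out)
  }
  split_stream <- split(stream, stream$participant_id)
  for (p in names(split_stream)) {
    s <- split_stream[[p]]
    s <- s[order(s$timestamp), , drop = FALSE]
    num <- as.numeric(s$timestamp)
    sdate <- local_date(s$timestamp)
    rhr <- tapply(s$resting_hr, sdate, function(v) v[!is.na(v)][1])
    chan_vals <- lapply(channels, function(ch) s[[ch]])
    names(chan_vals) <- channels
    hr_vals <- s$heart_rate
    rows <- which(out$participant_id == p)
    tnum <- as.numeric(out$timestamp[rows])
    tdate <- as.character(local_date(out$timestamp[rows]))
    for (j in seq_along(rows)) {
      i <- rows[j]
      t <- tnum[j]
      # current heart rate: exact minute, else nearest within tolerance
      lo5 <- findInterval(t - hr_tolerance * 60 - 1, num)
      hi5 <- findInterval(t + hr_tolerance * 60, num)
      if (hi5 > lo5) {
        idx <- (lo5 + 1):hi5
        idx <- idx[!is.na(hr_vals[idx])]
        if (length(idx) > 0L) {
          acc$current_hr[i] <- hr_vals[idx[which.min(abs(num[idx] - t))]]
        }
      }
      day <- rhr[[tdate[j]]]
      if (!is.null(day) && length(day) == 1L && !is.na(day)) acc$resting_hr[i] <- day
      hi <- findInterval(t, num)
      for (w in windows) {
        lo <- findInterval(t - w * 60, num)
        idx <- if (hi > lo) (lo + 1):hi else integer(0)
        for (ch in channels) {
          v <- chan_vals[[ch]][idx]
          v <- v[!is.na(v)]
          cov <- length(v) / w
          acc[[paste0(ch, "_cov_", w)]][i] <- cov
          if (cov >= min_coverage) {
            m <- mean(v)
            acc[[paste0(ch, "_mean_", w)]][i] <- m
            acc[[paste0(ch, "_var_", w)]][i] <-
              if (var_type == "population") mean((v - m)^2)
              else if (length(v) > 1L) stats::var(v) else 0
          }
        }
      }
    }
  }
  out$current_hr <- acc$current_hr
  out$resting_hr <- acc$resting_hr
  for (ch in channels) for (w in windows) {
    for (suffix in c("_mean_", "_var_", "_cov_")) {
      nm <- paste0(ch, suffix, w)
      out[[nm]] <- acc[[nm]]
    }
  }
  out
}
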