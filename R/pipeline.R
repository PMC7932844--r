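#' Analysis configuration
#'
#' Collects the pipeline's constants: the session filters (800 ms absolute
#' MRT cutoff, 3 SD outlier rule, 42-task inclusion), the momentary window
#' lengths (10 and 60 minutes), the weekly epoch (7 nights), the cosinor
#' period (24 h) and the confidence level.
#'
#' @param mrt_threshold absolute MRT cutoff in ms.
#' @param sd_limit SD multiple for session outlier removal.
#' @param min_tasks participant inclusion threshold on completed batteries.
#' @param windows momentary window lengths, minutes.
#' @param weekly_epoch nights per cumulative sleep epoch.
#' @param period cosinor period in hours.
#' @param conf_level confidence level for intervals.
#' @param link_horizon maximum hours between a wake and a linked task.
#' @param bin_hours width of time-of-day summary bins.
#' @param mean_method MSF averaging, `"circular"` or `"linear"`.
#' @return a list of class `"analysis_config"`.
#' @export
analysis_config <- function(mrt_threshold = 800, sd_limit = 3, min_tasks = 42,
                            windows = c(10, 60), weekly_epoch = 7,
                            period = 24, conf_level = 0.95,
                            link_horizon = 36, bin_hours = 4,
                            mean_method = c("circular", "linear")) {
  mean_method <- match.arg(mean_method)
  stopifnot(mrt_threshold > 0, sd_limit > 0, min_tasks > 0,
            all(windows > 0), weekly_epoch > 0, period > 0)
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the end-to-end analysis
#'
#' Scores the task batteries, derives the chronobiological night metrics
#' and weekly aggregates, extracts momentary physiological features (when
#' streams are supplied), and estimates every association table: daily
#' sleep metrics against daily relative scores, momentary features against
#' session scores, and 24 h cosinor fits of both performance measures by
#' time of day and internal time. A manifest records row counts at every
#' filter stage so attrition is auditable.
#'
#' @param tasks task sessions (data.frame or path to `tasks.jsonl`).
#' @param sleep sleep sessions (data.frame or path to `sleep.csv`).
#' @param schedule work/free schedule (data.frame or path).
#' @param minutes optional minute streams (data.frame or path).
#' @param config an [analysis_config()].
#' @return a list of class `"chronoperf_analysis"` with elements `scores`,
#'   `daily`, `nights`, `profile`, `features`, the association tables
#'   `sleep_table`, `momentary_table`, `cosinor_table`, descriptive
#'   summaries `descriptives`, time-of-day `bins`, and `manifest`.
#' @export
run_analysis <- function(tasks, sleep, schedule, minutes = NULL,
                         config = analysis_config()) {
  if (is.character(tasks)) tasks <- read_task_sessions(tasks)
  if (is.character(sleep)) sleep <- read_sleep_sessions(sleep)
  if (is.character(schedule)) schedule <- read_schedule(schedule)
  if (is.character(minutes)) minutes <- read_minute_stream(minutes)

  manifest <- list(n_tasks_raw = nrow(tasks),
                   n_participants_raw = length(unique(tasks$participant_id)))
  keep <- include_participants(tasks, config$min_tasks)
  tasks <- tasks[tasks$participant_id %in% keep, , drop = FALSE]
  sleep <- sleep[sleep$participant_id %in% keep, , drop = FALSE]
  if (!is.null(minutes)) {
    minutes <- minutes[minutes$participant_id %in% keep, , drop = FALSE]
  }
  manifest$n_participants_included <- length(keep)
  manifest$n_tasks_included <- nrow(tasks)

  scores <- score_sessions(tasks, config$mrt_threshold, config$sd_limit)
  manifest$n_sessions_retained_pvt <- sum(scores$retained_pvt)
  manifest$n_sessions_retained_add <- sum(scores$retained_add)

  profile <- chronotype_msf(sleep, schedule, config$mean_method)
  nights <- night_metrics(sleep, profile)
  manifest$n_nights <- nrow(nights)

  daily <- daily_relative_scores(scores)
  daily <- merge_daily_sleep(daily, nights, config$weekly_epoch)
  manifest$n_days_linked <- sum(!is.na(daily$duration))

  scores <- add_session_context(scores, nights, profile, config$link_horizon)
  manifest$n_sessions_sleep_linked <- sum(!is.na(scores$time_since_wake))

  features <- NULL
  if (!is.null(minutes) && nrow(minutes) > 0) {
    features <- momentary_features(scores, minutes, config$windows)
  }

  sleep_table <- sleep_association_table(daily, config$conf_level)
  momentary_table <- momentary_association_table(scores, features, config$conf_level)
  cosinor_table <- cosinor_table(scores, config$period, config$conf_level)
  bins <- list(
    rrt = binned_summary(scores$timestamp[scores$retained_pvt],
                         scores$rrt[scores$retained_pvt], config$bin_hours),
    raa = binned_summary(scores$timestamp[scores$retained_add],
                         scores$raa[scores$retained_add], config$bin_hours))

  out <- list(scores = scores, daily = daily, nights = nights,
              profile = profile, features = features,
              sleep_table = sleep_table, momentary_table = momentary_table,
              cosinor_table = cosinor_table,
              descriptives = descriptive_table(scores, nights, features),
              bins = bins, manifest = manifest, config = config)
  class(out) <- "chronoperf_analysis"
  out
}

# join previous-night metrics and weekly aggregates onto daily scores;
# a night joins the daily score of its wake date
merge_daily_sleep <- function(daily, nights, weekly_epoch = 7) {
  cols <- c("duration", "rem_min", "light_min", "deep_min", "rem_pct",
            "light_pct", "deep_pct", "sleep_debt", "sleep_shift",
            "sleep_end", "efficiency")
  for (cn in cols) daily[[cn]] <- NA_real_
  wk_cols <- paste0("wk_", c("duration", "rem_min", "light_min", "deep_min",
                             "sleep_debt", "sleep_shift"))
  for (cn in wk_cols) daily[[cn]] <- NA_real_
  for (p in unique(daily$participant_id)) {
    di <- which(daily$participant_id == p)
    np <- nights[nights$participant_id == p, , drop = FALSE]
    idx <- match(daily$date[di], np$wake_date)
    for (cn in cols) daily[[cn]][di] <- np[[cn]][idx]
    for (j in di) {
      wk <- weekly_aggregates(np, daily$date[j])
      for (cn in wk_cols) daily[[cn]][j] <- wk[[cn]]
    }
  }
  daily
}

# per-session context: linked night, time since wake, internal time
add_session_context <- function(scores, nights, profile, horizon = 36) {
  scores$time_since_wake <- NA_real_
  scores$internal_time <- NA_real_
  scores$time_of_day <- clock_hour(scores$timestamp)
  for (p in unique(scores$participant_id)) {
    si <- which(scores$participant_id == p)
    np <- nights[nights$participant_id == p, , drop = FALSE]
    msf <- profile$msf[profile$participant_id == p]
    if (length(msf) == 1L) {
      scores$internal_time[si] <- internal_time(scores$timestamp[si], msf)
    }
    for (j in si) {
      scores$time_since_wake[j] <- time_since_wake(scores$timestamp[j], np, horizon)
    }
  }
  scores
}

rmcorr_row <- function(df, feature, outcome, label, conf_level) {
  ok <- !is.na(df[[feature]]) & !is.na(df[[outcome]])
  fit <- tryCatch(rmcorr(df[[feature]][ok], df[[outcome]][ok],
                         df$participant_id[ok], conf_level),
                  error = function(e) NULL)
  if (is.null(fit)) {
    return(data.frame(feature = label, outcome = outcome, r_rm = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      p_value = NA_real_, df = NA_integer_, n = sum(ok),
                      stringsAsFactors = FALSE))
  }
  data.frame(feature = label, outcome = outcome, r_rm = fit$r,
             ci_low = fit$conf.int[1], ci_high = fit$conf.int[2],
             p_value = fit$p.value, df = fit$df, n = fit$n_obs,
             stringsAsFactors = FALSE)
}

sleep_association_table <- function(daily, conf_level) {
  pairs <- c("Previous night's sleep duration" = "duration",
             "Average nightly sleep debt over previous week" = "wk_sleep_debt",
             "Sleep shift" = "sleep_shift",
             "Sleep end time" = "sleep_end",
             "Duration of REM sleep" = "rem_min",
             "Duration of light sleep" = "light_min",
             "Duration of deep sleep" = "deep_min")
  out <- list()
  for (i in seq_along(pairs)) {
    for (oc in c("rel_daily_rrt", "rel_daily_raa")) {
      out[[length(out) + 1]] <- rmcorr_row(daily, pairs[i], oc,
                                           names(pairs)[i], conf_level)
    }
  }
  do.call(rbind, out)
}

momentary_association_table <- function(scores, features, conf_level) {
  df <- scores
  pairs <- c("Time since waking up" = "time_since_wake")
  if (!is.null(features)) {
    fcols <- setdiff(names(features), c("participant_id", "timestamp"))
    df <- cbind(df, features[, fcols, drop = FALSE])
    lab <- c(current_hr = "Current heart rate",
             resting_hr = "Resting heart rate",
             heart_rate_mean_60 = "Average heart rate over last 60 minutes",
             heart_rate_mean_10 = "Average heart rate over last 10 minutes",
             heart_rate_var_60 = "Variance in heart rate over last 60 minutes",
             heart_rate_var_10 = "Variance in heart rate over last 10 minutes",
             calories_mean_60 = "Average calories burnt over last 60 minutes",
             calories_mean_10 = "Average calories burnt over last 10 minutes",
             calories_var_60 = "Variance in calories burnt over last 60 minutes",
             calories_var_10 = "Variance in calories burnt over last 10 minutes",
             distance_mean_60 = "Average distance traveled over last 60 minutes",
             distance_mean_10 = "Average distance traveled over last 10 minutes",
             distance_var_60 = "Variance in distance traveled over last 60 minutes",
             distance_var_10 = "Variance in distance traveled over last 10 minutes",
             steps_mean_60 = "Average steps walked over last 60 minutes",
             steps_mean_10 = "Average steps walked over last 10 minutes",
             steps_var_60 = "Variance in steps walked over last 60 minutes",
             steps_var_10 = "Variance in steps walked over last 10 minutes")
    lab <- lab[names(lab) %in% names(df)]
    pairs <- c(pairs, stats::setNames(names(lab), lab))
  }
  out <- list()
  for (i in seq_along(pairs)) {
    for (oc in c("rrt", "raa")) {
      out[[length(out) + 1]] <- rmcorr_row(df, pairs[i], oc,
                                           names(pairs)[i], conf_level)
    }
  }
  do.call(rbind, out)
}

cosinor_table <- function(scores, period = 24, conf_level = 0.95) {
  cases <- expand.grid(basis = c("time_of_day", "internal_time"),
                       outcome = c("rrt", "raa"), stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(cases))) {
    b <- cases$basis[i]; oc <- cases$outcome[i]
    keep <- if (oc == "rrt") scores$retained_pvt else scores$retained_add
    ok <- keep & !is.na(scores[[b]]) & !is.na(scores[[oc]])
    fit <- tryCatch(cosinor(scores[[b]][ok], scores[[oc]][ok], period, conf_level),
                    error = function(e) NULL)
    out[[i]] <- data.frame(
      basis = b, outcome = oc,
      mesor = if (is.null(fit)) NA_real_ else fit$mesor,
      amplitude = if (is.null(fit)) NA_real_ else fit$amplitude,
      acrophase = if (is.null(fit)) NA_real_ else fit$acrophase,
      acrophase_fmt = if (is.null(fit)) NA_character_ else format_acrophase(fit),
      p_value = if (is.null(fit)) NA_real_ else fit$amplitude_p,
      n = sum(ok), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

descriptive_table <- function(scores, nights, features) {
  desc <- function(x, name) {
    x <- x[!is.na(x)]
    data.frame(metric = name, n = length(x),
               min = if (length(x)) min(x) else NA_real_,
               max = if (length(x)) max(x) else NA_real_,
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- list(
    desc(scores$mrt[scores$retained_pvt], "Median response time (ms)"),
    desc(scores$rrt[scores$retained_pvt], "Relative response time (%)"),
    desc(scores$naa[scores$retained_add], "Number of additions attempted"),
    desc(scores$raa[scores$retained_add], "Relative additions attempted (%)"),
    desc(scores$time_since_wake, "Time since waking up (minutes)"),
    desc(nights$duration, "Sleep duration (minutes)"),
    desc(nights$rem_pct, "REM sleep (%)"),
    desc(nights$light_pct, "Light sleep (%)"),
    desc(nights$deep_pct, "Deep sleep (%)"),
    desc(nights$sleep_debt, "Sleep debt"),
    desc(nights$sleep_shift, "Sleep shift (minutes)"))
  if (!is.null(features)) {
    out <- c(out, list(desc(features$current_hr, "Current heart rate (bpm)"),
                       desc(features$resting_hr, "Resting heart rate (bpm)"),
                       desc(features$steps_mean_10, "Steps walked, 10-min mean")))
  }
  do.call(rbind, out)
}

#' Time-of-day binned summary of a score
#'
#' Means and standard errors per time-of-day bin. Bins are aligned at
#' midnight; bins with no observations are omitted.
#'
#' @param timestamps `POSIXct` timestamps (or fractional hours).
#' @param values numeric scores, same length.
#' @param bin_hours bin width in hours (4 by default; 2 for finer summaries).
#' @return data.frame `bin_start`, `bin_end` (hours), `n`, `mean`, `sem`.
#' @export
binned_summary <- function(timestamps, values, bin_hours = 4) {
  stopifnot(bin_hours > 0, 24 %% bin_hours == 0)
  h <- if (inherits(timestamps, "POSIXct")) clock_hour(timestamps) else timestamps
  ok <- !is.na(h) & !is.na(values)
  h <- h[ok]; values <- values[ok]
  starts <- seq(0, 24 - bin_hours, by = bin_hours)
  rows <- lapply(starts, function(s) {
    v <- values[h >= s & h < s + bin_hours]
    if (length(v) == 0L) return(NULL)
    data.frame(bin_start = s, bin_end = s + bin_hours, n = length(v),
               mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.chronoperf_analysis <- function(x, ...) {
  cat("chronoperf analysis\n")
  m <- x$manifest
  cat(sprintf("  tasks: %d raw -> %d after inclusion (%d participants)\n",
              m$n_tasks_raw, m$n_tasks_included, m$n_participants_included))
  cat(sprintf("  sessions retained: %d PVT, %d ADD; %d nights\n",
              m$n_sessions_retained_pvt, m$n_sessions_retained_add, m$n_nights))
  cat("  association tables: sleep_table, momentary_table, cosinor_table\n")
  invisible(x)
}
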