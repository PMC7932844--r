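#' Readers and writers for study record formats
#'
#' Four plain-text formats cover everything the pipeline consumes:
#'
#' * `tasks.jsonl` — one JSON object per task battery (PVT + ADD session):
#'   `participant_id`, `timestamp` (ISO-8601, minute resolution),
#'   `pvt` (array of `{rt, false_start}` stimulus records, `rt` in ms),
#'   `add_attempts` (count), optional `kss` (1-9) and `caffeine_last_hour`.
#' * `sleep.csv` — one row per sleep session: `participant_id`, `start`,
#'   `end`, `minutes_asleep`, stage minutes (`rem_min`, `light_min`,
#'   `deep_min`, `awake_min`, present only for sessions longer than
#'   180 minutes), `efficiency` (0-100), `awakenings_gt5min`,
#'   `onset_latency`.
#' * `minutes.csv` — minute-level streams, wide
#'   (`participant_id,timestamp,heart_rate,calories,steps,distance,floors,resting_hr`)
#'   or long (`participant_id,timestamp,channel,value`); the dialect is
#'   auto-detected from the header.
#' * `schedule.csv` — `participant_id,date,day_type` with
#'   `day_type` in `{work, free}` for every date of the observation span.
#'
#' All timestamps are naive local time; sessions may cross midnight and a
#' sleep session belongs to the calendar date of its end (the wake-up
#' date). Missing KSS/caffeine answers stay missing and are never imputed.
#'
#' @name io-formats
NULL

#' Read task-battery sessions from JSONL
#'
#' @param path path to a JSONL file, one task battery per line.
#' @return a data.frame sorted by `(participant_id, timestamp)` with columns
#'   `participant_id`, `timestamp` (`POSIXct`), `add_attempts`, `kss`,
#'   `caffeine_last_hour`, and a list column `pvt` of per-stimulus
#'   data.frames `(rt, false_start)`.
#' @export
read_task_sessions <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0L) return(empty_task_sessions())

  recs <- vector("list", n)
  for (i in seq_len(n)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(obj) || is.null(obj$participant_id) || is.null(obj$timestamp)) {
      stop(sprintf("tasks line %d: malformed JSON record", i))
    }
    ts <- parse_iso_minute(obj$timestamp)
    if (is.na(ts)) stop(sprintf("tasks line %d: timestamp '%s' is not ISO-8601",
                                i, obj$timestamp))
    pvt <- obj$pvt
    if (is.null(pvt) || length(pvt) == 0L) {
      pvt <- data.frame(rt = numeric(0), false_start = logical(0))
    } else {
      pvt <- as.data.frame(pvt)
      if (is.null(pvt$false_start)) pvt$false_start <- FALSE
      pvt <- data.frame(rt = as.numeric(pvt$rt),
                        false_start = as.logical(pvt$false_start))
    }
    if (any(!pvt$false_start & pvt$rt <= 0)) {
      stop(sprintf("tasks line %d: non-false-start response time must be > 0", i))
    }
    add <- as.integer(obj$add_attempts)
    if (is.na(add) || add < 0) {
      stop(sprintf("tasks line %d: add_attempts must be a nonnegative count", i))
    }
    recs[[i]] <- list(
      participant_id = as.character(obj$participant_id),
      timestamp = ts,
      pvt = pvt,
      add_attempts = add,
      kss = if (is.null(obj$kss) || is.na(obj$kss)) NA_integer_ else as.integer(obj$kss),
      caffeine_last_hour = if (is.null(obj$caffeine_last_hour) ||
                               is.na(obj$caffeine_last_hour)) NA
                           else as.logical(obj$caffeine_last_hour)
    )
  }
  out <- data.frame(
    participant_id = vapply(recs, `[[`, "", "participant_id"),
    timestamp = as.POSIXct(vapply(recs, function(r) as.numeric(r$timestamp), 0),
                           origin = "1970-01-01", tz = "UTC"),
    add_attempts = vapply(recs, `[[`, 0L, "add_attempts"),
    kss = vapply(recs, `[[`, NA_integer_, "kss"),
    caffeine_last_hour = vapply(recs, function(r) as.logical(r$caffeine_last_hour), NA),
    stringsAsFactors = FALSE
  )
  out$pvt <- I(lapply(recs, `[[`, "pvt"))
  out <- out[order(out$participant_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  dup <- stats::ave(as.numeric(out$timestamp), out$participant_id,
                    FUN = function(x) c(1, diff(x)))
  if (any(dup <= 0)) {
    stop("task timestamps must be strictly increasing within a participant")
  }
  out
}

empty_task_sessions <- function() {
  out <- data.frame(participant_id = character(0),
                    timestamp = as.POSIXct(character(0), tz = "UTC"),
                    add_attempts = integer(0), kss = integer(0),
                    caffeine_last_hour = logical(0))
  out$pvt <- I(list())
  out
}

#' Write task-battery sessions to JSONL
#' @param tasks a task-session data.frame as returned by [read_task_sessions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_task_sessions <- function(tasks, path) {
  lines <- vapply(seq_len(nrow(tasks)), function(i) {
    rec <- list(
      participant_id = tasks$participant_id[i],
      timestamp = format_iso_minute(tasks$timestamp[i]),
      pvt = tasks$pvt[[i]],
      add_attempts = tasks$add_attempts[i]
    )
    if (!is.na(tasks$kss[i])) rec$kss <- tasks$kss[i]
    if (!is.na(tasks$caffeine_last_hour[i])) {
      rec$caffeine_last_hour <- tasks$caffeine_last_hour[i]
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE, dataframe = "rows", digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read sleep sessions from CSV
#'
#' Sessions are returned sorted by start time. Stage columns are optional
#' and only treated as usable (`stages_valid`) for sessions longer than
#' 180 minutes, mirroring tracker behaviour where staging needs a session
#' longer than 3 hours. Overlapping sessions of one participant are kept
#' with a warning.
#'
#' @param path path to `sleep.csv`.
#' @return data.frame with `participant_id`, `start`, `end` (`POSIXct`),
#'   `duration` (elapsed minutes), `minutes_asleep`, `rem_min`, `light_min`,
#'   `deep_min`, `awake_min`, `efficiency`, `awakenings_gt5min`,
#'   `onset_latency`, `wake_date` (`Date`) and `stages_valid` (logical).
#' @export
read_sleep_sessions <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(finish_sleep(df0 = NULL))
  start <- parse_iso_minute(df$start)
  end <- parse_iso_minute(df$end)
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("sleep row %d: timestamp is not ISO-8601",
                 which(is.na(start) | is.na(end))[1]))
  }
  if (any(end <= start)) {
    stop(sprintf("sleep row %d: end must be after start", which(end <= start)[1]))
  }
  out <- data.frame(
    participant_id = as.character(df$participant_id),
    start = start, end = end,
    duration = diff_minutes(end, start),
    minutes_asleep = num_col(df, "minutes_asleep"),
    rem_min = num_col(df, "rem_min"),
    light_min = num_col(df, "light_min"),
    deep_min = num_col(df, "deep_min"),
    awake_min = num_col(df, "awake_min"),
    efficiency = num_col(df, "efficiency"),
    awakenings_gt5min = num_col(df, "awakenings_gt5min"),
    onset_latency = num_col(df, "onset_latency"),
    stringsAsFactors = FALSE
  )
  finish_sleep(out)
}

finish_sleep <- function(df0) {
  if (is.null(df0) || nrow(df0) == 0L) {
    df0 <- data.frame(participant_id = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      duration = numeric(0), minutes_asleep = numeric(0),
                      rem_min = numeric(0), light_min = numeric(0),
                      deep_min = numeric(0), awake_min = numeric(0),
                      efficiency = numeric(0), awakenings_gt5min = numeric(0),
                      onset_latency = numeric(0))
  }
  out <- df0[order(df0$start), , drop = FALSE]
  rownames(out) <- NULL
  stage_sum <- rowSums(out[, c("rem_min", "light_min", "deep_min", "awake_min")],
                       na.rm = TRUE)
  if (any(stage_sum > out$duration + 1e-6)) {
    stop("stage minutes exceed elapsed session time")
  }
  out$wake_date <- local_date(out$end)
  out$stages_valid <- out$duration > 180 & !is.na(out$rem_min)
  for (p in unique(out$participant_id)) {
    s <- out[out$participant_id == p, , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      warning(sprintf("participant %s has overlapping sleep sessions; keeping both", p))
    }
  }
  out
}

num_col <- function(df, name) {
  if (name %in% names(df)) suppressWarnings(as.numeric(df[[name]]))
  else rep(NA_real_, nrow(df))
}

#' Write sleep sessions to CSV
#' @param sleep sleep-session data.frame (see [read_sleep_sessions()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sleep_sessions <- function(sleep, path) {
  df <- sleep[, c("participant_id", "start", "end", "minutes_asleep",
                  "rem_min", "light_min", "deep_min", "awake_min",
                  "efficiency", "awakenings_gt5min", "onset_latency")]
  df$start <- format_iso_minute(df$start)
  df$end <- format_iso_minute(df$end)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a minute-level stream from CSV
#'
#' Accepts either the wide dialect (one column per channel) or the long
#' dialect (`timestamp,channel,value`); the header decides. Duplicate
#' minutes collapse to the last-written value with a warning.
#'
#' @param path path to `minutes.csv`.
#' @return data.frame with `participant_id`, `timestamp` and the channels
#'   `heart_rate`, `calories`, `steps`, `distance`, `floors`, `resting_hr`,
#'   sorted by participant and minute.
#' @export
read_minute_stream <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  channels <- c("heart_rate", "calories", "steps", "distance", "floors", "resting_hr")
  if (nrow(df) == 0L) {
    out <- data.frame(participant_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"))
    for (ch in channels) out[[ch]] <- numeric(0)
    return(out)
  }
  long <- "channel" %in% names(df)
  ts <- parse_iso_minute(df$timestamp)
  if (anyNA(ts)) stop(sprintf("minutes row %d: bad timestamp", which(is.na(ts))[1]))
  if (long) {
    val <- suppressWarnings(as.numeric(df$value))
    if (anyNA(val) & any(is.na(val) & !(df$value %in% c("", "NA")))) {
      stop(sprintf("minutes row %d: unparseable numeric value",
                   which(is.na(val) & !(df$value %in% c("", "NA")))[1]))
    }
    wide <- stats::reshape(
      data.frame(participant_id = df$participant_id, timestamp = ts,
                 channel = df$channel, value = val, stringsAsFactors = FALSE),
      idvar = c("participant_id", "timestamp"), timevar = "channel",
      direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    df <- wide
  } else {
    for (ch in intersect(channels, names(df))) {
      v <- df[[ch]]
      val <- suppressWarnings(as.numeric(v))
      bad <- is.na(val) & !(as.character(v) %in% c("", "NA"))
      if (any(bad)) stop(sprintf("minutes row %d: unparseable numeric in '%s'",
                                 which(bad)[1], ch))
      df[[ch]] <- val
    }
    df$timestamp <- ts
  }
  for (ch in channels) if (!ch %in% names(df)) df[[ch]] <- NA_real_
  key <- paste(df$participant_id, as.numeric(df$timestamp))
  if (anyDuplicated(key)) {
    warning("duplicate minutes collapsed to last-written value")
    df <- df[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  bad_hr <- !is.na(df$heart_rate) & (df$heart_rate < 25 | df$heart_rate > 250)
  if (any(bad_hr)) stop("heart_rate outside plausible range [25, 250]")
  df <- df[order(df$participant_id, df$timestamp),
           c("participant_id", "timestamp", channels), drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a minute-level stream to CSV (wide dialect)
#' @param stream minute-stream data.frame (see [read_minute_stream()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_minute_stream <- function(stream, path) {
  df <- stream
  df$timestamp <- format_iso_minute(df$timestamp)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a work/free-day schedule from CSV
#'
#' @param path path to `schedule.csv` with columns
#'   `participant_id,date,day_type`.
#' @return data.frame `participant_id`, `date` (`Date`), `day_type`
#'   (`"work"` or `"free"`). Every date of each participant's span must be
#'   labeled (contiguous dates).
#' @export
read_schedule <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(participant_id = as.character(df$participant_id),
                    date = as.Date(df$date),
                    day_type = as.character(df$day_type),
                    stringsAsFactors = FALSE)
  if (!all(out$day_type %in% c("work", "free"))) {
    stop("schedule day_type must be 'work' or 'free'")
  }
  out <- out[order(out$participant_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  for (p in unique(out$participant_id)) {
    d <- out$date[out$participant_id == p]
    if (length(d) > 1 && any(diff(as.integer(d)) != 1L)) {
      stop(sprintf("participant %s: schedule has unlabeled dates in its span", p))
    }
  }
  out
}

#' Write a schedule to CSV
#' @param schedule schedule data.frame (see [read_schedule()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(schedule, path, row.names = FALSE)
  invisible(path)
}
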