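#' Session-level scoring of alertness and cognitive throughput
#'
#' A task battery pairs a short psychomotor vigilance test (PVT; median
#' response time over the session's stimuli, false starts ignored) with a
#' fixed-duration addition test (ADD; number of additions attempted).
#' Performance is expressed relative to each participant's own baseline:
#'
#' \deqn{RRT_{s,p} = (1 - MRT_{s,p} / \overline{MRT}_p) \times 100}
#' \deqn{RAA_{s,p} = (NAA_{s,p} / \overline{NAA}_p - 1) \times 100}
#'
#' so that higher values always mean better performance, and the mean of
#' each relative score over a participant's retained sessions is zero by
#' construction.
#'
#' Quality filters, applied per participant in this order:
#' 1. the chronologically first task battery is dropped (familiarisation);
#' 2. PVT sessions with missing MRT or MRT strictly above `mrt_threshold`
#'    (default 800 ms) are dropped;
#' 3. sessions farther than `sd_limit` (default 3) standard deviations from
#'    the mean of the survivors are dropped (strictly-greater rule, so
#'    exactly 3 SD is retained; population SD by default).
#' The ADD filter applies only steps 1 and 3 to the attempt counts (there is
#' no absolute threshold for ADD).
#'
#' @name performance-scoring
NULL

#' Median response time of one task session
#'
#' Median of the session's response times over non-false-start stimuli;
#' even-length medians are midpoint averages. Returns `NA` when the session
#' has no valid stimuli.
#'
#' @param pvt per-stimulus data.frame with columns `rt` (ms) and
#'   `false_start` (logical).
#' @return median response time in milliseconds, or `NA`.
#' @export
median_response_time <- function(pvt) {
  rt <- pvt$rt[!pvt$false_start]
  if (length(rt) == 0L) return(NA_real_)
  stats::median(rt)
}

#' Retention filter for PVT sessions
#'
#' Applies the first-instance, absolute-threshold and SD filters described
#' in [performance-scoring], per participant, to a vector of session MRTs.
#'
#' @param mrt numeric vector of session MRTs (ms), time-ordered.
#' @param first_instance logical; drop the first element (default `TRUE`).
#' @param mrt_threshold absolute cutoff in ms (strictly-greater rule).
#' @param sd_limit SD multiple for the outlier rule (strictly-greater rule).
#' @param sd_type `"population"` (default) or `"sample"` SD.
#' @return logical vector of retained flags, same length as `mrt`.
#' @export
filter_pvt <- function(mrt, first_instance = TRUE, mrt_threshold = 800,
                       sd_limit = 3, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  keep <- rep(TRUE, length(mrt))
  if (first_instance && length(mrt) > 0L) keep[1] <- FALSE
  keep <- keep & !is.na(mrt) & mrt <= mrt_threshold
  keep & !sd_outlier(mrt, keep, sd_limit, sd_type)
}

#' Retention filter for ADD sessions
#'
#' First-instance drop plus the per-participant SD rule on attempt counts;
#' no absolute threshold exists for the addition test.
#'
#' @param naa numeric vector of attempt counts, time-ordered.
#' @inheritParams filter_pvt
#' @return logical vector of retained flags.
#' @export
filter_add <- function(naa, first_instance = TRUE, sd_limit = 3,
                       sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  keep <- rep(TRUE, length(naa))
  if (first_instance && length(naa) > 0L) keep[1] <- FALSE
  keep <- keep & !is.na(naa)
  keep & !sd_outlier(naa, keep, sd_limit, sd_type)
}

# strictly-greater SD rule over the currently-kept values; zero variance
# removes nothing
sd_outlier <- function(x, keep, sd_limit, sd_type) {
  out <- rep(FALSE, length(x))
  v <- x[keep]
  if (length(v) == 0L) return(out)
  m <- mean(v)
  s <- if (sd_type == "population") {
    sqrt(mean((v - m)^2))
  } else if (length(v) > 1L) stats::sd(v) else 0
  out[keep] <- abs(x[keep] - m) > sd_limit * s
  out
}

#' Score task sessions
#'
#' Computes per-session MRT/NAA, applies the retention filters, and derives
#' the relative scores RRT and RAA against each participant's mean over
#' retained sessions.
#'
#' @param tasks task-session data.frame (see [read_task_sessions()]).
#' @param mrt_threshold,sd_limit,sd_type filter settings (see [filter_pvt()]).
#' @return data.frame with one row per session: `participant_id`,
#'   `timestamp`, `mrt`, `naa`, `retained_pvt`, `retained_add`, `rrt`,
#'   `raa` (relative scores in percent, `NA` for non-retained sessions).
#' @export
score_sessions <- function(tasks, mrt_threshold = 800, sd_limit = 3,
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  tasks <- tasks[order(tasks$participant_id, tasks$timestamp), , drop = FALSE]
  mrt <- vapply(tasks$pvt, median_response_time, 0)
  out <- data.frame(participant_id = tasks$participant_id,
                    timestamp = tasks$timestamp,
                    mrt = mrt, naa = as.numeric(tasks$add_attempts),
                    stringsAsFactors = FALSE)
  out$retained_pvt <- FALSE
  out$retained_add <- FALSE
  out$rrt <- NA_real_
  out$raa <- NA_real_
  for (p in unique(out$participant_id)) {
    i <- which(out$participant_id == p)
    kp <- filter_pvt(out$mrt[i], TRUE, mrt_threshold, sd_limit, sd_type)
    ka <- filter_add(out$naa[i], TRUE, sd_limit, sd_type)
    if (!any(kp)) warning(sprintf("participant %s: no PVT sessions survive the filters", p))
    out$retained_pvt[i] <- kp
    out$retained_add[i] <- ka
    if (any(kp)) {
      base <- mean(out$mrt[i][kp])
      out$rrt[i][kp] <- (1 - out$mrt[i][kp] / base) * 100
    }
    if (any(ka)) {
      base <- mean(out$naa[i][ka])
      out$raa[i][ka] <- (out$naa[i][ka] / base - 1) * 100
    }
  }
  rownames(out) <- NULL
  out
}

#' Study-inclusion filter on completed task count
#'
#' Participants who completed fewer than `min_tasks` task batteries over
#' the study period (default 42, an average of one per day over six weeks)
#' are excluded from all downstream analyses. The count is of completed
#' batteries, before session-level quality filters.
#'
#' @param tasks task-session data.frame (one row per completed battery).
#' @param min_tasks inclusion threshold; `count < min_tasks` excludes.
#' @return character vector of retained participant ids.
#' @export
include_participants <- function(tasks, min_tasks = 42) {
  counts <- table(tasks$participant_id)
  keep <- names(counts)[counts >= min_tasks]
  if (length(keep) == 0L) stop("no participants meet the task-count inclusion criterion")
  keep
}

#' Daily relative scores
#'
#' Per participant and calendar day (local midnight to midnight): the
#' median MRT and median NAA over that day's retained sessions, expressed
#' relative to the participant's across-days average of daily medians using
#' the same functional forms as the session-level relative scores.
#'
#' @param scores session scores from [score_sessions()].
#' @return data.frame `participant_id`, `date`, `daily_median_mrt`,
#'   `daily_median_naa`, `rel_daily_rrt`, `rel_daily_raa`.
#' @export
daily_relative_scores <- function(scores) {
  scores$date <- local_date(scores$timestamp)
  res <- list()
  for (p in unique(scores$participant_id)) {
    s <- scores[scores$participant_id == p, , drop = FALSE]
    dates <- sort(unique(s$date[s$retained_pvt | s$retained_add]))
    if (length(dates) == 0L) next
    med_mrt <- vapply(dates, function(d)
      safe_median(s$mrt[s$date == d & s$retained_pvt]), 0)
    med_naa <- vapply(dates, function(d)
      safe_median(s$naa[s$date == d & s$retained_add]), 0)
    base_mrt <- mean(med_mrt, na.rm = TRUE)
    base_naa <- mean(med_naa, na.rm = TRUE)
    res[[p]] <- data.frame(
      participant_id = p, date = dates,
      daily_median_mrt = med_mrt, daily_median_naa = med_naa,
      rel_daily_rrt = (1 - med_mrt / base_mrt) * 100,
      rel_daily_raa = (med_naa / base_naa - 1) * 100,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

safe_median <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else stats::median(x)
}
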