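#' Clock-time helpers
#'
#' Small utilities for working with times of day on the 24-hour circle.
#' All timestamps in this package are naive local times at minute resolution
#' (consumer-tracker exports carry no timezone); internally they are stored
#' as `POSIXct` in UTC so that daylight-saving transitions never enter the
#' arithmetic.
#'
#' @name clock-helpers
#' @keywords internal
NULL

#' Wrap a value in hours onto \[0, 24)
#' @param h numeric hours (any real value).
#' @return hours wrapped onto the 24 h circle.
#' @export
wrap24 <- function(h) {
  h %% 24
}

#' Hour of day of a timestamp
#' @param t `POSIXct` timestamp(s).
#' @return fractional hours since local midnight, in \[0, 24).
#' @keywords internal
clock_hour <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Circular mean of clock times
#'
#' Mean direction of times of day on the 24 h circle. A configuration
#' switch in [chronotype_msf()] exposes the alternative naive linear mean
#' anchored at 12:00 (values below 12:00 are counted as next-day).
#'
#' @param h numeric vector of hours in \[0, 24).
#' @param method `"circular"` (mean direction) or `"linear"` (anchored mean).
#' @return a single hour in \[0, 24).
#' @export
circular_mean_hours <- function(h, method = c("circular", "linear")) {
  method <- match.arg(method)
  h <- h[!is.na(h)]
  if (length(h) == 0L) return(NA_real_)
  if (method == "linear") {
    return(wrap24(mean(ifelse(h < 12, h + 24, h))))
  }
  theta <- h * 2 * pi / 24
  wrap24(atan2(mean(sin(theta)), mean(cos(theta))) * 24 / (2 * pi))
}

#' Format fractional hours as hh:mm
#'
#' Renders an hour value on \[0, 24) as `"hh:mm"`, flooring to the whole
#' minute (`23.999` becomes `"23:59"`).
#'
#' @param h fractional hours.
#' @return character vector of `"hh:mm"` strings.
#' @export
format_hhmm <- function(h) {
  m <- floor(wrap24(h) * 60)
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

# Parse "YYYY-mm-ddTHH:MM[:SS]" (ISO-8601, naive local) to POSIXct/UTC.
# Returns NA for unparseable input; callers decide whether that is an error.
parse_iso_minute <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- as.POSIXct(strptime(x[miss], "%Y-%m-%d %H:%M", tz = "UTC"))
  }
  out
}

format_iso_minute <- function(t) {
  format(t, "%Y-%m-%dT%H:%M", tz = "UTC")
}

# difference t2 - t1 in minutes
diff_minutes <- function(t2, t1) {
  as.numeric(difftime(t2, t1, units = "mins"))
}

# calendar date (Date) of a naive timestamp
local_date <- function(t) {
  as.Date(t, tz = "UTC")
}
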