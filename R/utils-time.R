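# Local civil time convention: every datetime in the package is a POSIXct
# carrying tz = "UTC", whose wall-clock rendering IS the local civil time of
# the recording (epoch-ms inputs are shifted by their declared UTC offset on
# read).  All clock rules (noon-to-noon cycles, the 25-h linearization) are
# local-time rules, so a fixed offset per recording is assumed throughout.

ts_tz <- "UTC"

as_local_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- ts_tz
    return(x)
  }
  as.POSIXct(x, tz = ts_tz)
}

local_datetime <- function(date, clock_hours) {
  as_local_time(as.POSIXct(as.Date(date), tz = ts_tz)) + clock_hours * 3600
}

#' Hours since local midnight
#' @param t a POSIXct datetime (local civil time).
#' @return numeric hours of day in `[0, 24)`.
#' @keywords internal
clock_hours_of <- function(t) {
  s <- as.numeric(t) %% 86400
  s / 3600
}

# Noon-to-noon cycle id: the calendar date of the noon that starts the cycle.
# A nocturnal sleep episode (onset in the evening, wake the next morning)
# always falls inside a single cycle.
cycle_of <- function(t) {
  as.Date(as_local_time(t) - 12 * 3600, tz = ts_tz)
}

cycle_noon <- function(cycle_date) {
  local_datetime(cycle_date, 12)
}

# Parse "HH:MM"/"HH:MM:SS" into fractional hours.
parse_clock <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    p[1] + p[2] / 60 + if (length(p) >= 3) p[3] / 3600 else 0
  }, numeric(1))
}

fmt_iso <- function(t) format(as_local_time(t), "%Y-%m-%dT%H:%M:%OS3")

parse_iso <- function(x) as.POSIXct(x, tz = ts_tz, format = "%Y-%m-%dT%H:%M:%OS")

# Length of the intersection of two half-open intervals, in minutes.
overlap_minutes <- function(a_start, a_end, b_start, b_end) {
  pmax(0, as.numeric(pmin(a_end, b_end)) - as.numeric(pmax(a_start, b_start))) / 60
}
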