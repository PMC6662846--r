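#' Column mapping for actigraphy CSV exports
#'
#' Describes how the columns of a vendor CSV map onto the channels the
#' pipeline needs.  The canonical dialect uses columns `time`, `ax`, `ay`,
#' `az`, `light_lux`, `temp_c` with ISO-8601 datetimes, '.' decimals and
#' acceleration in g.
#'
#' @param time,ax,ay,az,light,temperature column names in the file.
#' @param units one of `"g"` (default) or `"ms2"`; `"ms2"` inputs are
#'   divided by 9.81 on read.
#' @param sample_rate_hz declared sampling rate (Hz); `NULL` (default)
#'   infers it from the median time step.
#' @return a named list usable as the `dialect` argument of
#'   [read_actigraphy()].
#' @export
actigraphy_dialect <- function(time = "time", ax = "ax", ay = "ay", az = "az",
                               light = "light_lux", temperature = "temp_c",
                               units = c("g", "ms2"), sample_rate_hz = NULL) {
  units <- match.arg(units)
  list(time = time, ax = ax, ay = ay, az = az, light = light,
       temperature = temperature, units = units,
       sample_rate_hz = sample_rate_hz)
}

new_actigraphy_recording <- function(time, ax, ay, az, light, temperature,
                                     sample_rate, missing_intervals = NULL) {
  n <- length(time)
  stopifnot(length(ax) == n, length(ay) == n, length(az) == n,
            length(light) == n, length(temperature) == n, sample_rate > 0)
  out <- tibble::tibble(
    time = as_local_time(time),
    ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
    light = as.numeric(light), temperature = as.numeric(temperature)
  )
  attr(out, "sample_rate") <- sample_rate
  attr(out, "missing_intervals") <- missing_intervals %||%
    tibble::tibble(start = as_local_time(numeric(0)),
                   end = as_local_time(numeric(0)))
  class(out) <- c("actigraphy_recording", class(out))
  out
}

#' Read a raw actigraphy recording from CSV
#'
#' Reads tri-axial wrist acceleration plus ambient light and near-body
#' temperature.  Time must be strictly increasing; runs of missing samples
#' (time steps larger than 2 sample periods) are recorded as missing-data
#' intervals and later masked out of the per-minute activity series.
#'
#' @param path path to a CSV file.
#' @param dialect column mapping, see [actigraphy_dialect()].
#' @return a tibble of class `actigraphy_recording` with columns `time`,
#'   `ax`, `ay`, `az`, `light`, `temperature` and attributes `sample_rate`
#'   and `missing_intervals`.
#' @export
read_actigraphy <- function(path, dialect = actigraphy_dialect()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c(time = dialect$time, ax = dialect$ax, ay = dialect$ay,
              az = dialect$az, light = dialect$light,
              temperature = dialect$temperature)
  missing_cols <- needed[!needed %in% names(df)]
  if (length(missing_cols) > 0) {
    abort(sprintf("actigraphy file is missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "tapsleep_format_error")
  }
  t <- df[[dialect$time]]
  if (is.character(t)) t <- parse_iso(t)
  t <- as_local_time(t)
  if (anyNA(t)) {
    abort("actigraphy time column contains unparseable values",
          class = "tapsleep_format_error")
  }
  dt <- diff(as.numeric(t))
  if (any(dt <= 0)) {
    abort(sprintf("actigraphy time must be strictly increasing (first violation at row %d)",
                  which(dt <= 0)[1] + 1L),
          class = "tapsleep_format_error")
  }
  rate <- dialect$sample_rate_hz %||% round(1 / median(dt), 3)
  period <- 1 / rate
  gap_idx <- which(dt > 2 * period)
  gaps <- tibble::tibble(
    start = t[gap_idx] + period,
    end = t[gap_idx + 1L]
  )
  conv <- if (dialect$units == "ms2") 1 / 9.81 else 1
  new_actigraphy_recording(
    time = t,
    ax = df[[dialect$ax]] * conv, ay = df[[dialect$ay]] * conv,
    az = df[[dialect$az]] * conv,
    light = df[[dialect$light]], temperature = df[[dialect$temperature]],
    sample_rate = rate, missing_intervals = gaps
  )
}

#' Write an actigraphy recording to CSV (canonical dialect)
#' @param recording an `actigraphy_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_actigraphy <- function(recording, path) {
  out <- tibble::tibble(
    time = fmt_iso(recording$time),
    ax = recording$ax, ay = recording$ay, az = recording$az,
    light_lux = recording$light, temp_c = recording$temperature
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

new_touch_log <- function(time, timezone_offset_min = 0, n_duplicates = 0L,
                          was_sorted = TRUE) {
  out <- tibble::tibble(time = as_local_time(time))
  attr(out, "timezone_offset_min") <- timezone_offset_min
  attr(out, "n_duplicates") <- n_duplicates
  class(out) <- c("touch_log", class(out))
  out
}

#' Build a touch log from local-time touch instants
#' @param time POSIXct vector of touchscreen event times (local civil time).
#' @return a tibble of class `touch_log`, sorted, with duplicate count
#'   recorded in attribute `n_duplicates`.
#' @export
touch_log <- function(time) {
  time <- as_local_time(time)
  n_dup <- sum(duplicated(as.numeric(time)))
  new_touch_log(sort(time), n_duplicates = n_dup)
}

#' Read a smartphone touch log
#'
#' Canonical format is plain text with one epoch-millisecond integer per
#' line; a CSV with a `timestamp_ms` column is also accepted.  Timestamps
#' are converted to local civil time using `timezone_offset_min` and sorted
#' (with a warning if the input was unsorted).  Duplicate timestamps
#' (multi-finger touches) are kept but counted.
#'
#' @param path path to the file.
#' @param timezone_offset_min UTC offset of the device, in minutes.
#' @return a tibble of class `touch_log` with a `time` column and attributes
#'   `timezone_offset_min` and `n_duplicates`.
#' @export
read_touchlog <- function(path, timezone_offset_min = 0) {
  first <- readr::read_lines(path, n_max = 1)
  is_csv <- length(first) > 0 && grepl("timestamp_ms", first[1], fixed = TRUE)
  if (is_csv) {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!"timestamp_ms" %in% names(df)) {
      abort("touch log CSV lacks a 'timestamp_ms' column",
            class = "tapsleep_format_error")
    }
    ms <- df$timestamp_ms
    if (!is.numeric(ms) || anyNA(ms)) {
      abort("touch log 'timestamp_ms' column is not numeric",
            class = "tapsleep_format_error")
    }
  } else {
    lines <- readr::read_lines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      return(new_touch_log(numeric(0), timezone_offset_min))
    }
    ms <- suppressWarnings(as.numeric(lines))
    bad <- which(is.na(ms) | ms != floor(ms))
    if (length(bad) > 0) {
      abort(sprintf("touch log line %d is not an integer epoch-millisecond value: '%s'",
                    bad[1], lines[bad[1]]),
            class = "tapsleep_format_error")
    }
  }
  if (is.unsorted(ms)) {
    warn("touch log timestamps were not sorted; sorting")
    ms <- sort(ms)
  }
  time <- as_local_time(as.POSIXct(ms / 1000, origin = "1970-01-01", tz = ts_tz) +
                          timezone_offset_min * 60)
  new_touch_log(time, timezone_offset_min = timezone_offset_min,
                n_duplicates = sum(duplicated(ms)))
}

#' Write a touch log as one epoch-millisecond integer per line
#' @param log a `touch_log`.
#' @param path output path.
#' @param timezone_offset_min UTC offset used to convert local times back to
#'   epoch milliseconds; defaults to the offset stored on the log.
#' @return `path`, invisibly.
#' @export
write_touchlog <- function(log, path, timezone_offset_min = NULL) {
  off <- timezone_offset_min %||% attr(log, "timezone_offset_min") %||% 0
  ms <- round(as.numeric(log$time) * 1000) - off * 60000
  readr::write_lines(sprintf("%.0f", ms), path)
  invisible(path)
}

#' Read a sleep diary CSV
#'
#' Expects columns `date`, `report_time`, `sleep_time`, `wake_time`
#' (optionally `bed_time`, `outbed_time`).  At most one entry per calendar
#' day is kept; extra entries are dropped with a warning.
#'
#' @param path path to the CSV.
#' @return a tibble with one row per day: `date` (Date), `report_time`
#'   (POSIXct), `sleep_time`, `wake_time` (fractional clock hours).
#' @export
read_diary <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("date", "report_time", "sleep_time", "wake_time")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("diary file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "tapsleep_format_error")
  }
  df$date <- as.Date(df$date)
  dup <- duplicated(df$date)
  if (any(dup)) {
    warn(sprintf("diary has %d extra entries on already-reported days; keeping the first entry per day",
                 sum(dup)))
    df <- df[!dup, ]
  }
  tibble::tibble(
    date = df$date,
    report_time = parse_iso(as.character(df$report_time)),
    sleep_time = parse_clock(df$sleep_time),
    wake_time = parse_clock(df$wake_time)
  )
}

#' Write a diary table to CSV
#' @param diary tibble as returned by [read_diary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diary <- function(diary, path) {
  out <- tibble::tibble(
    date = as.character(diary$date),
    report_time = fmt_iso(diary$report_time),
    sleep_time = sprintf("%02d:%02d", floor(diary$sleep_time) %% 24,
                         round((diary$sleep_time %% 1) * 60)),
    wake_time = sprintf("%02d:%02d", floor(diary$wake_time) %% 24,
                        round((diary$wake_time %% 1) * 60))
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Construct a night table
#'
#' One row per (night, source): the per-cycle sleep window selected by one
#' of the estimation pipelines.  `night_id` is the calendar date of the noon
#' that starts the noon-to-noon cycle the window belongs to.
#'
#' @param night_id Date vector of cycle dates.
#' @param source character: `"actigraphy"`, `"tappigraphy"` or `"diary"`.
#' @param onset,wake POSIXct local datetimes, `wake > onset`.
#' @param veto_flags character, comma-separated flag names (`""` if none).
#' @param overlap_min minutes of overlap with the circadian low-activity
#'   window (`NA` if not evaluated).
#' @return a tibble of class `night_table`.
#' @export
night_table <- function(night_id = as.Date(character(0)),
                        source = character(0),
                        onset = as_local_time(numeric(0)),
                        wake = as_local_time(numeric(0)),
                        veto_flags = character(0),
                        overlap_min = numeric(0)) {
  onset <- as_local_time(onset)
  wake <- as_local_time(wake)
  if (any(wake <= onset)) {
    abort("night table requires wake > onset for every row",
          class = "tapsleep_value_error")
  }
  dur <- as.numeric(wake - onset, units = "hours")
  if (any(dur >= 24)) {
    abort("night table durations must be < 24 h",
          class = "tapsleep_value_error")
  }
  if (length(veto_flags) == 0 && length(onset) > 0) {
    veto_flags <- rep("", length(onset))
  }
  if (length(overlap_min) == 0 && length(onset) > 0) {
    overlap_min <- rep(NA_real_, length(onset))
  }
  out <- tibble::tibble(
    night_id = as.Date(night_id), source = as.character(source),
    onset = onset, wake = wake, duration_h = dur,
    veto_flags = as.character(veto_flags), overlap_min = overlap_min
  )
  class(out) <- c("night_table", class(out))
  out
}

#' Write a night table to CSV
#'
#' Fixed column order `night_id, source, onset_iso, wake_iso, duration_h,
#' veto_flags, overlap_min`; round-trips losslessly through
#' [read_night_table()] at millisecond precision.
#'
#' @param nights a `night_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_night_table <- function(nights, path) {
  out <- tibble::tibble(
    night_id = as.character(nights$night_id),
    source = nights$source,
    onset_iso = fmt_iso(nights$onset),
    wake_iso = fmt_iso(nights$wake),
    duration_h = nights$duration_h,
    veto_flags = nights$veto_flags,
    overlap_min = nights$overlap_min
  )
  readr::write_csv(out, path, progress = FALSE, na = "")
  invisible(path)
}

#' Read a night table written by [write_night_table()]
#' @param path path to the CSV.
#' @return a `night_table` tibble.
#' @export
read_night_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          night_id = readr::col_character(),
                          source = readr::col_character(),
                          onset_iso = readr::col_character(),
                          wake_iso = readr::col_character(),
                          duration_h = readr::col_double(),
                          veto_flags = readr::col_character(),
                          overlap_min = readr::col_double()
                        ))
  night_table(
    night_id = as.Date(df$night_id), source = df$source,
    onset = parse_iso(df$onset_iso), wake = parse_iso(df$wake_iso),
    veto_flags = dplyr::coalesce(df$veto_flags, ""),
    overlap_min = df$overlap_min
  )
}
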