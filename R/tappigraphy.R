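new_touch_binary <- function(bin_start, active) {
  out <- tibble::tibble(bin_start = as_local_time(bin_start),
                        active = as.integer(active))
  class(out) <- c("touch_binary", class(out))
  out
}

#' Binarize a touch log into 60-s active/rest states
#'
#' A bin is active (1) iff at least one touch timestamp falls inside
#' `[bin_start, bin_start + bin_seconds)`; any number of touches in one bin
#' still gives a single active state.  The grid is aligned to clock minutes
#' and spans the observation window.
#'
#' @param log a `touch_log`.
#' @param span optional POSIXct length-2 vector giving the observation span;
#'   defaults to the span of the log itself (first touch floored, last touch
#'   ceiled to the bin grid).
#' @param bin_seconds bin width, default 60 s.
#' @return a tibble of class `touch_binary` with columns `bin_start`,
#'   `active` (0/1).
#' @export
binarize_touches <- function(log, span = NULL, bin_seconds = 60) {
  t <- as.numeric(log$time)
  if (is.null(span)) {
    if (length(t) == 0) {
      abort("cannot binarize an empty touch log without an explicit span",
            class = "tapsleep_data_error")
    }
    span <- c(floor(t[1] / bin_seconds), ceiling((t[length(t)] + 1e-9) / bin_seconds))
  } else {
    span <- c(floor(as.numeric(span[1]) / bin_seconds),
              ceiling(as.numeric(span[2]) / bin_seconds))
  }
  n_bins <- span[2] - span[1]
  if (n_bins < 1) {
    abort("empty observation span", class = "tapsleep_data_error")
  }
  idx <- floor(t / bin_seconds) - span[1]
  idx <- idx[idx >= 0 & idx < n_bins]
  active <- integer(n_bins)
  active[unique(idx) + 1L] <- 1L
  new_touch_binary((span[1] + seq_len(n_bins) - 1) * bin_seconds, active)
}

#' Relabel brief isolated activity as rest (5%-in-an-hour rule)
#'
#' Each active bin is examined in a centered sliding window of
#' `window_min` minutes on the original series: if strictly less than
#' `frac_threshold` of the window's bins are active (for the defaults,
#' at most 2 active bins in 60), the bin is relabelled rest.  A single
#' pass; the rule never creates activity.  At the series edges the window
#' is truncated and the fraction is taken over the available bins.
#'
#' @param series a `touch_binary` on a 60-s grid.
#' @param frac_threshold active fraction below which a bin is isolated,
#'   default 0.05.
#' @param window_min window length in minutes, default 60.
#' @return a `touch_binary` with isolated activity relabelled rest.
#' @export
smooth_to_rest <- function(series, frac_threshold = 0.05, window_min = 60) {
  a <- series$active
  n <- length(a)
  w <- window_min
  lo <- floor((w - 1) / 2)          # bins before, 29 for w = 60
  hi <- w - 1 - lo                  # bins after, 30 for w = 60
  cs <- c(0L, cumsum(a))
  i <- seq_len(n)
  from <- pmax(1L, i - lo)
  to <- pmin(n, i + hi)
  n_active <- cs[to + 1L] - cs[from]
  n_avail <- to - from + 1L
  isolated <- a == 1L & (n_active / n_avail) < frac_threshold
  out <- series
  out$active <- ifelse(isolated, 0L, a)
  out
}

#' Extract usage gaps longer than a threshold
#'
#' Maximal runs of rest bins strictly longer than `min_gap_h` become gaps
#' (half-open intervals).  The observation span is treated as
#' active-bounded: rest runs touching the first or last bin of the series
#' are not gaps, so a gap can neither begin before the first observed
#' activity nor end after the last.
#'
#' @param series a (smoothed) `touch_binary`.
#' @param min_gap_h minimum gap length in hours (strict), default 2.
#' @return a tibble with columns `start`, `end`, `length_h`.
#' @export
extract_gaps <- function(series, min_gap_h = 2) {
  a <- series$active
  n <- length(a)
  bin_s <- if (n >= 2) {
    as.numeric(series$bin_start[2]) - as.numeric(series$bin_start[1])
  } else 60
  r <- rle(a == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_gap <- r$values &
    starts > 1L & ends < n &                       # active-bounded edges
    (r$lengths * bin_s / 3600) > min_gap_h
  start <- series$bin_start[starts[is_gap]]
  end <- series$bin_start[ends[is_gap]] + bin_s
  tibble::tibble(start = start, end = end,
                 length_h = as.numeric(end - start, units = "hours"))
}

#' Select the nightly sleep gap per cycle
#'
#' Each gap is assigned to the noon-to-noon cycle containing its midpoint.
#' Gaps overlapping that cycle's 6-h circadian low-activity window by at
#' least `min_overlap_min` minutes (inclusive) qualify; the longest
#' qualifying gap of each cycle is labelled sleep (ties: larger overlap,
#' then earlier start).
#'
#' @param gaps tibble from [extract_gaps()].
#' @param low_windows tibble from [low_activity_windows()].
#' @param min_overlap_min minimum overlap in minutes, default 36.
#' @return a [night_table()] with `source = "tappigraphy"`.
#' @export
select_sleep_gap <- function(gaps, low_windows, min_overlap_min = 36) {
  if (nrow(gaps) == 0) return(night_table())
  mid <- gaps$start + as.numeric(gaps$end - gaps$start) / 2
  gaps$cycle <- cycle_of(mid)
  g <- dplyr::inner_join(gaps, low_windows, by = "cycle",
                         suffix = c("", ".lw"))
  if (nrow(g) == 0) return(night_table())
  g$overlap_min <- overlap_minutes(g$start, g$end, g$start.lw, g$end.lw)
  g <- g[g$overlap_min >= min_overlap_min, , drop = FALSE]
  if (nrow(g) == 0) return(night_table())
  g <- g |>
    dplyr::group_by(.data$cycle) |>
    dplyr::arrange(dplyr::desc(.data$length_h),
                   dplyr::desc(.data$overlap_min), .data$start,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  night_table(night_id = g$cycle, source = rep("tappigraphy", nrow(g)),
              onset = g$start, wake = g$end,
              veto_flags = rep("", nrow(g)), overlap_min = g$overlap_min)
}

#' Full tappigraphy sleep pipeline
#'
#' Touch log to night table: 60-s binarization, 5%-per-hour smoothing,
#' >2 h gap extraction, cosinor fit on binned touch counts, per-cycle 6-h
#' low-activity windows, and maximal-overlapping-gap selection.
#'
#' @param log a `touch_log`.
#' @param config a [tapsleep_config()] list.
#' @return a list of class `tapsleep_tappigraphy` with elements `nights`,
#'   `binary`, `smoothed`, `gaps`, `cosinor` and `low_windows`.
#' @export
tappigraphy_sleep <- function(log, config = tapsleep_config()) {
  binary <- binarize_touches(log, bin_seconds = config$tap.bin_seconds)
  smoothed <- smooth_to_rest(binary, config$tap.smooth_frac,
                             config$tap.smooth_window_min)
  gaps <- extract_gaps(smoothed, config$tap.min_gap_hours)
  counts <- touch_count_series(log, config$cosinor.bin_minutes)
  fit <- cosinor_fit(counts)
  cycles <- sort(unique(cycle_of(binary$bin_start)))
  low <- if (isTRUE(config$cosinor.per_cycle)) {
    per_cycle_low_windows(counts, cycles)
  } else {
    low_activity_windows(fit, cycles)
  }
  nights <- select_sleep_gap(gaps, low, config$tap.min_overlap_min)
  structure(list(nights = nights, binary = binary, smoothed = smoothed,
                 gaps = gaps, cosinor = fit, low_windows = low),
            class = "tapsleep_tappigraphy")
}
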