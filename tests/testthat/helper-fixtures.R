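# Builders and independent brute-force oracles used across the suite.
# Oracles are deliberately naive (explicit loops / exhaustive scans) and
# share no code with the implementation they check.

loc_t <- function(x) as.POSIXct(x, tz = "UTC")

# Activity series on a 1-min grid starting at `start`.
make_activity <- function(counts, start = "2024-03-04 12:00:00") {
  minute <- loc_t(start) + 60 * (seq_along(counts) - 1)
  out <- tibble::tibble(minute = minute, counts = as.numeric(counts),
                        missing = is.na(counts),
                        light_median = NA_real_, temp_median = NA_real_)
  class(out) <- c("activity_series", class(out))
  out
}

make_scores <- function(asleep, start = "2024-03-04 12:00:00") {
  tibble::tibble(minute = loc_t(start) + 60 * (seq_along(asleep) - 1),
                 asleep = asleep)
}

make_binary <- function(active, start = "2024-03-04 12:00:00") {
  out <- tibble::tibble(bin_start = loc_t(start) + 60 * (seq_along(active) - 1),
                        active = as.integer(active))
  class(out) <- c("touch_binary", class(out))
  out
}

make_touches <- function(times) {
  touch_log(loc_t(times))
}

# --- oracles -------------------------------------------------------------

# Direct 7-term weighted sum, one minute at a time.
oracle_d <- function(counts, weights, scale) {
  n <- length(counts)
  d <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    if (t - 4 < 1 || t + 2 > n) next
    acc <- 0
    for (k in -4:2) acc <- acc + weights[k + 5] * counts[t + k]
    d[t] <- scale * acc
  }
  d
}

# Exhaustive scan for candidate periods: enumerate all (start, end) runs of
# sleep minutes, merge across interruptions <= tol by transitive closure,
# then filter by length.
oracle_candidates <- function(sleep, min_dur, tol) {
  n <- length(sleep)
  runs <- list()
  i <- 1
  while (i <= n) {
    if (sleep[i]) {
      j <- i
      while (j < n && sleep[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(runs) == 0) return(matrix(numeric(0), ncol = 2))
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] - 1 <= tol) {
      merged[[length(merged)]] <- c(last[1], r[2])
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  keep <- Filter(function(r) r[2] - r[1] + 1 >= min_dur, merged)
  if (length(keep) == 0) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, keep)
}

# Exhaustive rest-run scan for usage gaps (strict > min_len bins), interior
# runs only.
oracle_gaps <- function(active, min_len_bins) {
  n <- length(active)
  out <- list()
  i <- 1
  while (i <= n) {
    if (active[i] == 0) {
      j <- i
      while (j < n && active[j + 1] == 0) j <- j + 1
      if (i > 1 && j < n && (j - i + 1) > min_len_bins) {
        out[[length(out) + 1]] <- c(i, j)
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (length(out) == 0) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, out)
}

# Exhaustive minimal-integral 6-h window of a fitted sinusoid, scanned on a
# 1-min grid of window starts over one period.
oracle_low_window_start <- function(mesor, amplitude, acrophase_h,
                                    length_h = 6) {
  starts <- seq(0, 24 - 1 / 60, by = 1 / 60)
  integrand <- function(s) {
    tt <- seq(s, s + length_h, by = 1 / 600)
    sum(mesor + amplitude * cos(2 * pi * (tt - acrophase_h) / 24))
  }
  vals <- vapply(starts, integrand, numeric(1))
  starts[which.min(vals)]
}

# Independent IRLS with Tukey bisquare weights.
oracle_bisquare <- function(x, y, c_tune = 4.685, iter = 60) {
  beta <- coef(lm(y ~ x))
  for (k in seq_len(iter)) {
    r <- y - beta[1] - beta[2] * x
    s <- median(abs(r - median(r))) / 0.6745
    if (s == 0) break
    u <- r / (c_tune * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    fit <- lm(y ~ x, weights = w)
    new_beta <- coef(fit)
    if (max(abs(new_beta - beta)) < 1e-10) { beta <- new_beta; break }
    beta <- new_beta
  }
  unname(beta)
}

# Direct per-minute tally for the touch-by-D histogram.
oracle_touch_hist <- function(d_vals, minute_keys, touch_minute_keys,
                              step = 0.25, cap = 7) {
  n_bins <- round(cap / step) + 1
  n_minutes <- integer(n_bins); n_touch <- integer(n_bins)
  for (i in seq_along(d_vals)) {
    if (is.na(d_vals[i])) next
    b <- if (d_vals[i] >= cap) n_bins else floor(d_vals[i] / step) + 1
    n_minutes[b] <- n_minutes[b] + 1L
    if (minute_keys[i] %in% touch_minute_keys) n_touch[b] <- n_touch[b] + 1L
  }
  ifelse(n_minutes > 0, n_touch / n_minutes, 0)
}
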