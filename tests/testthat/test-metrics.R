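test_that("clock linearization shifts pre-10am times by 24 h", {
  expect_equal(linearize_clock("01:00"), 25)
  expect_equal(linearize_clock("23:00"), 23)
  expect_equal(linearize_clock("09:59"), 9 + 59 / 60 + 24)
  expect_equal(linearize_clock("10:00"), 10)
  expect_equal(linearize_clock(loc_t("2024-03-05 00:30:00")), 24.5)

  # injective and order-preserving along a night 22:00 -> 09:00
  h <- c(22, 23, 23.9, 0.1, 3, 8.9)
  lin <- linearize_clock(h)
  expect_true(all(diff(lin) > 0))
  expect_equal(length(unique(lin)), length(h))
})

sleep_window <- function(onset, wake, id = as.Date("2024-03-04")) {
  night_table(night_id = id, source = "actigraphy",
              onset = loc_t(onset), wake = loc_t(wake))
}

test_that("sleep fracture fraction matches its defining worked examples", {
  w <- sleep_window("2024-03-04 23:00:00", "2024-03-05 07:00:00")
  # touch-free night
  sff1 <- sleep_fracture_fraction(w, touch_log(loc_t(character(0))))
  expect_equal(sff1$sff, 1)
  expect_equal(sff1$n_interrupting_touches, 0)
  # single touch at the midpoint
  sff2 <- sleep_fracture_fraction(w, make_touches("2024-03-05 03:00:00"))
  expect_equal(sff2$sff, 0.5)
  expect_equal(sff2$n_interrupting_touches, 1)
  # touches every hour through 8 h -> longest clean stretch is 1 h
  hourly <- loc_t("2024-03-04 23:00:00") + 3600 * (1:7)
  sff3 <- sleep_fracture_fraction(w, touch_log(hourly))
  expect_equal(sff3$sff, 1 / 8)
  # touches exactly at the boundaries are not interior
  sff4 <- sleep_fracture_fraction(
    w, make_touches(c("2024-03-04 23:00:00", "2024-03-05 07:00:00")))
  expect_equal(sff4$sff, 1)
})

test_that("SFF sub-intervals conserve the window duration", {
  set.seed(601)
  for (rep_i in 1:30) {
    o <- loc_t("2024-03-04 23:00:00")
    dur <- runif(1, 2, 10) * 3600
    inside <- sort(o + runif(sample(0:20, 1), 1, dur - 1))
    w <- sleep_window("2024-03-04 23:00:00",
                      format(o + dur, "%Y-%m-%d %H:%M:%OS3"))
    seg <- diff(c(as.numeric(o), as.numeric(inside), as.numeric(o) + dur))
    expect_equal(sum(seg), dur, tolerance = 1e-6)
    got <- sleep_fracture_fraction(w, touch_log(inside))
    expect_equal(got$sff, max(seg) / dur, tolerance = 1e-6)
    expect_true(got$sff > 0 && got$sff <= 1)
  }
})

test_that("touch-by-D histogram equals the per-minute tally oracle", {
  set.seed(602)
  for (rep_i in 1:20) {
    n <- sample(100:400, 1)
    counts <- rexp(n, 1 / 40)
    d <- cole_kripke_d(make_activity(counts))
    touched <- sample(n, size = floor(n / 4))
    touches <- touch_log(d$minute[touched] + runif(length(touched), 0, 59))
    got <- touch_by_d_histogram(d, touches)
    want <- oracle_touch_hist(d$d, floor(as.numeric(d$minute) / 60),
                              unique(floor(as.numeric(touches$time) / 60)))
    expect_equal(got$p_touch, want, tolerance = 1e-12)
    # law of total probability: bin-weighted mean equals overall rate
    defined <- !is.na(d$d)
    overall <- mean(floor(as.numeric(d$minute[defined]) / 60) %in%
                      floor(as.numeric(touches$time) / 60))
    expect_equal(sum(got$p_touch * got$n_minutes) / sum(got$n_minutes),
                 overall, tolerance = 1e-12)
  }
})

test_that("touch-by-D histogram handles the degenerate cases", {
  d <- cole_kripke_d(make_activity(rep(0, 50)))
  expect_true(all(touch_by_d_histogram(d, touch_log(loc_t(character(0))))$p_touch == 0))
  # all defined minutes have D = 0 and all carry touches
  touches <- touch_log(d$minute[5:48] + 1)
  hist <- touch_by_d_histogram(d, touches)
  expect_equal(hist$p_touch[1], 1)
  expect_true(all(hist$p_touch[-1] == 0))
  expect_equal(sum(hist$n_minutes), 44)
})

test_that("night pairing matches cycles and linearizes across midnight", {
  x <- night_table(night_id = as.Date(c("2024-03-04", "2024-03-05", "2024-03-06")),
                   source = rep("actigraphy", 3),
                   onset = loc_t(c("2024-03-04 23:30:00", "2024-03-05 23:00:00",
                                   "2024-03-06 23:15:00")),
                   wake = loc_t(c("2024-03-05 07:30:00", "2024-03-06 07:00:00",
                                  "2024-03-07 07:15:00")))
  y <- night_table(night_id = as.Date(c("2024-03-04", "2024-03-05")),
                   source = rep("tappigraphy", 2),
                   onset = loc_t(c("2024-03-05 00:30:00", "2024-03-05 23:10:00")),
                   wake = loc_t(c("2024-03-05 07:20:00", "2024-03-06 06:50:00")))
  pairs <- pair_nights(x, y)
  expect_equal(nrow(pairs), 2)
  expect_equal(attr(pairs, "n_dropped"), 1)
  # 23:30 vs 00:30 must compare as 23.5 vs 24.5, not 23.5 vs 0.5
  expect_equal(pairs$onset_x[1], 23.5)
  expect_equal(pairs$onset_y[1], 24.5)
  expect_equal(pairs$pct_error[1],
               100 * (pairs$duration_y[1] - pairs$duration_x[1]) /
                 pairs$duration_x[1])

  # identical tables -> zero error
  self <- pair_nights(x, x)
  expect_true(all(self$pct_error == 0))
})

test_that("robust fit recovers exact lines and resists gross outliers", {
  d_exact <- tibble::tibble(x = seq(0, 10, by = 0.5))
  d_exact$y <- d_exact$x
  f1 <- robust_fit(d_exact, y ~ x)
  expect_equal(f1$beta, 1, tolerance = 1e-8)
  expect_equal(f1$intercept, 0, tolerance = 1e-8)
  expect_equal(f1$r_squared, 1, tolerance = 1e-8)

  d2 <- tibble::tibble(x = seq(-5, 5, by = 0.25))
  d2$y <- 2 * d2$x + 1
  f2 <- robust_fit(d2, y ~ x)
  expect_equal(f2$beta, 2, tolerance = 1e-8)
  expect_equal(f2$intercept, 1, tolerance = 1e-8)

  # 5% gross outliers: bisquare stays near the truth, OLS does not, and the
  # estimate agrees with an independent IRLS implementation
  ok <- logical(40); agree <- logical(40); ols_worse <- logical(40)
  for (s in seq_len(40)) {
    set.seed(7000 + s)
    n <- 500
    x <- runif(n, 0, 10)
    y <- 1.5 * x + 2 + rnorm(n, 0, 0.5)
    out <- sample(n, 25)
    y[out] <- y[out] + 30
    fit <- robust_fit(tibble::tibble(x = x, y = y), y ~ x)
    ok[s] <- abs(fit$beta - 1.5) <= 0.05
    oracle <- oracle_bisquare(x, y)
    agree[s] <- abs(fit$beta - oracle[2]) <= 0.02 &&
      abs(fit$intercept - oracle[1]) <= 0.1
    ols_beta <- coef(lm(y ~ x))[2]
    ols_worse[s] <- abs(ols_beta - 1.5) > abs(fit$beta - 1.5)
  }
  expect_gte(mean(ok), 0.95)
  expect_gte(mean(agree), 0.95)
  expect_gte(mean(ols_worse), 0.9)

  expect_error(robust_fit(tibble::tibble(x = rep(1, 10), y = rnorm(10)), y ~ x),
               class = "tapsleep_data_error")
  expect_error(robust_fit(tibble::tibble(x = 1:2, y = 1:2), y ~ x),
               class = "tapsleep_data_error")
})

test_that("subject summaries compute medians, CoV and errors vs a reference", {
  mk_nights <- function(durs, source) {
    n <- length(durs)
    onset <- loc_t("2024-03-04 23:00:00") + 86400 * (seq_len(n) - 1)
    night_table(night_id = as.Date("2024-03-04") + seq_len(n) - 1,
                source = rep(source, n), onset = onset,
                wake = onset + durs * 3600)
  }
  same <- mk_nights(rep(8, 5), "actigraphy")
  s0 <- subject_summary(same)
  expect_equal(s0$cov, 0)
  expect_equal(s0$median_duration, 8)
  expect_equal(s0$median_onset, 23)

  s1 <- subject_summary(mk_nights(c(7, 8, 9), "actigraphy"))
  expect_equal(s1$median_duration, 8)
  expect_equal(s1$cov, 1 / 8)                     # sample SD 1, mean 8

  # tappigraphy 7.5 h vs actigraphy 8 h -> median error -6.25%
  s2 <- subject_summary(mk_nights(rep(7.5, 5), "tappigraphy"),
                        reference = mk_nights(rep(8, 5), "actigraphy"))
  expect_equal(s2$median_pct_error, -6.25)
  expect_equal(s2$median_abs_pct_error, 6.25)

  # a single night leaves the CoV undefined
  expect_true(is.na(subject_summary(mk_nights(8, "actigraphy"))$cov))
})

test_that("multiple regression applies the 0.05/5 Bonferroni rule", {
  set.seed(603)
  n <- 80
  df <- tibble::tibble(
    touches_per_day = rnorm(n, 3000, 800), age = rnorm(n, 23, 2.6),
    gender = rbinom(n, 1, 0.5), height = rnorm(n, 175, 8),
    weight = rnorm(n, 70, 10))
  df$duration <- 2 * df$weight
  # the noiseless construction triggers base R's perfect-fit warning
  fit <- suppressWarnings(
    multi_fit(df, duration ~ touches_per_day + age + gender + height + weight))
  expect_equal(fit$n_tests, 5)
  expect_equal(fit$alpha_adjusted, 0.01)
  wrow <- fit$coefficients[fit$coefficients$term == "weight", ]
  expect_equal(wrow$estimate, 2, tolerance = 1e-6)
  expect_true(wrow$significant)
})

test_that("multiple regression type-I error is controlled on pure noise", {
  set.seed(604)
  n <- 80
  hits <- logical(500)
  for (s in 1:500) {
    df <- tibble::tibble(
      touches_per_day = rnorm(n, 3000, 800), age = rnorm(n, 23, 2.6),
      gender = rbinom(n, 1, 0.5), height = rnorm(n, 175, 8),
      weight = rnorm(n, 70, 10), duration = rnorm(n, 8, 1))
    fit <- multi_fit(df, duration ~ touches_per_day + age + gender + height + weight)
    hits[s] <- fit$f_p < 0.05
  }
  expect_gte(mean(!hits), 0.94)
})

test_that("peri-sleep profile handles touch-free and saturated regimes", {
  mk <- function(n_subj, n_nights, touch_offset_min = NULL) {
    nights <- purrr::map_dfr(seq_len(n_subj), function(s) {
      onset <- loc_t("2024-03-04 23:30:00") + 86400 * (seq_len(n_nights) - 1)
      tibble::tibble(subject = paste0("s", s), onset = onset,
                     wake = onset + 8 * 3600)
    })
    touches <- if (is.null(touch_offset_min)) {
      tibble::tibble(subject = character(0), time = loc_t(character(0)))
    } else {
      tibble::tibble(subject = nights$subject,
                     time = nights$onset + touch_offset_min * 60)
    }
    list(nights = nights, touches = touches)
  }
  # no touches anywhere: all-zero profile, nothing significant
  d0 <- mk(6, 5)
  p0 <- peri_sleep_profile(d0$nights, d0$touches, anchor = "onset")
  expect_true(all(p0$mean_p == 0))
  expect_false(any(p0$significant))

  # a touch 1 min after onset every night: first bin saturates at 1
  d1 <- mk(6, 5, touch_offset_min = 1)
  p1 <- peri_sleep_profile(d1$nights, d1$touches, anchor = "onset")
  expect_equal(p1$mean_p[1], 1)
  expect_true(p1$significant[1])
  expect_true(all(p1$mean_p[-1] == 0))

  # monotonicity: adding touches can only raise per-bin probabilities
  extra <- dplyr::bind_rows(d1$touches,
                            tibble::tibble(subject = d1$nights$subject,
                                           time = d1$nights$onset + 50 * 60))
  p2 <- peri_sleep_profile(d1$nights, extra, anchor = "onset")
  expect_true(all(p2$mean_p >= p1$mean_p))
})

test_that("peri-sleep profile truncates bins beyond short nights", {
  nights <- tibble::tibble(
    subject = "s1",
    onset = loc_t(c("2024-03-04 23:30:00", "2024-03-05 23:30:00")),
    wake = loc_t(c("2024-03-05 01:30:00", "2024-03-06 07:30:00")))  # 2 h and 8 h
  touches <- tibble::tibble(subject = character(0), time = loc_t(character(0)))
  prof <- peri_sleep_profile(nights, touches, anchor = "onset",
                             horizon_min = 240)
  expect_equal(nrow(prof), 80)
  expect_true(all(prof$n_subjects >= 0))
  # bins past 2 h only covered by the long night, still defined
  expect_equal(prof$n_subjects[50], 1)
})
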