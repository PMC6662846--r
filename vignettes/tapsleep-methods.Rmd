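---
title: "Estimating sleep from wrist actigraphy and smartphone touchscreen gaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sleep from wrist actigraphy and smartphone touchscreen gaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapsleep)
```

## The two estimation problems

`tapsleep` implements two independent routes to a per-night estimate of
sleep onset and wake-up time, plus the statistics needed to compare them.

The **actigraphy** route starts from raw tri-axial wrist acceleration
(typically 50 Hz) with co-recorded ambient light and near-body
temperature.  The **tappigraphy** route needs nothing but the epoch
timestamps of smartphone touchscreen interactions, exploiting two
behavioural facts: a touchscreen can only be touched while awake, and
diurnal users follow a 24-h sleep-wake cycle.  Gaps in touchscreen use
that coincide with the circadian inactive phase are therefore a proxy for
sleep.

## The actigraphy pipeline

1. **Activity counts.** Per sample, the three axes are combined with the
   sum of squares, `m = ax^2 + ay^2 + az^2` (units g^2), and low-pass
   filtered at 2 Hz with a zero-phase 4th-order Butterworth filter
   (forward-backward application; filter order and zero phase are package
   choices — only the 2 Hz cutoff is fixed by the method).  Each clock
   minute's count is the rectified sum of the filtered signal around its
   within-minute median; the within-minute median acts as a local
   static-gravity/posture baseline, so a motionless wrist scores exactly
   zero whatever its orientation.
2. **Cole-Kripke D.** Each minute is scored
   `D_t = P * sum_{k=-4}^{+2} W_k A_{t+k}` with the published
   one-minute-epoch weight set `W = (404, 598, 326, 441, 1408, 508, 350)`
   and `P = 1e-5` (both configurable, since deployed implementations
   vary).  `D < 1` (strict) is scored sleep; D is undefined wherever the
   7-minute window is incomplete.
3. **Candidate periods.** Maximal sleep-scored runs, bridging embedded
   wake or unknown runs of at most 5 min and keeping runs of at least
   30 min (artifact defaults, config keys
   `candidate.wake_tolerance_min` / `candidate.min_duration_min`).
   Candidates with more than 10% unknown minutes are dropped.
4. **Vetoes.** A candidate is discarded when (a) its median near-body
   temperature is strictly below 25 degC (watch off-body), (b) its median
   ambient light fails to drop strictly below 25 lux (a lit environment,
   e.g. a daytime nap), or (c) it overlaps the 6-h circadian low-activity
   window by less than 36 min (10% of 6 h; the 36-min bound is
   inclusive).  Missing coverage vetoes conservatively with a warning.
5. **Nightly selection.** Per noon-to-noon local cycle the longest
   surviving candidate wins (ties: larger circadian overlap, then earlier
   onset).  The noon boundary means a normal night is never split across
   cycles; the package does not attempt nap detection, and shift-work or
   non-24-h schedules are out of scope.

## The tappigraphy pipeline

1. **Binarize** touches into 60-s bins: 1 if the bin contains at least
   one touch, 0 otherwise (a thousand touches count the same as one).
2. **Smooth to rest** with the 5%-in-an-hour rule: an active bin whose
   centered 60-min window holds fewer than 5% active bins (at most 2 of
   60) is relabelled rest.  The rule is applied in a single pass on the
   original labels and can only remove activity.  A sliding centered
   window was chosen as the least phase-biased reading of an "in an
   hour" criterion; the alternative tumbling-hour reading would make the
   outcome depend on where clock hours happen to fall.
3. **Extract gaps**: maximal rest runs strictly longer than 2 h.  The
   observation span is treated as active-bounded — rest before the first
   or after the last observed touch is not evidence of sleep, just
   absence of observation.
4. **Select the sleep gap**: each gap belongs to the noon-to-noon cycle
   containing its midpoint; gaps overlapping that cycle's 6-h circadian
   low-activity window by at least 36 min qualify, and the longest
   qualifying gap is the night's sleep estimate.

Because a bedtime phone session ends after true sleep onset ends and a
morning check begins before the phone's first "real" use of the day, the
tappigraphy estimate is inherently conservative: nocturnal touches can
only shorten the detected gap, never lengthen it, so tappigraphy
underestimates sleep whenever the phone accompanies falling asleep or
waking up.

## The cosinor and the low-activity window

Both pipelines need the circadian inactive phase.  A fixed-period 24-h
sinusoid `y(t) = M + A cos(2*pi*(t - phi)/24)` is fit by ordinary least
squares (`M` mesor, `A >= 0` amplitude, `phi` acrophase in clock hours).
The 6-h low-activity window is centered on the bathyphase
(`phi + 12 mod 24`); for a pure sinusoid this is provably the 6-h window
of least fitted activity, which the test suite verifies against an
exhaustive 1-min-step search.  The fit is global (all days pooled) and
the window is instantiated once per cycle; a per-cycle refit is available
(`cosinor.per_cycle`) but the global fit is the default because single
noisy days can produce wild phase estimates.  The actigraphy pipeline
fits per-minute activity counts; the tappigraphy pipeline fits hourly
touch counts (`cosinor.bin_minutes`), a bin width that conditions the
regression well without hiding the diurnal rhythm.  A fit with zero
amplitude has no bathyphase and raises an error rather than guessing.

## Derived metrics

* **25-h clock linearization** — sleep landmarks cluster around midnight,
  so clock times strictly before 10:00 are shifted by +24 h (01:00
  becomes 25 h) before any regression or median.  The same rule is
  applied to wake-up times: wake times before 10 am are the norm, and a
  linear clock is required for the wake regressions (cutoff
  configurable).
* **Sleep fracture fraction (SFF)** — touches strictly inside an
  actigraphy sleep window split it into sub-intervals; SFF is the longest
  sub-interval over the window duration.  SFF = 1 is
  smartphone-uninterrupted sleep; a single midpoint touch gives exactly
  0.5.
* **Touch probability by D** — the fraction of minutes in each 0.25-wide
  D bin containing a touch, with an overflow bin at `D >= 7` (the
  overflow bin is closed at 7 so a minute with D exactly 7 is not lost).
* **Peri-sleep profiles** — per subject, the fraction of nights with a
  touch in each 3-min bin after onset (or before wake); the population
  mean is tested against zero per bin with one-sample t-tests,
  Bonferroni-corrected over the number of bins.  The default horizon is
  4 h so a ~2-h effect can be seen to end.  Tests operate on
  subject-level means, not pooled nights, so subjects are the unit of
  inference.
* **Comparison statistics** — nights paired by cycle; simple relations
  fitted by bisquare IRLS (tuning constant 4.685) so a few aberrant
  nights do not drive the slope; per-subject medians, the duration CoV
  (sample SD / mean); multiple regression on demographic covariates with
  the per-coefficient alpha Bonferroni-corrected over the 5 simultaneous
  hypotheses (0.05/5 = 0.01).

## What the synthetic generator emulates

`subject_scenario()` and `simulate_subject()` produce the three input
streams with known ground truth:

* wrist motility as zero-mean Gaussian acceleration noise whose SD
  follows a day/night two-level profile with a 10-min logistic ramp at
  each true onset and wake (1%-99% span), plus a 20% 24-h cosinor
  modulation peaking mid-wake.  The day level (0.09 g per axis) is
  calibrated so daytime D sits at free-living levels (~4-6) and sleep D
  near 0.15 — the calibration any deployed actigraph needs for the D < 1
  rule to be meaningful;
* light ~250 lux awake / ~1 lux asleep; near-body temperature 31 degC
  worn, 22 degC during declared non-wear episodes (during which motility
  also collapses, as for a watch on a nightstand);
* touches as a piecewise-constant-rate Poisson process confined to wake
  (~180/h by default, doubled in the half-hour wakeful-rest windows
  around the night), one anchor touch 1 s before onset and 1 s after
  wake (the phone put down at lights-out and checked on waking), plus an
  optional nocturnal model: linear-decay touching after onset, a
  mirrored ramp before wake, or brief hourly checks;
* diary entries as ground truth plus 10-min Gaussian reporting noise.

The generator is deterministic from one seed; raw streams are rendered
per noon-to-noon day from derived sub-seeds, so any contiguous range of
days reproduces the corresponding slice of the full rendering exactly
(`score_scenario()` exploits this to process long recordings in chunks).

What it does **not** emulate: gait harmonics and posture changes, daytime
wakeful-rest bouts of low motility, vehicle vibration (the classic
high-D-without-activity artifact), naps, non-24-h schedules, and
between-subject parameter heterogeneity.  Passing the recovery tests
therefore shows the pipelines are correct implementations of their rules
under clean diurnal conditions, not that those rules are accurate
against polysomnography in free-living data.

## Validation conditions and problem sizes

The test suite checks, among others:

* exact agreement of the D scorer, run extraction, gap extraction and
  touch histogram with brute-force oracles on over a thousand random
  small instances;
* cosinor recovery: exact on noiseless sinusoids, and with sigma = 0.5
  Gaussian noise on an amplitude-2 rhythm (7 days hourly) M and A within
  0.2 and phase within 0.5 h in at least 95% of 500 seeds;
* ground-truth recovery on the clean-sleeper scenario over 100 nights
  (10 subjects x 10 nights): actigraphy onset/wake within 5 min,
  tappigraphy within 1 min; non-wear nights 100% vetoed;
* the direction of the tappigraphy bias on the phone-in-bed scenario
  (12 subjects x 14 nights, nocturnal touching decaying from 40/h to 0
  over 2 h): median tappigraphy duration strictly below actigraphy, and
  the significant bins of the peri-sleep profile extending to the 2-h
  support within 15 min.  The 40/h rate and the 12 x 14 design were
  fixed together by a power analysis of the Bonferroni-corrected
  per-bin t-test, so that the detectability boundary of the profile
  falls within a few minutes of the injected support.

Numerical conventions worth knowing: all datetimes are local civil time
carried as POSIXct with a fixed UTC offset (daylight-saving transitions
inside one recording are not modelled); threshold semantics follow the
wording of each rule — D < 1 strict, temperature < 25 strict, light must
be strictly below 25, gap length strictly > 2 h, circadian overlap >= 36
min inclusive; ties between equal-length candidates are broken by larger
circadian overlap and then earlier onset; the CoV uses the sample SD.

## Known limitations

* Estimates inherit actigraphy's intrinsic biases: quiescence precedes
  sleep and follows waking, so even a perfect D scorer brackets true
  sleep only approximately.
* The tappigraphy route requires sustained engagement; for users
  generating few touches the observation-span and smoothing rules can
  leave whole nights without a qualifying gap (reported as missing
  nights, never imputed).
* A fixed 24-h period is assumed throughout; no period estimation, no
  multi-component cosinor.
* Daytime naps are explicitly not detected by either route.
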