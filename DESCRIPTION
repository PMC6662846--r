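Package: tapsleep
Title: Sleep Estimation from Wrist Actigraphy and Smartphone Touchscreen Gaps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two parallel behavioural sleep-estimation pipelines and the
    metrics to compare them. The actigraphy pipeline converts raw 50 Hz
    tri-axial wrist acceleration to per-minute activity counts, scores each
    minute with the Cole-Kripke weighted-sum statistic (D < 1 scored as
    sleep), and vetoes putative sleep periods using near-body temperature
    (non-wear), ambient light (daytime naps) and overlap with the cosinor
    derived 6-hour circadian low-activity window. The "tappigraphy" pipeline
    infers sleep from gaps in smartphone touchscreen activity: touches are
    binarized into 60-second bins, smoothed with a 5-percent-per-hour rule,
    and the longest usage gap exceeding 2 hours that overlaps the circadian
    inactive phase is labelled sleep. Derived metrics include the sleep
    fracture fraction, touch-probability-by-activity histograms, peri-sleep
    touch-probability profiles, and robust per-night comparison statistics.
    A seeded synthetic-data generator produces actigraphy, touch-log and
    sleep-diary streams with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
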