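Package: ertwave
Title: Waveform Analysis of Event-Related Transients in Peri-Event Neural Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects event-related transients (ERTs) in peri-event neural time
    series such as fiber photometry dF/F recordings. Provides pointwise
    waveform confidence intervals (parametric t and expanded percentile
    bootstrap), two-sample waveform comparisons, whole-trace permutation
    tests, and consecutive-significance thresholds that control the
    family-wise error rate across the peri-event window. Includes a
    synthetic-signal generator (low-pass filtered Gaussian noise with
    parabolic transients of half-normal magnitude) and a Monte Carlo harness
    quantifying family-wise Type I error and correct-rejection rates for each
    detection method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
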