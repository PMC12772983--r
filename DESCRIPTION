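Package: ehgtrends
Title: Whole-Window Electrohysterogram Feature Extraction and
    Gestational-Age Trend Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising uterine myoelectrical activity from
    single-channel electrohysterogram (EHG) recordings across the third
    trimester of pregnancy.  Implements the whole-window analysis pipeline:
    zero-phase band-pass filtering (0.1-4 Hz), anti-aliased resampling to
    20 Hz, artifact-interval exclusion, 120-second sliding windows with 50%
    overlap, and four per-window features (peak-to-peak amplitude, kurtosis
    of the Hilbert envelope, median frequency in 0.2-1 Hz, and sample
    entropy of the 0.34-4 Hz fast-wave-high component, m = 2, r = 0.2 SD)
    aggregated to per-recording medians.  Includes stratified dynamic
    downsampling for gestational-age balance between singleton and multiple
    gestations, generalized additive model trend curves, Spearman
    correlations and Wilcoxon rank-sum comparisons across gestational
    stages, plus a seeded synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mgcv,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
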