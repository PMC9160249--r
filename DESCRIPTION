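Package: choiceEEG
Title: Simulation and Time-Frequency Analysis of Instructed and Free Choice EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse a 2x2 (choice context x difficulty)
    reaching experiment with 64-channel EEG. Includes a synthetic-data generator
    (logistic choice model around a per-participant point of subjective equality,
    condition-dependent truncated-normal reaction times, 1/f EEG background with
    planted midfrontal theta bursts and RT-coupled sensorimotor beta
    desynchronization), psychometric fitting, trial rejection and RT-matching
    rules, zero-phase filtering, spherical-spline surface Laplacian, Morlet
    wavelet band power with relative-change baselines, spatio-temporal
    cluster-mass permutation tests over an electrode neighbourhood graph,
    windowed correlation topographies, and trial-level linear mixed models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
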