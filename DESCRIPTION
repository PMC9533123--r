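Package: eegmse
Title: Multiscale Entropy Analysis of Resting-State EEG for Cognitive-Function Grouping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to quantify the temporal complexity of multichannel
    resting-state EEG with multiscale entropy (coarse-graining plus sample
    entropy over 40 time scales at the 19 electrodes of the 10-20 system),
    reduce the scale axis to eight five-scale bins, and test for group
    differences between high and low cognitive-function cohorts using a
    mixed-design repeated-measures ANCOVA with age and sex covariates,
    Greenhouse-Geisser correction, post-hoc t grids and Benjamini-Hochberg
    false discovery rate control. Includes a Welch power-spectral-density
    control analysis, EDF and delimited-matrix signal I/O, and a seeded
    synthetic-cohort generator that emulates the statistical structure of
    eyes-closed recordings with a slow-scale complexity group effect.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
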