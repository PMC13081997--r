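Package: itsdev
Title: Development of fMRI Intrinsic Timescale Along the Cortical Hierarchy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates per-region intrinsic neural timescale from parcellated
    resting-state BOLD time series as the repetition-time-scaled sum of
    positive autocorrelation values up to the first zero-crossing (with
    exponential-decay and zero-crossing sensitivity variants), models its
    development across age with penalized-spline generalized additive models
    (signed partial R-squared effect sizes, nested-model ANOVA, FDR control,
    fitted trajectories and ages of maximal change), and assigns significance
    to cortical map comparisons with spatial-autocorrelation-preserving spin
    permutation tests against a sensorimotor-association axis. Includes a
    synthetic cohort generator with region-specific AR(1) temporal structure
    so the full pipeline is testable without access-controlled neuroimaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
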