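Package: gateopt
Title: Optimal Gate Counts for Dual Respiratory-Cardiac Gated PET
Version: 0.1.0
Authors@R:
    person("gateopt", "developers", email = "gateopt@example.org", role = c("aut", "cre"))
Description: Motion models and tools for choosing the optimal number of
    respiratory, cardiac and dual gates in gated cardiac PET. Implements
    single-mode and dual respiratory-cardiac gate-count motion models with
    closed-form least-squares fitting, the exponential respiratory model of
    Dawood and colleagues, optimal-gate-count rules based on capturing motion
    to within half the scanner resolution, amplitude-based respiratory and
    phase-based cardiac gate assignment, hot-spot and centre-of-mass motion
    measurement from gated image sets, SNR and FWHM image-quality metrics, and
    a synthetic moving-heart-phantom simulator so the whole method can be
    exercised without scanner data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
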