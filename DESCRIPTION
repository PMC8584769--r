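Package: scmsi
Title: Population Modeling of Visuoauditory Integration in the Superior Colliculus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying nonlinear multisensory integration in
    populations of superior colliculus neurons recorded under factorial
    visuoauditory stimulation. Implements sigmoidal unisensory intensity
    tuning multiplied by an exponentiated, population-shared, center-surround
    modulation function; a quasi-Poisson deviance likelihood with two-phase
    alternating block-coordinate fitting and multi-restart; model comparison
    between audition-modulated, vision-modulated, and linear-summation
    variants; Wald tests for per-neuron modulation; upstream unisensory
    characterization (response windows, responsiveness and monotonicity
    tests, receptive-field and topographic-map fits); and a synthetic-data
    generator with known ground truth for calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
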