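Package: aaipipe
Title: Alpha-Asymmetry Neurofeedback Pipelines for Pain Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sham-controlled EEG neurofeedback experiments that
    target the somatosensory alpha asymmetry index (AAI). Implements the
    real-time feedback computation (sliding-window Hanning band power,
    temporal smoothing, visibility mapping, Fourier phase scrambling of
    feedback images, trial rewards), offline single-trial feature
    extraction (trial AAI, laser-evoked N1/N2/P2 potentials, induced
    alpha/beta/gamma power, exclusion rules, control indices), one-sided
    JZS Bayes factors with a sequential Bayes-factor design simulator
    (SBF+maxN), the adaptive Bayesian hypothesis pipeline that classifies
    outcomes into result patterns, moderated multilevel (1-1-1) mediation
    of pain ratings by trial-wise alpha asymmetry, and a synthetic-data
    generator that emulates the statistical structure of such experiments
    so that every stage can be tested without recorded data.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
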