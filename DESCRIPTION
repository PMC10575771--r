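Package: glumeta
Title: Meta-Analysis of Variability and Mean Differences in Case-Control
    Brain Metabolite Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for meta-analysing case-control summary data on brain
    metabolite concentrations (glutamate, glutamine, Glx from proton magnetic
    resonance spectroscopy), with an emphasis on variability: bias-corrected
    log coefficient of variation ratios (lnCVR) and log variability ratios
    (lnVR) alongside Hedges' g standardised mean differences; random-effects
    pooling with restricted maximum likelihood estimation of between-study
    variance; subgroup Wald comparisons, moderator meta-regression and
    Benjamini-Hochberg false discovery rate control across brain regions;
    Hartigan's dip test of unimodality with Monte-Carlo calibration for
    individual-level metabolite distributions; and a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
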