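Package: doublepass
Title: Double-Pass Psychophysics: Decision-Variable Correlation and
    Variance Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing double-pass forced-choice experiments in
    which the same unique trials are presented twice (or, across paired
    experiments, four times).  Implements constrained maximum-likelihood
    fitting of cumulative-Gaussian psychometric functions with log-linear
    threshold laws, maximum-likelihood estimation of decision-variable
    correlation from response-agreement counts via bivariate and
    quadrivariate normal orthant probabilities, a quasi-quadruple-pass
    analysis that partitions stimulus-driven variance into luminance-driven
    and depth-driven components, between-observer decision-variable
    correlations, trial-level bootstrap confidence intervals, stimulus
    statistics (disparity-contrast, RMS contrast) for stereo image patches,
    and a synthetic-observer generator for the full study design of a
    natural-stimulus disparity-discrimination experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
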