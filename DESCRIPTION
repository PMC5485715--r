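Package: txrecon
Title: Reconstructing Transcriptional Activity from Expression Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs temporal transcription-rate profiles of a gene from
    mRNA expression or protein-reporter time series, using a linear ODE model
    of transcription, translation and first-order degradation. Two estimators
    are provided: a non-parametric smooth back-calculation based on
    local-linear kernel regression with leave-one-out bandwidth selection and
    bootstrap credibility envelopes, and a Bayesian piecewise-constant
    "switch" model sampled by reversible-jump Markov chain Monte Carlo with
    Gaussian-mixture summarisation of switch-time posteriors. Includes a
    tabular reader for expression time-course spreadsheets with replicates, a
    synthetic-data generator for the underlying kinetic model, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
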