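Package: i131biokin
Title: Five-Compartment Biokinetic Modelling of Radioiodine I-131
Version: 0.1.0
Authors@R: person("i131biokin", "developers", email = "i131biokin@example.org",
    role = c("aut", "cre"))
Description: Tools for compartmental biokinetic modelling of orally
    administered I-131 in thyroid-remnant ablation patients. Implements a
    five-compartment (stomach, body fluid, thyroid, whole body, excretion)
    linear kinetic model solved by matrix exponential with an independent
    Runge-Kutta oracle, a gamma-scan observation model (region-of-interest
    projection, background subtraction, stomach-peak normalization), the AT
    root-mean-square agreement index, per-patient parameter estimation by
    grid search with derivative-free refinement, cohort summarization, a
    synthetic gamma-scan data generator, and CSV/JSON readers, writers and a
    subcommand command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
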