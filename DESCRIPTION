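Package: diagsim
Title: Simulation of Sequential Clinical Diagnostic Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying sequential clinical diagnosis as a problem of
    probabilistic inference and test selection. Builds maximum-entropy
    disease-sign models (one- and two-disease factors acting on single signs)
    whose parameters are computed exactly from conditional sign marginals of a
    synthetic exponential benchmark model; computes disease posteriors,
    unobserved-sign marginals and maximum-likelihood disease hypotheses either
    by exhaustive enumeration or by Metropolis Monte Carlo and simulated
    annealing; simulates step-by-step diagnostic processes in which test
    outcomes are either revealed (Diags-I) or imputed from the model
    (Diags-II) under greedy and random test-selection strategies; optimizes
    whole observation sequences by zero-temperature Monte Carlo with
    marginal-guided proposals; and evaluates diagnostic quality through
    posterior-truth overlap, first right/wrong diagnosis times and cumulative
    observation cost.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
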