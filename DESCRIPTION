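Package: cavte
Title: Censoring-Imputation Bias in Time-Averaged Exposure-Response Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for studying how the derivation of
    time-averaged concentration to event (CavTE) in censored subjects biases
    logistic exposure-response analyses of binary safety endpoints. Provides a
    one-compartment oral population pharmacokinetic simulator with closed-form
    concentration and cumulative-AUC functions, an ordinal Grade 0/1/2
    proportional-odds adverse-event simulator with Markov components and a
    saturable (Emax) concentration-dependent logit shift, exposure-metric
    derivation under end-of-treatment follow-up imputation policies, a logistic
    regression fitter with Wald slope inference, and a replicated scenario-grid
    engine that summarises slope p-value trends across imputation policies,
    sample sizes and drug-effect magnitudes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
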