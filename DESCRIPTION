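Package: opioidsparing
Title: Bayesian Hierarchical Analysis of Opioid-Sparing Prescribing Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cross-sectional surveys of surgeon opioid
    prescribing practice with a Bayesian hierarchical Bernoulli-logit model.
    Includes evidence-weighted prior elicitation from historical studies,
    an adaptive Metropolis sampler with province-level random intercepts,
    split-chain R-hat and effective-sample-size diagnostics, posterior
    probability-of-superiority comparisons across clinician characteristics,
    Pareto-smoothed importance-sampling leave-one-out (PSIS-LOO) model
    comparison with an exact refit fallback, and a synthetic survey
    generator for end-to-end validation without any external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
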