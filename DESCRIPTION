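Package: srsignal
Title: Signal Detection in Spontaneous Adverse-Event Reporting Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection in spontaneous
    reporting system (SRS) databases such as JADER and FAERS: readers and
    de-duplication for both table dialects, drug-event pair expansion,
    four disproportionality metrics (reporting odds ratio, proportional
    reporting ratio, the Bayesian confidence propagation neural network
    information component, and the Gamma-Poisson Shrinker empirical Bayes
    geometric mean) with their signal rules and stratified variants,
    Weibull time-to-onset modelling with bootstrap confidence intervals,
    and a synthetic-SRS generator with known ground-truth association
    strength for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fitdistrplus
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
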