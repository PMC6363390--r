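Package: discountr
Title: Delay-Discounting Analysis Across Time-Horizons and Task Modalities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing intertemporal-choice experiments in which the
    same subjects are measured in several tasks that differ in time-horizon
    (seconds versus days versus weeks) and modality (verbal versus
    experiential). Provides a blocked offer-schedule generator and cohort
    simulator with correlated subject-level discount rates, hyperbolic and
    exponential utility with softmax and matching choice rules, per-subject
    maximum-likelihood fitting with leave-one-trial-out cross-validation and
    BIC model comparison, a Bayesian hierarchical softmax-hyperbolic model
    (fit by Gibbs sampling via 'rjags') with evidence ratios, Bayesian R
    squared and K-fold information criteria, cross-task reliability
    statistics with simulation-based attenuation correction, and
    temporal-context analyses (shift/scale comparisons, unit-shift
    predictions, and an early-trial adaptation mixed model).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
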