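Package: tmlesurv
Title: Targeted Maximum Likelihood Estimation for Discrete-Time Survival
    Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Doubly robust estimation of the causal effect of a point binary
    or multilevel exposure on a time-to-event outcome discretized into
    intervals, under missing-at-random censoring.  Implements targeted
    maximum likelihood estimation (TMLE) of counterfactual survival curves
    via an iterated-conditional-expectation backward recursion with a
    weighted-regression fluctuation step, average treatment effects over
    time, and marginal structural models for the discrete-time hazard fitted
    by weighted logistic regression of the estimated counterfactual hazards.
    Inference is based on the efficient influence curve, including a
    delta-method influence curve for the marginal structural model
    coefficients.  Nuisance models (exposure, per-interval censoring,
    per-interval event or iterated-expectation regressions) can be fitted
    with parametric logistic models or with a cross-validated stacking
    ensemble.  A synthetic-data generator with closed-form ground truth
    supports simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    nnet,
    pracma,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Collate: 
    'data_model.R'
    'learners.R'
    'msm.R'
    'nuisance.R'
    'pipeline.R'
    'synthetic.R'
    'tmle.R'
    'utils.R'
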