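Package: motr
Title: Mouse-Tracking-for-Reading Measures and Bayesian Hierarchical Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for mouse-tracking-for-reading (MoTR) experiments:
    converts timestamped cursor trajectories into attentional associations
    and eye-movement-style reading measures (gaze duration, go-past time,
    total duration, first-pass and incoming regressions), generates
    factorial study designs and synthetic data with known ground truth,
    builds custom hypothesis-matrix contrasts via the generalized inverse,
    fits lognormal and Bernoulli Bayesian hierarchical models with crossed
    LKJ-correlated random effects by Gibbs sampling, and supports
    bridge-sampling Bayes-factor model comparison with prior-sensitivity
    sweeps and simulation-based power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
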