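Package: itcddm
Title: Hierarchical Bayesian Drift Diffusion Modelling of Intertemporal
    Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits hierarchical Bayesian drift diffusion models (DDMs) to
    intertemporal choice data, in which trial-level reward-magnitude and
    delay differences, and a pharmacological condition, are mapped onto the
    drift rate, starting bias, decision threshold and non-decision time of a
    two-boundary Wiener diffusion. Provides six model variants (attribute-
    difference drift with a sigmoidal saturation link, fixed-bias and
    attribute-free reductions, a delay-sum bias model, a hyperbolic
    discounted-value drift, and a relative-starting-time model with
    asynchronous attribute onsets), an exact Wiener first-passage density and
    simulator, DIC model comparison, posterior predictive checks with
    quantile binning, parameter recovery, hyperbolic discounting with softmax
    choice, robust Bayesian t-tests, Bayesian mixed-effects regressions of
    choice and response time, and synthetic task generators for within- and
    between-subject pharmacological designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    coda,
    jsonlite,
    rjags,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
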