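Package: causalsets
Title: Marginal Causal Effects for Binary Outcomes and Covariate-Set Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimation of marginal causal effects (average treatment effect and
    average treatment effect on the treated) of a binary treatment on a binary
    outcome by g-computation, inverse probability of treatment weighting,
    optimal full matching on the propensity score, and targeted maximum
    likelihood estimation. Includes a synthetic cohort generator with nine
    binary confounders, a Monte-Carlo engine benchmarking the four estimators
    under four covariate-set strategies (outcome, treatment, common, entire),
    and performance metrics (bias, mean squared error, variance-estimation
    bias, coverage, power, type-I error, convergence).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    parallel,
    MASS,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
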