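#' Estimate a marginal causal effect from a data set
#'
#' High-level interface for real (or simulated) tabular data: one row per
#' subject, a binary outcome column, a binary treatment column and binary
#' covariate columns. Applies one of the four estimators and returns the
#' marginal effects with a 95\% confidence interval.
#'
#' @param data a data frame (or `cs_cohort`).
#' @param outcome,treatment column names of the 0/1 outcome and treatment.
#' @param covariates character vector of covariate column names to adjust
#'   for.
#' @param method `"gc"`, `"iptw"`, `"fm"` or `"tmle"`.
#' @param estimand `"ATE"` or `"ATT"`.
#' @param ci for g-computation, `"param-sim"` (parametric simulation of the
#'   coefficient distribution) or `"bootstrap"`; ignored by the other
#'   methods (IPTW and full matching use the robust sandwich, TMLE the
#'   efficient influence curve).
#' @param n_draws draws for the parametric simulation or bootstrap
#'   resamples.
#' @param seed optional seed for the variance simulation.
#' @return A `cs_effects` record.
#' @examples
#' sc <- make_scenario("ATE", "alternative")
#' d <- as.data.frame(generate_cohort(sc, 1000, seed = 7))
#' estimate_effect(d, "Y", "A", paste0("L", 1:6), method = "gc", seed = 1)
#' @export
estimate_effect <- function(data, outcome = "Y", treatment = "A",
                            covariates = NULL,
                            method = c("gc", "iptw", "fm", "tmle"),
                            estimand = c("ATE", "ATT"),
                            ci = c("param-sim", "bootstrap"),
                            n_draws = 1000, seed = NULL) {
  method <- match.arg(method)
  estimand <- match.arg(estimand)
  ci <- match.arg(ci)
  if (inherits(data, "cs_cohort")) data <- as.data.frame(data)
  lcols <- if (is.null(covariates)) setdiff(names(data), c(outcome, treatment))
           else covariates
  ch <- cohort(data[[outcome]], data[[treatment]],
               as.matrix(data[, lcols, drop = FALSE]))
  covs <- seq_along(lcols)
  if (method == "gc") {
    q <- fit_qmodel(ch, covs)
    if (!q$converged) return(.effects_nonconverged("gc", NA_character_, estimand))
    e <- gcomp_effects(q, ch, estimand)
    v <- if (ci == "param-sim") {
      gcomp_variance_parametric(q, ch, estimand, n_draws = n_draws, seed = seed)
    } else {
      gcomp_variance_bootstrap(ch, covs, estimand, n_boot = n_draws,
                               seed = seed)$var_theta
    }
    return(.effects_from_pis(e$pi1, e$pi0, v, "gc", NA_character_, estimand))
  }
  if (method == "tmle") {
    q <- fit_qmodel(ch, covs)
    ps <- fit_propensity(ch, covs)
    if (!q$converged || !ps$converged)
      return(.effects_nonconverged("tmle", NA_character_, estimand))
    tm <- if (estimand == "ATE") tmle_ate(ch, q, ps) else tmle_att(ch, q, ps)
    return(tm$effects)
  }
  ps <- fit_propensity(ch, covs)
  if (!ps$converged) return(.effects_nonconverged(method, NA_character_, estimand))
  w <- if (method == "iptw") {
    if (estimand == "ATE") iptw_weights_ate(ps, ch$A) else iptw_weights_att(ps, ch$A)
  } else {
    st <- full_match(ps, ch$A)
    if (estimand == "ATE") fm_weights_ate(st, ch$A, ps$marginal_treated)
    else fm_weights_att(st, ch$A)
  }
  f <- weighted_outcome_fit(ch, w,
                            variance = if (method == "fm") "model" else "sandwich")
  if (!f$converged) return(.effects_nonconverged(method, NA_character_, estimand))
  effects_from_alpha(f$alpha0, f$alpha1, f$var_alpha1, method,
                     NA_character_, estimand)
}
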