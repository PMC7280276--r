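#' Build a simulation scenario
#'
#' Parameterizes the generative model of the synthetic cohorts. Nine binary
#' covariates L1..L9 are iid Bernoulli(0.5). Treatment follows
#' \eqn{A \sim Bernoulli(expit(\gamma_0 + \sum_j \gamma_j L_j))} and the
#' outcome \eqn{Y \sim Bernoulli(expit(\beta_0 + \beta_A A + \sum_j \beta_j L_j))}.
#'
#' The intercepts are calibrated so that roughly 50\% of subjects are treated
#' under the ATE configuration (\eqn{\gamma_0 = -3.3}) and 20\% under the ATT
#' configuration (\eqn{\gamma_0 = -5.2}), with an event rate near 50\% under
#' the alternative hypothesis (\eqn{\beta_0 = -3.65} for ATE, \eqn{-3.5} for
#' ATT). Six covariates enter each model: three with a strong association
#' (OR = 6.0) and three with a moderate one (OR = 1.5). The treatment model
#' uses L1, L2, L4, L5, L7, L8 and the outcome model L1..L6, so that
#' L1, L2, L4, L5 are the common causes.
#'
#' @param estimand `"ATE"` or `"ATT"`; selects the intercept calibration.
#' @param hypothesis `"null"` (conditional treatment OR 1, \eqn{\beta_A = 0})
#'   or `"alternative"` (conditional OR 2, \eqn{\beta_A = \log 2}).
#' @param unmeasured if `TRUE`, covariate L1 still drives the generation but
#'   is hidden from every analysis model (unmeasured-confounder variant).
#' @param strong_treatment,strong_outcome indices of the three covariates with
#'   the strong (OR 6.0) association in each model; the remaining three active
#'   covariates get the moderate (OR 1.5) one. The active sets are fixed
#'   (treatment: 1,2,4,5,7,8; outcome: 1..6). Since the covariates are
#'   exchangeable iid Bernoulli(0.5), the theoretical effects do not depend on
#'   this assignment; the defaults make L1 a strong cause of both treatment
#'   and outcome.
#' @return An object of class `cs_scenario`: a list with elements `estimand`,
#'   `hypothesis`, `unmeasured`, `gamma0`, `gamma` (length 9), `beta0`,
#'   `beta_treat`, `beta` (length 9).
#' @examples
#' sc <- make_scenario("ATE", "alternative")
#' sc$gamma0   # -3.3
#' sc$beta_treat  # log(2)
#' @export
make_scenario <- function(estimand = c("ATE", "ATT"),
                          hypothesis = c("alternative", "null"),
                          unmeasured = FALSE,
                          strong_treatment = c(1L, 2L, 7L),
                          strong_outcome = c(1L, 3L, 4L)) {
  estimand <- match.arg(estimand)
  hypothesis <- match.arg(hypothesis)
  trt_active <- c(1L, 2L, 4L, 5L, 7L, 8L)
  out_active <- 1:6
  strong_treatment <- as.integer(strong_treatment)
  strong_outcome <- as.integer(strong_outcome)
  if (length(strong_treatment) != 3L || !all(strong_treatment %in% trt_active))
    stop("'strong_treatment' must be 3 indices among {1,2,4,5,7,8}")
  if (length(strong_outcome) != 3L || !all(strong_outcome %in% out_active))
    stop("'strong_outcome' must be 3 indices among 1..6")

  gamma <- numeric(9)
  gamma[trt_active] <- log(1.5)
  gamma[strong_treatment] <- log(6)
  beta <- numeric(9)
  beta[out_active] <- log(1.5)
  beta[strong_outcome] <- log(6)

  structure(list(
    estimand = estimand,
    hypothesis = hypothesis,
    unmeasured = isTRUE(unmeasured),
    gamma0 = if (estimand == "ATE") -3.3 else -5.2,
    gamma = gamma,
    beta0 = if (estimand == "ATE") -3.65 else -3.5,
    beta_treat = if (hypothesis == "alternative") log(2) else 0,
    beta = beta
  ), class = "cs_scenario")
}

#' @export
print.cs_scenario <- function(x, ...) {
  cat("Simulation scenario (", x$estimand, ", ", x$hypothesis,
      if (x$unmeasured) ", L1 unmeasured" else "", ")\n", sep = "")
  cat("  treatment model: gamma0 =", x$gamma0, "; log-OR:",
      paste0("L", which(x$gamma != 0), "=", signif(x$gamma[x$gamma != 0], 3),
             collapse = " "), "\n")
  cat("  outcome model:   beta0 =", x$beta0, "; beta_A =",
      signif(x$beta_treat, 3), "; log-OR:",
      paste0("L", which(x$beta != 0), "=", signif(x$beta[x$beta != 0], 3),
             collapse = " "), "\n")
  invisible(x)
}

#' Covariate-set strategies
#'
#' Returns the covariate column indices selected by each of the four
#' adjustment strategies: the *outcome* set (causes of Y: L1..L6), the
#' *treatment* set (causes of A: L1, L2, L4, L5, L7, L8), the *common* set
#' (causes of both: L1, L2, L4, L5) and the *entire* set (L1..L9). When the
#' confounder L1 is unmeasured it is removed from every set.
#'
#' @param set_name one of `"outcome"`, `"treatment"`, `"common"`, `"entire"`.
#' @param unmeasured drop L1 from the returned set?
#' @return Integer vector of covariate indices (columns of the cohort's `L`).
#' @examples
#' covariate_subset("common")           # 1 2 4 5
#' covariate_subset("common", TRUE)     # 2 4 5
#' @export
covariate_subset <- function(set_name = c("outcome", "treatment", "common", "entire"),
                             unmeasured = FALSE) {
  set_name <- match.arg(set_name)
  idx <- switch(set_name,
    outcome = 1:6,
    treatment = c(1L, 2L, 4L, 5L, 7L, 8L),
    common = c(1L, 2L, 4L, 5L),
    entire = 1:9
  )
  if (isTRUE(unmeasured)) idx <- setdiff(idx, 1L)
  as.integer(idx)
}
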