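#' Construct a cohort object
#'
#' A cohort is the rectangle (Y, A, L) of n subjects: binary outcome, binary
#' treatment and a matrix of binary baseline covariates.
#'
#' @param Y length-n 0/1 outcome vector.
#' @param A length-n 0/1 treatment vector.
#' @param L n x K 0/1 covariate matrix; columns are labelled L1..LK if
#'   unnamed.
#' @return An object of class `cs_cohort`.
#' @export
cohort <- function(Y, A, L) {
  L <- as.matrix(L)
  n <- length(Y)
  if (length(A) != n || nrow(L) != n)
    stop("Y, A and rows of L must have a common length")
  if (!all(Y %in% c(0, 1))) stop("Y must contain only 0/1 values")
  if (!all(A %in% c(0, 1))) stop("A must contain only 0/1 values")
  if (is.null(colnames(L))) colnames(L) <- paste0("L", seq_len(ncol(L)))
  structure(list(Y = as.integer(Y), A = as.integer(A), L = L, n = n),
            class = "cs_cohort")
}

#' @export
print.cs_cohort <- function(x, ...) {
  cat("Cohort: n =", x$n, "|", ncol(x$L), "covariates |",
      sum(x$A), "treated |", sum(x$Y), "events\n")
  invisible(x)
}

#' @export
as.data.frame.cs_cohort <- function(x, ...) {
  data.frame(Y = x$Y, A = x$A, x$L, check.names = FALSE)
}

#' Generate a synthetic cohort
#'
#' Simulates one cohort from a scenario: covariates iid Bernoulli(0.5),
#' treatment from the logistic treatment model, outcome from the logistic
#' outcome model. The generation always uses the full scenario (including L1
#' when `unmeasured = TRUE`); hiding L1 is an analysis-time decision made via
#' [covariate_subset()].
#'
#' @param scenario a [make_scenario()] object.
#' @param n number of subjects.
#' @param seed integer seed; identical `(scenario, n, seed)` yield identical
#'   cohorts.
#' @return A `cs_cohort` with 9 covariate columns L1..L9.
#' @examples
#' sc <- make_scenario("ATE", "alternative")
#' ch <- generate_cohort(sc, 500, seed = 1)
#' mean(ch$A)
#' @export
generate_cohort <- function(scenario, n, seed) {
  stopifnot(inherits(scenario, "cs_scenario"), n >= 1)
  if (!missing(seed)) set.seed(seed)
  L <- matrix(rbinom(n * 9L, 1L, 0.5), n, 9L,
              dimnames = list(NULL, paste0("L", 1:9)))
  A <- rbinom(n, 1L, expit(scenario$gamma0 + drop(L %*% scenario$gamma)))
  Y <- rbinom(n, 1L, expit(scenario$beta0 + scenario$beta_treat * A +
                             drop(L %*% scenario$beta)))
  cohort(Y, A, L)
}

#' Theoretical ("true") marginal effects of a scenario
#'
#' Computes the population marginal effects \eqn{\pi_1, \pi_0, \Delta\pi,
#' \theta} of a scenario by Monte-Carlo integration over the covariate
#' distribution, with treatment set by intervention rather than by the
#' confounded treatment model.
#'
#' For the ATE the counterfactual event probabilities are averaged over the
#' whole covariate population. For the ATT they are averaged over the treated
#' population, i.e. with covariate draws weighted by the true propensity
#' \eqn{P(A=1|L)} -- the covariate distribution induced by the scenario's
#' treatment model among treated subjects.
#'
#' Rather than drawing Bernoulli outcomes and refitting a univariate logistic
#' model (whose fitted arm probabilities converge to the same quantities),
#' the conditional event probabilities are averaged directly: this removes the
#' outcome-level Monte-Carlo noise and makes `mc_draws = 1e7` stable well
#' below the third decimal.
#'
#' @param scenario a [make_scenario()] object.
#' @param mc_draws number of covariate draws (>= 1e5; default 1e7).
#' @param seed integer seed.
#' @param chunk_size draws per chunk (memory control).
#' @return A list of class `cs_truth` with `pi1`, `pi0`, `delta`, `theta`
#'   (\eqn{\theta = logit(\pi_1) - logit(\pi_0)}) and `mc_draws`.
#' @examples
#' sc <- make_scenario("ATE", "alternative")
#' theoretical_effects(sc, mc_draws = 1e5, seed = 1)
#' @export
theoretical_effects <- function(scenario, mc_draws = 1e7, seed = NULL,
                                chunk_size = 1e6) {
  stopifnot(inherits(scenario, "cs_scenario"))
  if (mc_draws < 1e5)
    warning("mc_draws < 1e5: theoretical effects may not be stable to the third decimal")
  if (!is.null(seed)) set.seed(seed)
  att <- scenario$estimand == "ATT"
  s1 <- s0 <- sw <- 0
  remaining <- mc_draws
  while (remaining > 0) {
    m <- min(chunk_size, remaining)
    L <- matrix(rbinom(m * 9L, 1L, 0.5), m, 9L)
    blp <- scenario$beta0 + drop(L %*% scenario$beta)
    w <- if (att) expit(scenario$gamma0 + drop(L %*% scenario$gamma)) else rep(1, m)
    s1 <- s1 + sum(w * expit(blp + scenario$beta_treat))
    s0 <- s0 + sum(w * expit(blp))
    sw <- sw + sum(w)
    remaining <- remaining - m
  }
  pi1 <- s1 / sw
  pi0 <- s0 / sw
  structure(list(pi1 = pi1, pi0 = pi0, delta = pi1 - pi0,
                 theta = qlogis(pi1) - qlogis(pi0),
                 mc_draws = mc_draws),
            class = "cs_truth")
}

#' @export
print.cs_truth <- function(x, ...) {
  cat(sprintf("Theoretical effects (%g draws): pi1 = %.4f, pi0 = %.4f, delta = %.4f, theta = %.4f\n",
              x$mc_draws, x$pi1, x$pi0, x$delta, x$theta))
  invisible(x)
}
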