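#' Fit the Q-model (multivariable outcome regression)
#'
#' Maximum-likelihood logistic regression of the outcome on treatment and the
#' selected covariates (with intercept):
#' \eqn{logit P(Y=1|A,L) = \mu + \gamma A + \beta L}. This is the outcome
#' model standardized by g-computation and used as the initial estimator by
#' TMLE. The coefficient covariance is the inverse observed information.
#'
#' @param cohort a `cs_cohort`.
#' @param covariates integer covariate column indices; an empty vector
#'   reduces the model to the univariate logistic of Y on A.
#' @return An object of class `cs_qmodel`: `coef`, `vcov`, `covariates`,
#'   `converged` and the internal `glm` fit.
#' @export
fit_qmodel <- function(cohort, covariates = integer(0)) {
  stopifnot(inherits(cohort, "cs_cohort"))
  if (length(unique(cohort$A)) < 2L)
    stop("cohort must contain both treated and untreated subjects")
  if (length(unique(cohort$Y)) < 2L)
    stop("cohort must contain at least one event and one non-event")
  X <- cohort$L[, covariates, drop = FALSE]
  d <- data.frame(Y = cohort$Y, A = cohort$A, X, check.names = FALSE)
  fit <- suppressWarnings(
    glm(Y ~ ., family = binomial(), data = d, control = list(maxit = 100))
  )
  conv <- .glm_converged(fit)
  structure(list(
    coef = coef(fit),
    vcov = vcov(fit),
    covariates = as.integer(covariates),
    converged = conv,
    fit = fit
  ), class = "cs_qmodel")
}

# design matrices with treatment forced to a = 1 and a = 0
.q_design <- function(q, cohort) {
  X <- cohort$L[, q$covariates, drop = FALSE]
  list(X1 = cbind(1, 1, X), X0 = cbind(1, 0, X))
}

#' G-computation marginal effects
#'
#' Standardizes the Q-model predictions: for every subject the event
#' probability is predicted with treatment forced to 1 and to 0 (own
#' covariates retained), and the two prediction vectors are averaged -- over
#' all subjects for the ATE, over the treated subjects only for the ATT (the
#' Q-model itself is always fitted on the full cohort). Point estimates only;
#' see [gcomp_variance_parametric()] and [gcomp_variance_bootstrap()] for the
#' variance.
#'
#' @param q a converged `cs_qmodel`.
#' @param cohort the cohort it was fitted on.
#' @param estimand `"ATE"` or `"ATT"`.
#' @return A `cs_effects` record (variance fields `NA`).
#' @export
gcomp_effects <- function(q, cohort, estimand = c("ATE", "ATT")) {
  stopifnot(inherits(q, "cs_qmodel"), q$converged)
  estimand <- match.arg(estimand)
  d <- .q_design(q, cohort)
  p1 <- expit(drop(d$X1 %*% q$coef))
  p0 <- expit(drop(d$X0 %*% q$coef))
  keep <- if (estimand == "ATT") cohort$A == 1 else rep(TRUE, cohort$n)
  .effects_from_pis(mean(p1[keep]), mean(p0[keep]), NA_real_,
                    method = "gc", set = NA_character_, estimand = estimand)
}

#' Parametric-simulation variance for g-computation
#'
#' Draws coefficient vectors from the multivariate normal distribution
#' centred at the Q-model estimate with its covariance, recomputes the
#' standardized \eqn{\hat\theta} for each draw, and returns the empirical
#' variance of the draws.
#'
#' @param q a converged `cs_qmodel`.
#' @param cohort the cohort it was fitted on.
#' @param estimand `"ATE"` or `"ATT"`.
#' @param n_draws number of coefficient draws (>= 100; default 1000).
#' @param seed optional integer seed.
#' @return The simulated variance of \eqn{\hat\theta}.
#' @export
gcomp_variance_parametric <- function(q, cohort, estimand = c("ATE", "ATT"),
                                      n_draws = 1000, seed = NULL) {
  stopifnot(inherits(q, "cs_qmodel"), q$converged, n_draws >= 100)
  estimand <- match.arg(estimand)
  ev <- eigen(q$vcov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("Q-model coefficient covariance is not positive semi-definite")
  if (!is.null(seed)) set.seed(seed)
  B <- MASS::mvrnorm(n_draws, mu = q$coef, Sigma = q$vcov)
  d <- .q_design(q, cohort)
  keep <- if (estimand == "ATT") cohort$A == 1 else rep(TRUE, cohort$n)
  P1 <- 1 / (1 + exp(-tcrossprod(B, d$X1[keep, , drop = FALSE])))
  P0 <- 1 / (1 + exp(-tcrossprod(B, d$X0[keep, , drop = FALSE])))
  pi1 <- rowMeans(P1)
  pi0 <- rowMeans(P0)
  th <- qlogis(pi1) - qlogis(pi0)
  var(th[is.finite(th)])
}

#' Bootstrap variance for g-computation
#'
#' Nonparametric bootstrap of subjects with replacement: the Q-model is
#' refitted and \eqn{\hat\theta} recomputed for each resample. Resamples
#' where the refit fails (single-arm, constant outcome or non-convergence)
#' are dropped; a warning is raised when more than 20\% fail.
#'
#' @param cohort a `cs_cohort`.
#' @param covariates covariate indices of the Q-model.
#' @param estimand `"ATE"` or `"ATT"`.
#' @param n_boot number of resamples (>= 100).
#' @param seed optional integer seed.
#' @return List with `var_theta`, `n_failed`.
#' @export
gcomp_variance_bootstrap <- function(cohort, covariates,
                                     estimand = c("ATE", "ATT"),
                                     n_boot = 500, seed = NULL) {
  stopifnot(inherits(cohort, "cs_cohort"), n_boot >= 100)
  estimand <- match.arg(estimand)
  if (!is.null(seed)) set.seed(seed)
  th <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(cohort$n, cohort$n, replace = TRUE)
    cb <- cohort(cohort$Y[idx], cohort$A[idx], cohort$L[idx, , drop = FALSE])
    ok <- length(unique(cb$A)) == 2L && length(unique(cb$Y)) == 2L &&
      (estimand == "ATE" || any(cb$A == 1))
    if (!ok) next
    qb <- fit_qmodel(cb, covariates)
    if (!qb$converged) next
    eff <- gcomp_effects(qb, cb, estimand)
    th[b] <- eff$theta
  }
  n_failed <- sum(!is.finite(th))
  if (n_failed > 0.2 * n_boot)
    warning(sprintf("%d of %d bootstrap resamples failed", n_failed, n_boot))
  list(var_theta = var(th[is.finite(th)]), n_failed = n_failed)
}
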