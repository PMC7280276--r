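#' Targeted maximum likelihood estimation of the ATE
#'
#' Targets the g-computation (Q-model) estimate with a single canonical
#' fluctuation: the clever covariate \eqn{H(A, L) = A/g - (1-A)/(1-g)} (with
#' \eqn{g} the propensity score) enters an intercept-free logistic
#' fluctuation of \eqn{logit Q} with the initial \eqn{logit Q} as offset. The
#' fitted fluctuation coefficient \eqn{\epsilon} updates both counterfactual
#' prediction vectors on the logit scale (which keeps them inside (0,1)),
#' and the updated vectors are averaged into \eqn{\hat\pi_1^*},
#' \eqn{\hat\pi_0^*}. The estimator is doubly robust: it is consistent when
#' either the Q-model or the propensity model is correctly specified.
#'
#' Standard errors come from the efficient influence curve: the IC of
#' \eqn{\hat{\Delta\pi}} has mean zero at the solved fluctuation, and the
#' \eqn{\theta}-scale SE applies the delta method to the joint IC of
#' \eqn{(\hat\pi_1^*, \hat\pi_0^*)}. For numeric safety \eqn{g} is bounded
#' to [0.01, 0.99] inside the clever covariate only, and Q predictions to
#' \eqn{[10^{-6}, 1-10^{-6}]}.
#'
#' @param cohort a `cs_cohort`.
#' @param q a converged `cs_qmodel` fitted on the cohort.
#' @param ps a converged `cs_propensity` fitted on the cohort.
#' @return An object of class `cs_tmle`: initial predictions (`Q1`, `Q0`,
#'   `QA`), `g`, `epsilon`, updated predictions (`Q1_star`, `Q0_star`,
#'   `QA_star`), influence-curve components (`ic_pi1`, `ic_pi0`,
#'   `ic_delta`, `ic_theta`) and `effects` (a `cs_effects` on the
#'   \eqn{\theta} scale).
#' @export
tmle_ate <- function(cohort, q, ps) {
  stopifnot(inherits(cohort, "cs_cohort"), inherits(q, "cs_qmodel"),
            inherits(ps, "cs_propensity"), q$converged, ps$converged)
  A <- cohort$A; Y <- cohort$Y; n <- cohort$n
  d <- .q_design(q, cohort)
  Q1 <- .clip_prob(expit(drop(d$X1 %*% q$coef)))
  Q0 <- .clip_prob(expit(drop(d$X0 %*% q$coef)))
  QA <- ifelse(A == 1, Q1, Q0)
  g <- pmin(pmax(ps$p, 0.01), 0.99)
  H <- A / g - (1 - A) / (1 - g)
  fl <- .fluctuate(Y, H, offset = qlogis(QA))
  if (!fl$ok) return(.tmle_nonconverged("ATE", q, ps))
  eps <- fl$eps
  Q1s <- expit(qlogis(Q1) + eps / g)
  Q0s <- expit(qlogis(Q0) - eps / (1 - g))
  QAs <- ifelse(A == 1, Q1s, Q0s)
  pi1 <- mean(Q1s); pi0 <- mean(Q0s)
  ic1 <- A / g * (Y - QAs) + Q1s - pi1
  ic0 <- (1 - A) / (1 - g) * (Y - QAs) + Q0s - pi0
  .tmle_result("ATE", q, ps, Q1, Q0, QA, g, eps, Q1s, Q0s, QAs,
               pi1, pi0, ic1, ic0, n)
}

#' Targeted maximum likelihood estimation of the ATT
#'
#' ATT targeting via the weighted-fluctuation construction: the fluctuation
#' logistic model uses subject weights \eqn{A + (1-A) g/(1-g)} (standardizing
#' the untreated to the treated covariate distribution) with the signed
#' clever covariate \eqn{H = 2A - 1} and the initial \eqn{logit Q} as offset.
#' The updated counterfactual predictions are averaged over the treated
#' subjects only.
#'
#' @inheritParams tmle_ate
#' @return A `cs_tmle` object (see [tmle_ate()]); influence-curve components
#'   are for the treated-population means.
#' @export
tmle_att <- function(cohort, q, ps) {
  stopifnot(inherits(cohort, "cs_cohort"), inherits(q, "cs_qmodel"),
            inherits(ps, "cs_propensity"), q$converged, ps$converged)
  A <- cohort$A; Y <- cohort$Y; n <- cohort$n
  d <- .q_design(q, cohort)
  Q1 <- .clip_prob(expit(drop(d$X1 %*% q$coef)))
  Q0 <- .clip_prob(expit(drop(d$X0 %*% q$coef)))
  QA <- ifelse(A == 1, Q1, Q0)
  g <- pmin(pmax(ps$p, 0.01), 0.99)
  wt <- A + (1 - A) * g / (1 - g)
  H <- 2 * A - 1
  fl <- .fluctuate(Y, H, offset = qlogis(QA), weights = wt)
  if (!fl$ok) return(.tmle_nonconverged("ATT", q, ps))
  eps <- fl$eps
  Q1s <- expit(qlogis(Q1) + eps)
  Q0s <- expit(qlogis(Q0) - eps)
  QAs <- ifelse(A == 1, Q1s, Q0s)
  treated <- A == 1
  pi1 <- mean(Q1s[treated]); pi0 <- mean(Q0s[treated])
  pA <- mean(A)
  ic1 <- A / pA * (Y - pi1)
  ic0 <- (1 - A) * g / ((1 - g) * pA) * (Y - Q0s) + A / pA * (Q0s - pi0)
  .tmle_result("ATT", q, ps, Q1, Q0, QA, g, eps, Q1s, Q0s, QAs,
               pi1, pi0, ic1, ic0, n)
}

# intercept-free logistic fluctuation with offset; returns epsilon
.fluctuate <- function(Y, H, offset, weights = NULL) {
  d <- data.frame(Y = Y, H = H)
  fit <- tryCatch(suppressWarnings(
    glm(Y ~ H - 1, family = quasibinomial(), data = d, offset = offset,
        weights = weights, control = list(maxit = 100))
  ), error = function(e) NULL)
  if (is.null(fit) || !isTRUE(fit$converged) || !all(is.finite(coef(fit))))
    return(list(ok = FALSE, eps = NA_real_))
  list(ok = TRUE, eps = unname(coef(fit)["H"]))
}

.tmle_result <- function(estimand, q, ps, Q1, Q0, QA, g, eps, Q1s, Q0s, QAs,
                         pi1, pi0, ic1, ic0, n) {
  ic_delta <- ic1 - ic0
  ic_theta <- ic1 / (pi1 * (1 - pi1)) - ic0 / (pi0 * (1 - pi0))
  var_theta <- var(ic_theta) / n
  structure(list(
    estimand = estimand,
    Q1 = Q1, Q0 = Q0, QA = QA, g = g, epsilon = eps,
    Q1_star = Q1s, Q0_star = Q0s, QA_star = QAs,
    ic_pi1 = ic1, ic_pi0 = ic0, ic_delta = ic_delta, ic_theta = ic_theta,
    effects = .effects_from_pis(pi1, pi0, var_theta, method = "tmle",
                                set = NA_character_, estimand = estimand)
  ), class = "cs_tmle")
}

.tmle_nonconverged <- function(estimand, q, ps) {
  structure(list(
    estimand = estimand, epsilon = NA_real_,
    effects = .effects_nonconverged("tmle", NA_character_, estimand)
  ), class = "cs_tmle")
}

#' @export
print.cs_tmle <- function(x, ...) {
  cat("TMLE (", x$estimand, "), epsilon = ", signif(x$epsilon, 4), "\n", sep = "")
  print(x$effects)
  invisible(x)
}

#' Influence-curve standard error of a TMLE fit
#'
#' \eqn{SE(\hat{\Delta\pi}) = \sqrt{Var(IC_\Delta)/n}};
#' \eqn{SE(\hat\theta)} applies the delta method
#' (\eqn{d\,logit(\pi)/d\pi = 1/(\pi(1-\pi))}) to the joint influence curve
#' of \eqn{(\hat\pi_1^*, \hat\pi_0^*)}.
#'
#' @param fit a converged `cs_tmle`.
#' @param scale `"theta"` (log marginal OR) or `"delta"` (risk difference).
#' @return The standard error.
#' @export
influence_curve_se <- function(fit, scale = c("theta", "delta")) {
  stopifnot(inherits(fit, "cs_tmle"), fit$effects$converged)
  scale <- match.arg(scale)
  ic <- if (scale == "theta") fit$ic_theta else fit$ic_delta
  sqrt(var(ic) / length(ic))
}
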