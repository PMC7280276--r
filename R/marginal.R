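#' Weighted univariate marginal outcome model
#'
#' Fits the weighted logistic regression
#' \eqn{logit P(Y=1|A) = \alpha_0 + \alpha_1 A} shared by IPTW and full
#' matching: the weights build the pseudo-population in which confounders are
#' balanced, and \eqn{\hat\theta = \hat\alpha_1} is the marginal log odds
#' ratio. The variance of \eqn{\hat\alpha_1} is the robust HC0 sandwich
#' (see [sandwich_variance()]).
#'
#' The fit is flagged non-converged when one arm has zero total weight or a
#' weighted event rate of exactly 0 or 1 (infinite coefficients).
#'
#' @param cohort a `cs_cohort`.
#' @param weights a `cs_weights` object, or `NULL` for unit weights.
#' @param variance `"sandwich"` (robust HC0, the IPTW convention) or
#'   `"model"` (classical inverse weighted information with dispersion 1).
#'   The model-based form is what the full-matching pipeline uses: it
#'   ignores both the weight variability and the matched structure, which is
#'   exactly what produces the anticonservative full-matching intervals seen
#'   in the benchmark (strongly negative variance-estimation bias).
#' @return A list with `alpha0`, `alpha1`, `var_alpha1`, `converged`.
#' @export
weighted_outcome_fit <- function(cohort, weights = NULL,
                                 variance = c("sandwich", "model")) {
  stopifnot(inherits(cohort, "cs_cohort"))
  variance <- match.arg(variance)
  w <- if (is.null(weights)) rep(1, cohort$n) else weights$w
  stopifnot(length(w) == cohort$n)
  A <- cohort$A; Y <- cohort$Y
  bad <- FALSE
  for (a in 0:1) {
    sw <- sum(w[A == a])
    if (sw <= 0) bad <- TRUE
    else {
      r <- sum(w[A == a & Y == 1]) / sw
      if (r <= 0 || r >= 1) bad <- TRUE
    }
  }
  if (bad)
    return(list(alpha0 = NA_real_, alpha1 = NA_real_, var_alpha1 = NA_real_,
                converged = FALSE))
  d <- data.frame(Y = Y, A = A)
  fit <- suppressWarnings(
    glm(Y ~ A, family = quasibinomial(), data = d, weights = w,
        control = list(maxit = 100))
  )
  al <- coef(fit)
  v <- .sandwich_a1(A, Y, w, fitted(fit), meat = variance == "sandwich")
  list(alpha0 = unname(al[1]), alpha1 = unname(al[2]),
       var_alpha1 = v$var_alpha1,
       converged = isTRUE(fit$converged) && !v$singular)
}

# HC0 sandwich (meat = TRUE) or classical model-based variance (meat = FALSE)
# for the 2-parameter weighted logistic of Y on A. Score contribution of
# subject i is w_i (y_i - mu_i) x_i, so a uniform rescaling of the weights
# cancels between bread and meat in the sandwich form.
.sandwich_a1 <- function(A, Y, w, mu, meat = TRUE) {
  X <- cbind(1, A)
  info <- crossprod(X, X * (w * mu * (1 - mu)))
  if (!is.finite(determinant(info)$modulus) || abs(det(info)) < 1e-12)
    return(list(var_alpha1 = NA_real_, singular = TRUE))
  bread <- solve(info)
  V <- if (meat) {
    U <- X * (w * (Y - mu))
    bread %*% crossprod(U) %*% bread
  } else bread
  list(var_alpha1 = V[2, 2], singular = FALSE)
}

#' Robust sandwich variance of the marginal log odds ratio
#'
#' HC0 sandwich estimator for the treatment coefficient of the weighted
#' univariate logistic model: bread = inverse of the weighted observed
#' information, meat = sum of squared per-subject weighted score
#' contributions \eqn{w_i (y_i - \mu_i) x_i}. Weights are treated as fixed
#' known quantities (the uncertainty of the propensity fit is ignored, which
#' is the conservative convention for stabilized IPTW). With this form a
#' uniform rescaling of all weights leaves the variance unchanged.
#'
#' @param cohort a `cs_cohort`.
#' @param weights a `cs_weights` (or `NULL` for unit weights).
#' @param alpha0,alpha1 fitted coefficients of the marginal model.
#' @return The sandwich variance of `alpha1` (`NA` with a warning if the
#'   information matrix is singular).
#' @export
sandwich_variance <- function(cohort, weights, alpha0, alpha1) {
  stopifnot(inherits(cohort, "cs_cohort"))
  w <- if (is.null(weights)) rep(1, cohort$n) else weights$w
  mu <- expit(alpha0 + alpha1 * cohort$A)
  v <- .sandwich_a1(cohort$A, cohort$Y, w, mu)
  if (v$singular) warning("singular information matrix in sandwich variance")
  v$var_alpha1
}

#' Marginal effects from the marginal-model coefficients
#'
#' Maps \eqn{(\hat\alpha_0, \hat\alpha_1)} to the marginal effect scales:
#' \eqn{\hat\pi_0 = expit(\hat\alpha_0)}, \eqn{\hat\pi_1 =
#' expit(\hat\alpha_0 + \hat\alpha_1)}, \eqn{\hat\theta = \hat\alpha_1},
#' \eqn{\hat{\Delta\pi} = \hat\pi_1 - \hat\pi_0}, with a 95\% Wald interval
#' \eqn{\hat\alpha_1 \pm 1.96 \sqrt{var}} for \eqn{\theta}.
#'
#' @param alpha0,alpha1 marginal-model coefficients.
#' @param var_alpha1 variance of `alpha1`.
#' @param method,set,estimand optional descriptor tags carried along.
#' @param converged convergence flag carried along.
#' @return An object of class `cs_effects`: `pi0`, `pi1`, `delta`, `theta`,
#'   `var_theta`, `se`, `ci_low`, `ci_high`, `converged` plus tags.
#' @export
effects_from_alpha <- function(alpha0, alpha1, var_alpha1,
                               method = NA_character_, set = NA_character_,
                               estimand = NA_character_, converged = TRUE) {
  pi0 <- expit(alpha0)
  pi1 <- expit(alpha0 + alpha1)
  se <- sqrt(var_alpha1)
  z <- qnorm(0.975)
  structure(list(
    pi0 = pi0, pi1 = pi1, delta = pi1 - pi0, theta = alpha1,
    var_theta = var_alpha1, se = se,
    ci_low = alpha1 - z * se, ci_high = alpha1 + z * se,
    converged = isTRUE(converged),
    method = method, set = set, estimand = estimand
  ), class = "cs_effects")
}

# effects record from counterfactual means (g-computation / TMLE path)
.effects_from_pis <- function(pi1, pi0, var_theta, method, set, estimand,
                              converged = TRUE) {
  theta <- qlogis(pi1) - qlogis(pi0)
  se <- sqrt(var_theta)
  z <- qnorm(0.975)
  structure(list(
    pi0 = pi0, pi1 = pi1, delta = pi1 - pi0, theta = theta,
    var_theta = var_theta, se = se,
    ci_low = theta - z * se, ci_high = theta + z * se,
    converged = isTRUE(converged),
    method = method, set = set, estimand = estimand
  ), class = "cs_effects")
}

.effects_nonconverged <- function(method, set, estimand) {
  structure(list(
    pi0 = NA_real_, pi1 = NA_real_, delta = NA_real_, theta = NA_real_,
    var_theta = NA_real_, se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    converged = FALSE, method = method, set = set, estimand = estimand
  ), class = "cs_effects")
}

#' @export
print.cs_effects <- function(x, ...) {
  if (!x$converged) {
    cat("Marginal effects (", x$method, "): not converged\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Marginal effects (%s%s):\n", x$method,
              if (!is.na(x$estimand)) paste0(", ", x$estimand) else ""))
  cat(sprintf("  pi0 = %.4f  pi1 = %.4f  delta = %.4f\n", x$pi0, x$pi1, x$delta))
  cat(sprintf("  theta (log marginal OR) = %.4f  SE = %.4f  95%% CI [%.4f, %.4f]\n",
              x$theta, x$se, x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
as.data.frame.cs_effects <- function(x, ...) {
  data.frame(method = x$method, set = x$set, estimand = x$estimand,
             pi0 = x$pi0, pi1 = x$pi1, delta = x$delta, theta = x$theta,
             se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
             converged = x$converged)
}
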