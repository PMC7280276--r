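#' Fit the propensity score model
#'
#' Maximum-likelihood logistic regression of treatment on the selected
#' covariates (with intercept). Fitted probabilities are truncated to
#' \eqn{[10^{-6}, 1-10^{-6}]} for numeric safety only; the simulation design
#' guarantees positivity so no further trimming is applied.
#'
#' A fit is flagged non-converged when the optimizer fails to converge within
#' 100 iterations, when complete or quasi-complete separation is detected
#' (any fitted |linear predictor| > 30), or when the information matrix is
#' singular. Downstream estimators treat a non-converged propensity fit as a
#' non-convergent replicate rather than an error.
#'
#' @param cohort a `cs_cohort`.
#' @param covariates integer covariate column indices (e.g. from
#'   [covariate_subset()]).
#' @return An object of class `cs_propensity`: list with `p` (fitted
#'   probabilities), `marginal_treated` (raw proportion treated, used for
#'   weight stabilization), `coef`, `converged`.
#' @export
fit_propensity <- function(cohort, covariates) {
  stopifnot(inherits(cohort, "cs_cohort"))
  if (length(unique(cohort$A)) < 2L)
    stop("cohort must contain both treated and untreated subjects")
  X <- cohort$L[, covariates, drop = FALSE]
  d <- data.frame(A = cohort$A, X, check.names = FALSE)
  fit <- suppressWarnings(
    glm(A ~ ., family = binomial(), data = d, control = list(maxit = 100))
  )
  conv <- .glm_converged(fit)
  structure(list(
    p = .clip_prob(fitted(fit)),
    marginal_treated = mean(cohort$A),
    coef = coef(fit),
    converged = conv
  ), class = "cs_propensity")
}

# shared convergence screen: optimizer status, separation, singular information
.glm_converged <- function(fit, lp_bound = 30) {
  isTRUE(fit$converged) &&
    all(abs(predict(fit, type = "link")) <= lp_bound) &&
    fit$qr$rank == ncol(stats::model.matrix(fit)) &&
    all(is.finite(coef(fit)))
}

#' Stabilized IPTW weights for the ATE
#'
#' Evaluates the stabilized inverse-probability weights
#' \eqn{\omega_i = A_i P(A=1)/p_i + (1-A_i) P(A=0)/(1-p_i)}, with
#' \eqn{P(A=1)} the raw sample proportion treated. Under a correctly
#' specified propensity model the sample mean of the weights tends to 1.
#'
#' @param fit a converged `cs_propensity`.
#' @param A treatment vector.
#' @return An object of class `cs_weights` with fields `w`, `target` and
#'   `rescaled`.
#' @export
iptw_weights_ate <- function(fit, A) {
  stopifnot(inherits(fit, "cs_propensity"), fit$converged)
  pA <- fit$marginal_treated
  w <- A * pA / fit$p + (1 - A) * (1 - pA) / (1 - fit$p)
  structure(list(w = w, target = "ATE", rescaled = FALSE), class = "cs_weights")
}

#' IPTW weights for the ATT
#'
#' Treated subjects receive weight 1; untreated subjects receive the odds of
#' treatment \eqn{p_i/(1-p_i)}, standardizing the untreated arm to the
#' covariate distribution of the treated.
#'
#' @inheritParams iptw_weights_ate
#' @return A `cs_weights` object with `target = "ATT"`.
#' @export
iptw_weights_att <- function(fit, A) {
  stopifnot(inherits(fit, "cs_propensity"), fit$converged)
  w <- A + (1 - A) * fit$p / (1 - fit$p)
  structure(list(w = w, target = "ATT", rescaled = FALSE), class = "cs_weights")
}

#' Weighted standardized differences of covariates
#'
#' Covariate-balance diagnostic: for each covariate the weighted prevalences
#' in the treated and untreated arms are compared via
#' \eqn{d = 100 (\bar p_t - \bar p_u) / \sqrt{(\bar p_t (1-\bar p_t) +
#' \bar p_u (1-\bar p_u))/2}} (the standard formulation for binary
#' covariates). An absolute value above 10\% is conventionally read as
#' imbalance.
#'
#' @param cohort a `cs_cohort`.
#' @param covariates covariate column indices to report.
#' @param weights a `cs_weights` object, or `NULL` for unit weights.
#' @return A data frame with columns `covariate`, `std_diff_pct`,
#'   `flag_gt_10pct`.
#' @export
standardized_differences <- function(cohort, covariates, weights = NULL) {
  stopifnot(inherits(cohort, "cs_cohort"))
  w <- if (is.null(weights)) rep(1, cohort$n) else weights$w
  stopifnot(length(w) == cohort$n)
  A <- cohort$A
  if (sum(w[A == 1]) <= 0 || sum(w[A == 0]) <= 0)
    stop("zero total weight in one treatment arm")
  X <- cohort$L[, covariates, drop = FALSE]
  pt <- colSums(X[A == 1, , drop = FALSE] * w[A == 1]) / sum(w[A == 1])
  pu <- colSums(X[A == 0, , drop = FALSE] * w[A == 0]) / sum(w[A == 0])
  denom <- sqrt((pt * (1 - pt) + pu * (1 - pu)) / 2)
  d <- ifelse(pt == pu, 0, 100 * (pt - pu) / denom)
  data.frame(covariate = colnames(X), std_diff_pct = unname(d),
             flag_gt_10pct = unname(abs(d) > 10), row.names = NULL)
}
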