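#' Run one simulation replicate
#'
#' Generates one cohort from the scenario and applies one estimator with one
#' covariate-set strategy. When `scenario$unmeasured` is `TRUE` the cohort is
#' generated with L1 but L1 is removed from the analysis covariates.
#' Non-convergence (of the propensity model, the Q-model, the marginal model
#' or the TMLE fluctuation, or a degenerate cohort such as a single-arm draw
#' at small n) is recorded in the result, never raised.
#'
#' @param scenario a [make_scenario()] object.
#' @param n cohort size.
#' @param method one of `"gc"`, `"iptw"`, `"fm"`, `"tmle"`.
#' @param set_name covariate-set strategy (see [covariate_subset()]).
#' @param seed integer replicate seed; generation and variance simulation run
#'   on disjoint child streams spawned from it.
#' @param n_draws coefficient draws for the g-computation parametric
#'   variance.
#' @param variance `"parametric"` (default) or `"none"` (point estimates
#'   only; relevant for g-computation bias studies).
#' @return A one-row data frame: scenario descriptors, `seed`, `converged`,
#'   `pi0`, `pi1`, `delta`, `theta`, `var_theta`, `ci_low`, `ci_high`.
#' @export
run_replicate <- function(scenario, n, method = c("gc", "iptw", "fm", "tmle"),
                          set_name = c("outcome", "treatment", "common", "entire"),
                          seed, n_draws = 1000,
                          variance = c("parametric", "none")) {
  method <- match.arg(method)
  set_name <- match.arg(set_name)
  variance <- match.arg(variance)
  seeds <- spawn_seeds(seed, 2)
  ch <- generate_cohort(scenario, n, seeds[1])
  eff <- .analyze_cohort(ch, scenario, method, set_name,
                         n_draws = n_draws, var_seed = seeds[2],
                         variance = variance)
  data.frame(estimand = scenario$estimand, hypothesis = scenario$hypothesis,
             n = n, method = method, set = set_name,
             unmeasured = scenario$unmeasured, seed = seed,
             converged = eff$converged, pi0 = eff$pi0, pi1 = eff$pi1,
             delta = eff$delta, theta = eff$theta, var_theta = eff$var_theta,
             ci_low = eff$ci_low, ci_high = eff$ci_high)
}

# apply one estimator/set to an existing cohort; returns a cs_effects
.analyze_cohort <- function(ch, scenario, method, set_name, n_draws = 1000,
                            var_seed = NULL, variance = "parametric") {
  estimand <- scenario$estimand
  covs <- covariate_subset(set_name, scenario$unmeasured)
  fail <- function() .effects_nonconverged(method, set_name, estimand)
  if (length(unique(ch$A)) < 2L || length(unique(ch$Y)) < 2L) return(fail())
  eff <- tryCatch({
    if (method == "gc") {
      q <- fit_qmodel(ch, covs)
      if (!q$converged) return(fail())
      e <- gcomp_effects(q, ch, estimand)
      if (variance == "parametric") {
        v <- gcomp_variance_parametric(q, ch, estimand, n_draws = n_draws,
                                       seed = var_seed)
        e <- .effects_from_pis(e$pi1, e$pi0, v, "gc", set_name, estimand)
      }
      e
    } else if (method == "iptw") {
      ps <- fit_propensity(ch, covs)
      if (!ps$converged) return(fail())
      w <- if (estimand == "ATE") iptw_weights_ate(ps, ch$A) else iptw_weights_att(ps, ch$A)
      f <- weighted_outcome_fit(ch, w)
      if (!f$converged) return(fail())
      effects_from_alpha(f$alpha0, f$alpha1, f$var_alpha1, "iptw", set_name, estimand)
    } else if (method == "fm") {
      ps <- fit_propensity(ch, covs)
      if (!ps$converged) return(fail())
      st <- full_match(ps, ch$A)
      w <- if (estimand == "ATE") fm_weights_ate(st, ch$A, ps$marginal_treated)
           else fm_weights_att(st, ch$A)
      f <- weighted_outcome_fit(ch, w, variance = "model")
      if (!f$converged) return(fail())
      effects_from_alpha(f$alpha0, f$alpha1, f$var_alpha1, "fm", set_name, estimand)
    } else {
      q <- fit_qmodel(ch, covs)
      ps <- fit_propensity(ch, covs)
      if (!q$converged || !ps$converged) return(fail())
      tm <- if (estimand == "ATE") tmle_ate(ch, q, ps) else tmle_att(ch, q, ps)
      e <- tm$effects
      e$set <- set_name
      e
    }
  }, error = function(e) fail())
  eff$method <- method
  eff$set <- set_name
  eff
}

#' Summarize replicate results into performance metrics
#'
#' Computes the performance criteria of the Monte-Carlo study from a set of
#' replicate results and the theoretical truth: signed mean bias of
#' \eqn{\hat\pi_0, \hat\pi_1, \hat{\Delta\pi}, \hat\theta}; the MSE
#' \eqn{E[(\hat\theta - \theta)^2]} and its square root; the variance
#' estimation bias \eqn{VEB = 100 (\sqrt{E[\widehat{Var}(\hat\theta)]} /
#' \sqrt{Var(\hat\theta)} - 1)}; the empirical coverage of the nominal 95\%
#' CI (percentage of CIs containing the true \eqn{\theta}); the rejection
#' rate (percentage of CIs excluding 0 -- power under the alternative
#' hypothesis, type-I error under the null); and the percentage of
#' non-convergence. Metrics use converged replicates only.
#'
#' @param results data frame of [run_replicate()] rows (one scenario cell).
#' @param truth a [theoretical_effects()] object (or list with `pi0`, `pi1`,
#'   `delta`, `theta`).
#' @return A one-row data frame of performance metrics.
#' @export
compute_metrics <- function(results, truth) {
  ok <- results[results$converged & is.finite(results$theta), , drop = FALSE]
  if (nrow(ok) == 0L) stop("no converged replicates")
  has_var <- is.finite(ok$var_theta)
  veb <- if (any(has_var) && nrow(ok) > 1L)
    100 * (sqrt(mean(ok$var_theta[has_var])) / sd(ok$theta) - 1) else NA_real_
  cover <- if (any(has_var))
    100 * mean(ok$ci_low <= truth$theta & truth$theta <= ok$ci_high, na.rm = TRUE)
    else NA_real_
  reject <- if (any(has_var))
    100 * mean(ok$ci_low > 0 | ok$ci_high < 0, na.rm = TRUE) else NA_real_
  data.frame(
    reps = nrow(results), n_converged = nrow(ok),
    nonconv_pct = 100 * (1 - nrow(ok) / nrow(results)),
    bias_pi0 = mean(ok$pi0) - truth$pi0,
    bias_pi1 = mean(ok$pi1) - truth$pi1,
    bias_delta = mean(ok$delta) - truth$delta,
    bias_theta = mean(ok$theta) - truth$theta,
    mse_theta = mean((ok$theta - truth$theta)^2),
    rmse_theta = sqrt(mean((ok$theta - truth$theta)^2)),
    veb_pct = veb, coverage_pct = cover, reject_pct = reject
  )
}

#' Run a Monte-Carlo benchmarking study
#'
#' Orchestrates the factorial experiment: for each replicate one cohort is
#' generated per sample size and every requested method x covariate-set
#' combination is applied to it (mirroring a design where all estimators see
#' the same data sets); results are then summarized per cell with
#' [compute_metrics()]. The run is deterministic given `master_seed`
#' regardless of `cores`, because every replicate runs on its own spawned
#' seed.
#'
#' @param scenario a [make_scenario()] object.
#' @param n vector of cohort sizes.
#' @param methods subset of `c("gc", "iptw", "fm", "tmle")`.
#' @param sets subset of `c("outcome", "treatment", "common", "entire")`.
#' @param reps replicates per cell (default 1000).
#' @param master_seed master seed spawning one child seed per replicate.
#' @param truth optional precomputed [theoretical_effects()]; when `NULL` it
#'   is computed once at `truth_draws` covariate draws.
#' @param truth_draws Monte-Carlo size for the truth oracle (default 1e7).
#' @param n_draws g-computation parametric-variance draws per replicate.
#' @param variance `"parametric"` or `"none"` (see [run_replicate()]).
#' @param cores parallel workers via `parallel::mclapply` (results are
#'   identical for any value).
#' @return A long-format data frame: one row per n x method x set with the
#'   scenario descriptors and all performance metrics.
#' @export
run_study <- function(scenario, n = c(100, 300, 500, 2000),
                      methods = c("gc", "iptw", "fm", "tmle"),
                      sets = c("outcome", "treatment", "common", "entire"),
                      reps = 1000, master_seed = 42,
                      truth = NULL, truth_draws = 1e7,
                      n_draws = 1000, variance = "parametric", cores = 1) {
  stopifnot(inherits(scenario, "cs_scenario"))
  methods <- match.arg(methods, c("gc", "iptw", "fm", "tmle"), several.ok = TRUE)
  sets <- match.arg(sets, c("outcome", "treatment", "common", "entire"),
                    several.ok = TRUE)
  if (is.null(truth))
    truth <- theoretical_effects(scenario, mc_draws = truth_draws,
                                 seed = spawn_seeds(master_seed, 1))
  rep_seeds <- spawn_seeds(master_seed + 1L, reps)
  one_rep <- function(r) {
    seeds <- spawn_seeds(rep_seeds[r], 2L * length(n))
    out <- vector("list", length(n) * length(methods) * length(sets))
    k <- 0L
    for (i in seq_along(n)) {
      ch <- generate_cohort(scenario, n[i], seeds[2L * i - 1L])
      for (m in methods) for (s in sets) {
        eff <- .analyze_cohort(ch, scenario, m, s, n_draws = n_draws,
                               var_seed = seeds[2L * i], variance = variance)
        k <- k + 1L
        out[[k]] <- data.frame(rep = r, n = n[i], method = m, set = s,
                               converged = eff$converged, pi0 = eff$pi0,
                               pi1 = eff$pi1, delta = eff$delta,
                               theta = eff$theta, var_theta = eff$var_theta,
                               ci_low = eff$ci_low, ci_high = eff$ci_high)
      }
    }
    do.call(rbind, out)
  }
  rows <- if (cores > 1L) {
    parallel::mclapply(seq_len(reps), one_rep, mc.cores = cores)
  } else {
    lapply(seq_len(reps), one_rep)
  }
  all <- do.call(rbind, rows)
  cells <- expand.grid(n = n, method = methods, set = sets,
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- all[all$n == cells$n[i] & all$method == cells$method[i] &
                 all$set == cells$set[i], , drop = FALSE]
    cbind(data.frame(estimand = scenario$estimand,
                     hypothesis = scenario$hypothesis,
                     unmeasured = scenario$unmeasured,
                     n = cells$n[i], method = cells$method[i],
                     set = cells$set[i]),
          compute_metrics(sub, truth))
  })
  res <- do.call(rbind, out)
  attr(res, "truth") <- truth
  res
}
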