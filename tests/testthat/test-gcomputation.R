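test_that("Q-model recovers generating coefficients and nests the univariate fit", {
  sc <- make_scenario("ATE", "alternative")
  ch <- generate_cohort(sc, 1e5, seed = 40)
  q <- fit_qmodel(ch, covariate_subset("outcome"))
  expect_true(q$converged)
  expect_lt(abs(unname(q$coef["A"]) - log(2)), 0.05)
  expect_lt(max(abs(q$coef[paste0("L", 1:6)] - sc$beta[1:6])), 0.1)
  expect_true(isSymmetric(q$vcov, tol = 1e-10))
  expect_true(all(eigen(q$vcov, only.values = TRUE)$values > 0))

  # no covariate effects under the null with gamma = 0
  sc0 <- make_scenario("ATE", "null")
  sc0$beta <- rep(0, 9)
  ch0 <- generate_cohort(sc0, 1e5, seed = 41)
  q0 <- fit_qmodel(ch0, integer(0))
  expect_lt(abs(unname(q0$coef["A"])), 0.05)

  # empty covariate list reduces to the univariate logistic of Y on A
  qa <- fit_qmodel(ch, integer(0))
  f <- weighted_outcome_fit(ch)
  expect_equal(unname(qa$coef), c(f$alpha0, f$alpha1), tolerance = 1e-8)
})

test_that("standardization over the empty Q-model returns the arm event rates", {
  ch <- cohort_from_counts(30, 20, 15, 35)
  q <- fit_qmodel(ch, integer(0))
  e <- gcomp_effects(q, ch, "ATE")
  expect_equal(e$pi1, 30 / 50, tolerance = 1e-8)
  expect_equal(e$pi0, 15 / 50, tolerance = 1e-8)
  expect_equal(e$theta, logor_2x2(30, 20, 15, 35), tolerance = 1e-7)
})

test_that("a zero treatment coefficient forces identical counterfactual means", {
  ch <- cohort_from_counts(25, 25, 25, 25)
  q <- fit_qmodel(ch, 1L)
  q$coef["A"] <- 0
  e <- gcomp_effects(q, ch, "ATE")
  expect_equal(e$pi1, e$pi0)
  expect_equal(e$theta, 0)
  expect_equal(e$delta, 0)
})

test_that("ATT standardization averages over the treated rows only", {
  # construct a cohort where treated and untreated differ in L by design
  set.seed(50)
  n <- 4000
  L <- matrix(rbinom(n, 1, 0.5), n, 1)
  A <- rbinom(n, 1, plogis(-1 + 2 * L[, 1]))
  Y <- rbinom(n, 1, plogis(-1 + 0.5 * A + 1.5 * L[, 1]))
  ch <- cohort(Y, A, L)
  q <- fit_qmodel(ch, 1L)
  co <- q$coef
  X <- cbind(1, 1, L); X0 <- cbind(1, 0, L)
  p1 <- plogis(drop(X %*% co)); p0 <- plogis(drop(X0 %*% co))
  eatt <- gcomp_effects(q, ch, "ATT")
  expect_equal(eatt$pi1, mean(p1[A == 1]), tolerance = 1e-10)
  expect_equal(eatt$pi0, mean(p0[A == 1]), tolerance = 1e-10)
  eate <- gcomp_effects(q, ch, "ATE")
  # treated carry more L=1, so their counterfactual risks are higher
  expect_gt(eatt$pi1, eate$pi1)
  expect_gt(eatt$pi0, eate$pi0)
  expect_true(all(c(eatt$pi0, eatt$pi1, eate$pi0, eate$pi1) >= 0 &
                    c(eatt$pi0, eatt$pi1, eate$pi0, eate$pi1) <= 1))
})

test_that("g-computation is consistent for the theoretical effect", {
  sc <- make_scenario("ATE", "alternative")
  ch <- generate_cohort(sc, 5e5, seed = 42)
  q <- fit_qmodel(ch, covariate_subset("outcome"))
  e <- gcomp_effects(q, ch, "ATE")
  expect_lt(abs(e$theta - exact_truth(sc)$theta), 0.02)
})

test_that("estimation error shrinks with n", {
  sc <- make_scenario("ATE", "alternative")
  truth <- exact_truth(sc)$theta
  med_err <- sapply(c(100, 1000, 2e4), function(n) {
    errs <- sapply(1:30, function(r) {
      ch <- generate_cohort(sc, n, seed = 7000 + r)
      q <- try(fit_qmodel(ch, covariate_subset("outcome")), silent = TRUE)
      if (inherits(q, "try-error") || !q$converged) return(NA_real_)
      abs(gcomp_effects(q, ch, "ATE")$theta - truth)
    })
    median(errs, na.rm = TRUE)
  })
  expect_true(med_err[2] < med_err[1] && med_err[3] < med_err[2])
})

test_that("parametric-simulation variance is stable and degenerate at vcov = 0", {
  sc <- make_scenario("ATE", "alternative")
  ch <- generate_cohort(sc, 2000, seed = 43)
  q <- fit_qmodel(ch, covariate_subset("outcome"))
  v1 <- gcomp_variance_parametric(q, ch, "ATE", n_draws = 1000, seed = 1)
  v2 <- gcomp_variance_parametric(q, ch, "ATE", n_draws = 2000, seed = 2)
  expect_lt(abs(v2 / v1 - 1), 0.10)

  q0 <- q
  q0$vcov <- matrix(0, nrow(q$vcov), ncol(q$vcov))
  expect_equal(gcomp_variance_parametric(q0, ch, "ATE", seed = 3), 0)

  qb <- q
  qb$vcov[1, 2] <- qb$vcov[2, 1] <- 1e3  # not PSD
  expect_error(gcomp_variance_parametric(qb, ch, "ATE", seed = 4),
               "positive semi-definite")
})

test_that("bootstrap variance is deterministic and close to the parametric one", {
  sc <- make_scenario("ATE", "alternative")
  ch <- generate_cohort(sc, 2000, seed = 44)
  b1 <- gcomp_variance_bootstrap(ch, covariate_subset("outcome"), "ATE",
                                 n_boot = 200, seed = 5)
  b2 <- gcomp_variance_bootstrap(ch, covariate_subset("outcome"), "ATE",
                                 n_boot = 200, seed = 5)
  expect_identical(b1, b2)
  expect_equal(b1$n_failed, 0)
  q <- fit_qmodel(ch, covariate_subset("outcome"))
  vp <- gcomp_variance_parametric(q, ch, "ATE", seed = 6)
  expect_lt(abs(sqrt(b1$var_theta) / sqrt(vp) - 1), 0.15)
})
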