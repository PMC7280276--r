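test_that("ATE influence curve has mean zero at the solved fluctuation", {
  sc <- make_scenario("ATE", "alternative")
  for (s in 1:3) {
    ch <- generate_cohort(sc, 1000, seed = 60 + s)
    q <- fit_qmodel(ch, covariate_subset("common"))
    ps <- fit_propensity(ch, covariate_subset("common"))
    tm <- tmle_ate(ch, q, ps)
    expect_true(tm$effects$converged)
    expect_lt(abs(mean(tm$ic_delta)), 1e-6)
    expect_true(all(tm$Q1_star > 0 & tm$Q1_star < 1))
    expect_true(all(tm$Q0_star > 0 & tm$Q0_star < 1))
  }
})

test_that("a second fluctuation step changes epsilon negligibly (one-step property)", {
  sc <- make_scenario("ATE", "alternative")
  ch <- generate_cohort(sc, 2000, seed = 64)
  q <- fit_qmodel(ch, covariate_subset("outcome"))
  ps <- fit_propensity(ch, covariate_subset("outcome"))
  tm <- tmle_ate(ch, q, ps)
  H <- ch$A / tm$g - (1 - ch$A) / (1 - tm$g)
  refit <- glm(ch$Y ~ H - 1, family = quasibinomial(),
               offset = qlogis(tm$QA_star), control = list(maxit = 100))
  expect_lt(abs(unname(coef(refit))), 1e-4)
})

test_that("with correct models TMLE agrees with g-computation at large n", {
  sc <- make_scenario("ATE", "alternative")
  ch <- generate_cohort(sc, 1e5, seed = 65)
  q <- fit_qmodel(ch, covariate_subset("outcome"))
  ps <- fit_propensity(ch, covariate_subset("treatment"))
  tm <- tmle_ate(ch, q, ps)
  gc <- gcomp_effects(q, ch, "ATE")
  expect_lt(abs(tm$effects$theta - gc$theta), 0.02)
  expect_lt(abs(tm$epsilon), 0.05)
})

test_that("TMLE is doubly robust for the ATE", {
  sc <- make_scenario("ATE", "alternative")
  truth <- exact_truth(sc)$theta
  ch <- generate_cohort(sc, 1e5, seed = 66)
  # misspecified Q (all confounders omitted), correct PS
  q_bad <- fit_qmodel(ch, integer(0))
  ps_ok <- fit_propensity(ch, covariate_subset("treatment"))
  tm <- tmle_ate(ch, q_bad, ps_ok)
  expect_lt(abs(tm$effects$theta - truth), 0.05)
  expect_gt(abs(gcomp_effects(q_bad, ch, "ATE")$theta - truth), 0.1)
})

test_that("TMLE is doubly robust for the ATT (both directions)", {
  sc <- make_scenario("ATT", "alternative")
  truth <- exact_truth(sc)$theta
  ch <- generate_cohort(sc, 1e5, seed = 67)
  # correct Q, misspecified PS (intercept-only)
  q_ok <- fit_qmodel(ch, covariate_subset("outcome"))
  ps_bad <- fit_propensity(ch, integer(0))
  tm1 <- tmle_att(ch, q_ok, ps_bad)
  expect_lt(abs(tm1$effects$theta - truth), 0.05)
  # misspecified Q, correct PS
  q_bad <- fit_qmodel(ch, integer(0))
  ps_ok <- fit_propensity(ch, covariate_subset("treatment"))
  tm2 <- tmle_att(ch, q_bad, ps_ok)
  expect_lt(abs(tm2$effects$theta - truth), 0.05)
  expect_gt(abs(gcomp_effects(q_bad, ch, "ATT")$theta - truth), 0.1)
})

test_that("without confounding ATT and ATE targeting agree with the truth", {
  sc <- make_scenario("ATT", "alternative")
  sc$gamma <- rep(0, 9)  # A independent of L (keep the ~20% treated rate)
  ch <- generate_cohort(sc, 1e5, seed = 68)
  q <- fit_qmodel(ch, covariate_subset("outcome"))
  ps <- fit_propensity(ch, covariate_subset("outcome"))
  t_att <- tmle_att(ch, q, ps)$effects$theta
  t_ate <- tmle_ate(ch, q, ps)$effects$theta
  truth <- exact_truth(make_scenario("ATE", "alternative"))  # same form, beta0 differs
  ex <- exact_truth(sc)  # ATT weights are flat when gamma = 0
  expect_lt(abs(t_att - ex$theta), 0.05)
  expect_lt(abs(t_ate - ex$theta), 0.05)
  expect_lt(abs(t_att - t_ate), 0.05)
})

test_that("influence-curve SE scales as 1/sqrt(n) and matches var_theta", {
  sc <- make_scenario("ATE", "alternative")
  se_at <- function(n, seed) {
    ch <- generate_cohort(sc, n, seed)
    q <- fit_qmodel(ch, covariate_subset("outcome"))
    ps <- fit_propensity(ch, covariate_subset("outcome"))
    tm <- tmle_ate(ch, q, ps)
    c(influence_curve_se(tm, "theta"), sqrt(tm$effects$var_theta),
      influence_curve_se(tm, "delta"))
  }
  s1 <- rowMeans(sapply(1:5, function(r) se_at(1000, 70 + r)))
  s4 <- rowMeans(sapply(1:5, function(r) se_at(4000, 80 + r)))
  expect_equal(s1[1], s1[2], tolerance = 1e-12)  # same quantity, two surfaces
  expect_lt(abs(s1[1] / s4[1] - 2), 0.3)
  expect_lt(abs(s1[3] / s4[3] - 2), 0.3)
})

test_that("non-converged inputs propagate as non-convergence markers", {
  sc <- make_scenario("ATE", "alternative")
  ch <- generate_cohort(sc, 500, seed = 90)
  q <- fit_qmodel(ch, covariate_subset("outcome"))
  ps <- fit_propensity(ch, covariate_subset("outcome"))
  q$converged <- FALSE
  expect_error(tmle_ate(ch, q, ps))
})
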