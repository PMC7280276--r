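# full_match works from a propensity object; these tests feed it prescribed
# propensities via fake_propensity() so the distances are fully controlled

fm_from_logits <- function(lt, lu, ...) {
  p <- plogis(c(lt, lu))
  A <- c(rep(1, length(lt)), rep(0, length(lu)))
  full_match(fake_propensity(p), A, ...)
}

test_that("two subjects form the single admissible stratum", {
  st <- fm_from_logits(0.3, -1.2)
  expect_equal(st$n_strata, 1L)
  expect_equal(st$strata$t, 1L)
  expect_equal(st$strata$u, 1L)
  expect_equal(st$total_distance, 1.5, tolerance = 1e-6)
})

test_that("flow solution matches the brute-force optimum on a worked instance", {
  # 2 treated at logit-PS {0, 1}; 3 untreated at {0.1, 0.9, 2.0}
  lt <- c(0, 1); lu <- c(0.1, 0.9, 2.0)
  D <- abs(outer(lt, lu, "-"))
  st <- fm_from_logits(lt, lu)
  expect_equal(st$total_distance, brute_full_match_cost(D), tolerance = 1e-5)
  # optimal: (t1,u1), (t2,u2), (t2,u3) with cost 0.1 + 0.1 + 1.0
  expect_equal(st$total_distance, 1.2, tolerance = 1e-5)
  expect_true(all(pmin(st$strata$t, st$strata$u) == 1L))
})

test_that("flow cost equals the brute-force minimum on random small instances", {
  set.seed(99)
  for (k in 1:25) {
    nT <- sample(1:4, 1); nU <- sample(1:4, 1)
    lt <- rnorm(nT); lu <- rnorm(nU)
    st <- fm_from_logits(lt, lu)
    expect_equal(st$total_distance,
                 brute_full_match_cost(abs(outer(lt, lu, "-"))),
                 tolerance = 1e-4,
                 label = sprintf("flow cost (instance %d, %dx%d)", k, nT, nU))
  }
})

test_that("stratification invariants hold and flow beats greedy on larger cohorts", {
  set.seed(123)
  sc <- make_scenario("ATE", "alternative")
  for (k in 1:5) {
    ch <- generate_cohort(sc, 200, seed = 1000 + k)
    ps <- fit_propensity(ch, covariate_subset("outcome"))
    st <- full_match(ps, ch$A)
    # partition: every subject in exactly one stratum, counts consistent
    expect_equal(length(st$stratum_of), ch$n)
    expect_true(all(st$stratum_of >= 1 & st$stratum_of <= st$n_strata))
    expect_equal(sum(st$strata$t), sum(ch$A))
    expect_equal(sum(st$strata$u), sum(1 - ch$A))
    expect_equal(unname(table(st$stratum_of)[as.character(st$strata$stratum)]),
                 st$strata$t + st$strata$u, ignore_attr = TRUE)
    # composition: >=1 of each arm and min(t, u) = 1 in every stratum
    expect_true(all(st$strata$t >= 1L & st$strata$u >= 1L))
    expect_true(all(pmin(st$strata$t, st$strata$u) == 1L))
    # optimality against the greedy nearest-neighbour comparator
    x <- qlogis(ps$p)
    D <- abs(outer(x[ch$A == 1], x[ch$A == 0], "-"))
    expect_lte(st$total_distance, greedy_full_match_cost(D) + 1e-9)
  }
})

test_that("ATE stratum weights follow the stratum-propensity form", {
  # one stratum with t=1, u=3 and one pair, P(A=1) = 0.5
  st <- fm_from_logits(c(0, 5), c(0.1, 0.2, 0.3, 5.1))
  expect_equal(st$n_strata, 2L)
  A <- c(1, 1, 0, 0, 0, 0)
  w <- fm_weights_ate(st, A, marginal_treated = 0.5)
  big <- st$stratum_of[1]  # stratum of the first treated subject (t=1, u=3)
  expect_equal(unname(w$w[1]), 0.5 * 4 / 1)
  expect_equal(unname(w$w[which(A == 0 & st$stratum_of == big)]),
               rep(0.5 * 4 / 3, 3))
  # balanced pair: both weights 1
  pair <- st$stratum_of[2]
  expect_equal(unname(w$w[st$stratum_of == pair]), c(1, 1))
  # printed variant swaps denominators
  wp <- fm_weights_ate(st, A, marginal_treated = 0.5, formula = "printed")
  expect_equal(unname(wp$w[1]), 0.5 * 4 / 3)
})

test_that("ATT weights rescale the untreated mass exactly", {
  # single stratum t=1, u=2: raw untreated weights 0.5 rescale to 1
  st <- fm_from_logits(0, c(0.1, -0.1))
  A <- c(1, 0, 0)
  w <- fm_weights_att(st, A)
  expect_equal(w$w, c(1, 1, 1))
  expect_true(w$rescaled)

  # random stratifications: treated weight 1, untreated mass conserved exactly
  set.seed(7)
  sc <- make_scenario("ATT", "alternative")
  for (k in 1:3) {
    ch <- generate_cohort(sc, 150, seed = 2000 + k)
    ps <- fit_propensity(ch, covariate_subset("common"))
    st <- full_match(ps, ch$A)
    w <- fm_weights_att(st, ch$A)
    expect_equal(w$w[ch$A == 1], rep(1, sum(ch$A)))
    expect_equal(sum(w$w[ch$A == 0]), sum(1 - ch$A), tolerance = 1e-12)
  }
})

test_that("full-matching ATE weights balance covariates under the true model", {
  sc <- make_scenario("ATE", "alternative")
  ch <- generate_cohort(sc, 4000, seed = 31)
  ps <- fit_propensity(ch, covariate_subset("treatment"))
  st <- full_match(ps, ch$A)
  w <- fm_weights_ate(st, ch$A, ps$marginal_treated)
  bal <- standardized_differences(ch, covariate_subset("treatment"), w)
  expect_lt(max(abs(bal$std_diff_pct)), 3)
})

test_that("degenerate single-arm input is rejected", {
  expect_error(full_match(fake_propensity(rep(0.5, 3)), A = c(1, 1, 1)),
               "at least one treated and one untreated")
})
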