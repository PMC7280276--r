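# Independent oracles used across the suite.

# Exact population marginal effects of a scenario by enumeration of the 512
# covariate patterns (covariates are iid Bernoulli(0.5), so every pattern has
# probability 2^-9). For the ATT the pattern distribution is weighted by the
# true propensity P(A=1|L). Shares no code with theoretical_effects().
exact_truth <- function(scenario) {
  pats <- as.matrix(expand.grid(rep(list(0:1), 9)))
  blp <- scenario$beta0 + drop(pats %*% scenario$beta)
  w <- if (scenario$estimand == "ATT") {
    plogis(scenario$gamma0 + drop(pats %*% scenario$gamma))
  } else rep(1, nrow(pats))
  w <- w / sum(w)
  pi1 <- sum(w * plogis(blp + scenario$beta_treat))
  pi0 <- sum(w * plogis(blp))
  list(pi1 = pi1, pi0 = pi0, delta = pi1 - pi0,
       theta = qlogis(pi1) - qlogis(pi0))
}

# Brute-force optimal full matching: enumerate every subset of the complete
# bipartite edge set, keep those that cover all subjects with star-shaped
# components (min(t,u) = 1 per stratum), return the minimum total distance.
# Feasible for nT * nU <= 16.
brute_full_match_cost <- function(D) {
  nT <- nrow(D); nU <- ncol(D)
  ne <- nT * nU
  edges <- cbind(rep(seq_len(nT), nU), rep(seq_len(nU), each = nT))
  best <- Inf
  for (mask in seq_len(2^ne) - 1L) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(ne) - 1L)) != 0L)
    if (!length(sel)) next
    ei <- edges[sel, 1L]; ej <- edges[sel, 2L]
    dt <- tabulate(ei, nT); du <- tabulate(ej, nU)
    if (any(dt == 0L) || any(du == 0L)) next
    # star shape: no edge may join two vertices that both have other edges
    if (any(dt[ei] > 1L & du[ej] > 1L)) next
    cost <- sum(D[cbind(ei, ej)])
    if (cost < best) best <- cost
  }
  best
}

# Greedy nearest-neighbour full stratification comparator: pair each treated
# with its nearest unused untreated (ties to the first), then attach leftover
# subjects to their nearest opposite-arm neighbour.
greedy_full_match_cost <- function(D) {
  nT <- nrow(D); nU <- ncol(D)
  used_u <- rep(FALSE, nU)
  cost <- 0
  ord <- order(apply(D, 1L, min))
  paired_u <- integer(nT)
  for (i in ord) {
    if (!any(!used_u)) { paired_u[i] <- NA_integer_; next }
    j <- which(!used_u)[which.min(D[i, !used_u])]
    used_u[j] <- TRUE
    paired_u[i] <- j
    cost <- cost + D[i, j]
  }
  for (i in which(is.na(paired_u))) cost <- cost + min(D[i, ])
  for (j in which(!used_u)) cost <- cost + min(D[, j])
  cost
}

# saturated 2x2 log odds ratio from counts (a = Y1A1, b = Y0A1, c = Y1A0,
# d = Y0A0)
logor_2x2 <- function(a, b, c, d) log((a * d) / (b * c))

# build a cohort from explicit 2x2 cell counts with one constant covariate
# column (the covariate is never used by the callers)
cohort_from_counts <- function(y1a1, y0a1, y1a0, y0a0) {
  Y <- c(rep(1, y1a1), rep(0, y0a1), rep(1, y1a0), rep(0, y0a0))
  A <- c(rep(1, y1a1 + y0a1), rep(0, y1a0 + y0a0))
  n <- length(Y)
  causalsets::cohort(Y, A, matrix(rep(c(0, 1), length.out = n), n, 1))
}

# propensity-like object with prescribed probabilities (for weight-formula
# and matching unit tests)
fake_propensity <- function(p, marginal_treated = 0.5) {
  structure(list(p = p, marginal_treated = marginal_treated,
                 coef = NULL, converged = TRUE),
            class = "cs_propensity")
}
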