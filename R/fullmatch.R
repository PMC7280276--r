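#' Optimal full matching on the propensity score
#'
#' Partitions the cohort into strata, each containing one treated subject and
#' one or more untreated subjects or vice versa (`min(t, u) = 1`), minimizing
#' the total within-stratum treated--untreated distance over all admissible
#' full stratifications. The distance between two subjects is the absolute
#' difference of their logit-propensity scores (`distance = "logit"`, the
#' standard choice) or of the raw propensities (`distance = "ps"`).
#'
#' Because an unrestricted full stratification is exactly a union of
#' treated--untreated stars covering every subject, the optimum is the
#' minimum-weight edge cover of the bipartite treated x untreated graph. It
#' is found by the classical reduction: subtract each subject's cheapest
#' incident distance, solve a maximum-weight bipartite matching on the
#' transformed (profitable) edges with a min-cost-flow routine, then cover
#' every unmatched subject with its nearest opposite-arm neighbour. Distances
#' are scaled by `1e6` and rounded to integers so the flow arithmetic is
#' exact; the achieved total distance is reported on the original scale.
#'
#' @param fit a converged `cs_propensity`.
#' @param A treatment vector.
#' @param distance `"logit"` (default) or `"ps"`.
#' @return An object of class `cs_fullmatch`: list with `stratum_of`
#'   (length-n integer stratum labels), `strata` (data frame with `stratum`,
#'   `t`, `u`), `total_distance`, `n_strata`.
#' @export
full_match <- function(fit, A, distance = c("logit", "ps")) {
  stopifnot(inherits(fit, "cs_propensity"), fit$converged)
  distance <- match.arg(distance)
  n <- length(A)
  trt <- which(A == 1)
  ctl <- which(A == 0)
  nT <- length(trt)
  nU <- length(ctl)
  if (nT < 1L || nU < 1L)
    stop("full matching requires at least one treated and one untreated subject")
  x <- if (distance == "logit") qlogis(fit$p) else fit$p
  # integer-scaled pairwise distances (exact flow arithmetic)
  D <- round(abs(outer(x[trt], x[ctl], "-")) * 1e6)
  eps_t <- apply(D, 1L, min)
  eps_u <- apply(D, 2L, min)
  W <- outer(eps_t, eps_u, "+") - D
  keep <- which(W >= 0, arr.ind = TRUE)
  m <- if (nrow(keep)) {
    .mwb_matching(nT, nU, keep[, 1L] - 1L, keep[, 2L] - 1L, W[keep])
  } else rep(-1L, nT)

  # edge list of the cover: matched pairs + cheapest edge for uncovered subjects
  ei <- integer(0); ej <- integer(0)
  matched_u <- m[m >= 0L] + 1L
  matched_t <- which(m >= 0L)
  ei <- c(ei, matched_t); ej <- c(ej, matched_u)
  for (i in setdiff(seq_len(nT), matched_t)) {
    ei <- c(ei, i); ej <- c(ej, which.min(D[i, ]))
  }
  for (j in setdiff(seq_len(nU), matched_u)) {
    ei <- c(ei, which.min(D[, j])); ej <- c(ej, j)
  }
  # degenerate ties can leave an edge whose two endpoints both have other
  # edges; dropping it never increases the cost and restores the star shape
  repeat {
    dt <- tabulate(ei, nT); du <- tabulate(ej, nU)
    bad <- which(dt[ei] > 1L & du[ej] > 1L)
    if (!length(bad)) break
    drop <- bad[which.max(D[cbind(ei[bad], ej[bad])])]
    ei <- ei[-drop]; ej <- ej[-drop]
  }

  # strata = connected components (stars) of the cover
  parent <- seq_len(nT + nU)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  for (k in seq_along(ei)) {
    ra <- find(ei[k]); rb <- find(nT + ej[k])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(nT + nU), find, integer(1))
  lab <- match(roots, unique(roots))
  stratum_of <- integer(n)
  stratum_of[trt] <- lab[seq_len(nT)]
  stratum_of[ctl] <- lab[nT + seq_len(nU)]
  tcnt <- tabulate(lab[seq_len(nT)], max(lab))
  ucnt <- tabulate(lab[nT + seq_len(nU)], max(lab))
  structure(list(
    stratum_of = stratum_of,
    strata = data.frame(stratum = seq_along(tcnt), t = tcnt, u = ucnt),
    total_distance = sum(D[cbind(ei, ej)]) / 1e6,
    n_strata = length(tcnt)
  ), class = "cs_fullmatch")
}

#' @export
print.cs_fullmatch <- function(x, ...) {
  cat("Full matching:", x$n_strata, "strata, total distance",
      signif(x$total_distance, 5), "\n")
  invisible(x)
}

#' Full-matching weights for the ATE
#'
#' Stratum-based weights using the stratum propensity \eqn{t/(t+u)}: a
#' treated subject in a stratum with `t` treated and `u` untreated receives
#' \eqn{P(A=1)(t+u)/t} and an untreated one \eqn{(1-P(A=1))(t+u)/u}, the
#' full-matching analogue of stabilized inverse-probability weights
#' (`formula = "stratum"`, the default). `formula = "printed"` swaps the
#' denominators (treated \eqn{(t+u)/u}, untreated \eqn{(t+u)/t}) and is kept
#' selectable for audit; only the stratum form is consistent with the
#' stratum-propensity logic that also underlies the ATT weight `t/u`, and
#' only it is unbiased for the ATE in the simulations.
#'
#' @param strat a `cs_fullmatch`.
#' @param A treatment vector.
#' @param marginal_treated sample proportion treated, used for
#'   stabilization.
#' @param formula `"stratum"` (default) or `"printed"`.
#' @return A `cs_weights` object with `target = "ATE"`.
#' @export
fm_weights_ate <- function(strat, A, marginal_treated,
                           formula = c("stratum", "printed")) {
  stopifnot(inherits(strat, "cs_fullmatch"))
  formula <- match.arg(formula)
  s <- strat$stratum_of
  t <- strat$strata$t[s]
  u <- strat$strata$u[s]
  pA <- marginal_treated
  w <- if (formula == "stratum") {
    A * pA * (t + u) / t + (1 - A) * (1 - pA) * (t + u) / u
  } else {
    A * pA * (t + u) / u + (1 - A) * (1 - pA) * (t + u) / t
  }
  structure(list(w = w, target = "ATE", rescaled = FALSE), class = "cs_weights")
}

#' Full-matching weights for the ATT
#'
#' Treated subjects receive weight 1; an untreated subject receives the
#' treated-to-untreated ratio `t/u` of its own stratum. The untreated
#' weights are then rescaled so that their sum equals the number of untreated
#' subjects exactly.
#'
#' @param strat a `cs_fullmatch`.
#' @param A treatment vector.
#' @return A `cs_weights` object with `target = "ATT"` and `rescaled = TRUE`.
#' @export
fm_weights_att <- function(strat, A) {
  stopifnot(inherits(strat, "cs_fullmatch"))
  s <- strat$stratum_of
  t <- strat$strata$t[s]
  u <- strat$strata$u[s]
  w <- A + (1 - A) * t / u
  untreated <- A == 0
  w[untreated] <- w[untreated] * sum(untreated) / sum(w[untreated])
  structure(list(w = w, target = "ATT", rescaled = TRUE), class = "cs_weights")
}
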