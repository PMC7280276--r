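#' Read and write cohorts as CSV
#'
#' The on-disk format is a comma-separated file with header
#' `Y,A,L1,...,LK`, one row per subject, all values 0/1.
#'
#' @param path file path.
#' @return `read_cohort` returns a `cs_cohort`; `write_cohort` returns `path`
#'   invisibly.
#' @export
read_cohort <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  if (nrow(d) == 0L) stop("empty cohort file: ", path)
  need <- c("Y", "A")
  if (!all(need %in% names(d)))
    stop("cohort file must have columns Y and A")
  lcols <- setdiff(names(d), need)
  if (length(lcols) == 0L) stop("cohort file has no covariate columns")
  for (cn in c(need, lcols)) {
    bad <- which(!(d[[cn]] %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("non-binary value in column '%s' at row %d", cn, bad[1]))
  }
  cohort(d$Y, d$A, as.matrix(d[lcols]))
}

#' @param x a `cs_cohort`.
#' @rdname read_cohort
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cs_cohort"))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write scenarios as YAML
#'
#' Flat key-value serialization of a [make_scenario()] object; the round trip
#' is lossless.
#'
#' @param path file path.
#' @return `read_scenario` returns a `cs_scenario`; `write_scenario` returns
#'   `path` invisibly.
#' @export
read_scenario <- function(path) {
  s <- yaml::read_yaml(path)
  sc <- structure(list(
    estimand = s$estimand, hypothesis = s$hypothesis,
    unmeasured = isTRUE(s$unmeasured),
    gamma0 = as.numeric(s$gamma0), gamma = as.numeric(s$gamma),
    beta0 = as.numeric(s$beta0), beta_treat = as.numeric(s$beta_treat),
    beta = as.numeric(s$beta)
  ), class = "cs_scenario")
  stopifnot(length(sc$gamma) == 9L, length(sc$beta) == 9L)
  sc
}

#' @param x a `cs_scenario`.
#' @rdname read_scenario
#' @export
write_scenario <- function(x, path) {
  stopifnot(inherits(x, "cs_scenario"))
  yaml::write_yaml(unclass(x), path, precision = 15L)
  invisible(path)
}

#' Spawn deterministic child seeds
#'
#' Derives `count` distinct child seeds from one master seed, so that each
#' simulation replicate (and each of its internal randomizations) runs on its
#' own stream, independently of scheduling order.
#'
#' @param master_seed integer master seed.
#' @param count number of child seeds (>= 1).
#' @return Integer vector of `count` distinct seeds.
#' @export
spawn_seeds <- function(master_seed, count) {
  stopifnot(count >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, count)
}
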