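#' Piecewise-linear V-shaped log relative hazard
#'
#' Evaluates the true log relative hazard used by the simulator:
#' `s(x) = k1 * (x - a)` for `x <= a` and `k2 * (x - a)` for `x > a`.
#' With `k1 < 0 < k2` this is a continuous convex V with its minimum
#' (`s(a) = 0`) at the turning point `a`.
#'
#' @param x Numeric vector of predictor values.
#' @param k1 Slope of the left arm (must be negative).
#' @param k2 Slope of the right arm (must be positive).
#' @param a Turning point on the predictor axis.
#' @return Numeric vector of log relative hazard values.
#' @examples
#' piecewise_log_hazard(c(-1, 0, 1), k1 = -2, k2 = 2, a = 0)
#' @export
piecewise_log_hazard <- function(x, k1, k2, a = 0) {
  stopifnot(is.numeric(x), length(k1) == 1, length(k2) == 1, length(a) == 1)
  if (!all(is.finite(x))) stop("'x' must be finite")
  if (!(k1 < 0 && k2 > 0)) stop("need k1 < 0 < k2 for a V-shaped log hazard")
  ifelse(x <= a, k1 * (x - a), k2 * (x - a))
}

#' Peak asymmetry factor of a V-shaped log hazard
#'
#' Ratio `|k1| / k2` of the arm slopes; 1 means a symmetric V, values far
#' from 1 mean one arm rises much faster than the other.
#'
#' @inheritParams piecewise_log_hazard
#' @return A single number, `abs(k1) / k2`.
#' @export
peak_asymmetry <- function(k1, k2) {
  if (k2 == 0) stop("k2 must be non-zero")
  if (!(k1 < 0 && k2 > 0)) stop("need k1 < 0 < k2")
  abs(k1) / k2
}

#' Draw Weibull survival times by inverse transform
#'
#' Event times follow `T0 = (-log(U) / (lambda_scale * exp(s)))^(1/v)` with
#' `U ~ Uniform(0, 1)`, i.e. a Weibull with shape `v` whose hazard is scaled
#' multiplicatively by `exp(s)`.
#'
#' @param s_values Numeric vector of log relative hazard values, one per subject.
#' @param lambda_scale Weibull scale parameter (> 0).
#' @param v Weibull shape parameter (> 0).
#' @return Vector of positive event times, same length as `s_values`.
#' @export
draw_survival_times <- function(s_values, lambda_scale = 1, v = 1) {
  stopifnot(all(is.finite(s_values)), lambda_scale > 0, v > 0)
  u <- stats::runif(length(s_values))
  (-log(u) / (lambda_scale * exp(s_values)))^(1 / v)
}

#' Define a simulation scenario
#'
#' Bundles the parameters of one Monte-Carlo scenario: the V-shaped log
#' hazard (`k1`, `k2`, `a`), the Weibull baseline (`v`, `lambda_scale`),
#' the target censoring proportion `Pc`, the per-dataset sample size `n`,
#' the number of replicate datasets `reps` and the scenario seed. When
#' `Pc > 0` the upper bound `r` of the Uniform(0, r) censoring distribution
#' is calibrated at construction time (see [calibrate_censoring_bound()]).
#'
#' @inheritParams piecewise_log_hazard
#' @param v Weibull shape (1/2, 1 and 5 give decreasing, constant and
#'   increasing baseline hazard).
#' @param lambda_scale Weibull scale (default 1).
#' @param Pc Target censoring proportion in `[0, 1)`.
#' @param n Subjects per simulated dataset.
#' @param reps Number of replicate datasets.
#' @param seed Scenario seed; each replicate draws from its own substream
#'   derived deterministically from `(seed, rep_index)`.
#' @return An object of class `sim_scenario`.
#' @examples
#' sc <- sim_scenario(k1 = -2, k2 = 2, a = 0, Pc = 0, n = 200, reps = 5, seed = 1)
#' d <- generate_dataset(sc, 1)
#' head(d)
#' @export
sim_scenario <- function(k1, k2, a = 0, v = 1, lambda_scale = 1,
                         Pc = 0, n = 500, reps = 100, seed = 1) {
  if (!(k1 < 0 && k2 > 0)) stop("need k1 < 0 < k2 (U-shape in log hazard)")
  stopifnot(v > 0, lambda_scale > 0, n >= 2, Pc >= 0, Pc < 1,
            reps >= 1, is.finite(seed))
  sc <- structure(
    list(k1 = k1, k2 = k2, a = a, v = v, lambda_scale = lambda_scale,
         Pc = Pc, n = as.integer(n), reps = as.integer(reps),
         seed = as.integer(seed), r = Inf),
    class = "sim_scenario")
  if (Pc > 0) sc$r <- calibrate_censoring_bound(sc)
  sc
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Simulation scenario (V-shaped log relative hazard)\n")
  cat(sprintf("  s(x): k1 = %.4g, k2 = %.4g, turning point a = %.4g (asymmetry %.3g)\n",
              x$k1, x$k2, x$a, peak_asymmetry(x$k1, x$k2)))
  cat(sprintf("  Weibull baseline: shape v = %.4g, scale = %.4g\n", x$v, x$lambda_scale))
  cat(sprintf("  censoring: Pc = %.0f%% (uniform bound r = %.4g)\n", 100 * x$Pc, x$r))
  cat(sprintf("  n = %d per dataset, %d replicates, seed %d\n", x$n, x$reps, x$seed))
  invisible(x)
}

#' Calibrate the uniform censoring bound to a target censoring proportion
#'
#' Censoring times are Uniform(0, r). Given a scenario, the expected
#' censoring fraction is `P(T0 > C) = E[min(T0, r)] / r`, estimated on a
#' large Monte-Carlo sample of event times and inverted for `r` by
#' bisection. The calibration sample uses a fixed RNG substream so the
#' bound is reproducible; the global RNG state is restored on exit.
#'
#' @param scenario A [sim_scenario()] with `Pc > 0`.
#' @param n_calib Size of the calibration sample (default 2e5).
#' @param tol Tolerance on the achieved censoring proportion (default 0.005).
#' @return The bound `r` (> 0), or `Inf` when `scenario$Pc == 0`.
#' @export
calibrate_censoring_bound <- function(scenario, n_calib = 2e5, tol = 0.005) {
  if (scenario$Pc == 0) return(Inf)
  stopifnot(scenario$Pc > 0, scenario$Pc < 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(scenario$seed %% 1000000L + 777L)
  x <- stats::rnorm(n_calib)
  s <- piecewise_log_hazard(x, scenario$k1, scenario$k2, scenario$a)
  t0 <- draw_survival_times(s, scenario$lambda_scale, scenario$v)
  cens_frac <- function(r) mean(pmin(t0, r)) / r
  lo <- 1e-8
  hi <- 1
  while (cens_frac(hi) > scenario$Pc) {
    hi <- hi * 2
    if (hi > 1e12) stop("failed to bracket the censoring bound")
  }
  # cens_frac is decreasing in r: censored fraction shrinks as C grows
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (cens_frac(mid) > scenario$Pc) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-12 * max(1, hi)) break
  }
  r <- (lo + hi) / 2
  if (abs(cens_frac(r) - scenario$Pc) > tol)
    stop("censoring calibration did not reach the target proportion")
  r
}

#' Generate one replicate dataset from a scenario
#'
#' Draws `n` standard-normal predictor values, Weibull event times with the
#' scenario's V-shaped log relative hazard, and (when `Pc > 0`)
#' Uniform(0, r) censoring times. The observed time is `min(T0, C)` and
#' `status` is 1 for an event, 0 for censoring. Deterministic given
#' `(seed, rep_index)`.
#'
#' @param scenario A [sim_scenario()].
#' @param rep_index Replicate number in `1:reps`.
#' @return A `data.frame` with columns `time`, `status`, `x`.
#' @export
generate_dataset <- function(scenario, rep_index = 1) {
  stopifnot(inherits(scenario, "sim_scenario"),
            rep_index >= 1, rep_index <= scenario$reps)
  # per-replicate substream: distinct scenario seeds give disjoint streams
  set.seed(as.integer((scenario$seed * 10007 + rep_index) %% 2147483647))
  x <- stats::rnorm(scenario$n)
  s <- piecewise_log_hazard(x, scenario$k1, scenario$k2, scenario$a)
  t0 <- draw_survival_times(s, scenario$lambda_scale, scenario$v)
  if (is.finite(scenario$r)) {
    cens <- stats::runif(scenario$n, 0, scenario$r)
    time <- pmin(t0, cens)
    status <- as.integer(t0 <= cens)
  } else {
    time <- t0
    status <- rep(1L, scenario$n)
  }
  validate_survival_data(data.frame(time = time, status = status, x = x))
}

# Shared validation of the (time, status, x [, covariates]) table.
validate_survival_data <- function(data) {
  need <- c("time", "status", "x")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(data[need])) stop("missing values in time/status/x")
  if (any(data$time < 0)) stop("negative times")
  if (!all(data$status %in% c(0, 1))) stop("status must be 0 (censored) or 1 (event)")
  lens <- vapply(data, length, 0L)
  if (length(unique(lens)) != 1) stop("ragged columns")
  data$status <- as.integer(data$status)
  data
}

# Names of adjustment covariate columns, if any.
covariate_names <- function(data) setdiff(names(data), c("time", "status", "x"))
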