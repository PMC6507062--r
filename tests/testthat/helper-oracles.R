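# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own computational paths.

# Textbook de Boor recursion for a single B-spline basis function.
deboor_basis <- function(knots, x, i, k) {
  if (k == 1) return(as.numeric(knots[i] <= x & x < knots[i + 1]))
  w1 <- if (knots[i + k - 1] > knots[i])
    (x - knots[i]) / (knots[i + k - 1] - knots[i]) else 0
  w2 <- if (knots[i + k] > knots[i + 1])
    (knots[i + k] - x) / (knots[i + k] - knots[i + 1]) else 0
  w1 * deboor_basis(knots, x, i, k - 1) + w2 * deboor_basis(knots, x, i + 1, k - 1)
}

# O(n^2) Harrell c-index (assumes no tied event times).
brute_cindex <- function(time, status, risk) {
  conc <- 0; usable <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] < time[j] && status[i] == 1) {
      usable <- usable + 1
      conc <- conc + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    } else if (time[j] < time[i] && status[j] == 1) {
      usable <- usable + 1
      conc <- conc + (risk[j] > risk[i]) + 0.5 * (risk[j] == risk[i])
    }
  }
  conc / usable
}

# Published Gonen-Heller double summation.
brute_cpe <- function(lp) {
  n <- length(lp)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dij <- lp[i] - lp[j]
    s <- s + (dij < 0) / (1 + exp(dij)) + (dij > 0) / (1 + exp(-dij)) +
      0.5 * (dij == 0)
  }
  2 * s / (n * (n - 1))
}

# Per-split maximally selected log-rank statistic computed independently:
# scores from the Nelson-Aalen estimate of survfit, explicit per-candidate loop.
brute_maxsel <- function(time, status, x, candidates) {
  sf <- survival::survfit(survival::Surv(time, status) ~ 1)
  chaz <- stats::stepfun(sf$time, c(0, cumsum(sf$n.event / sf$n.risk)))
  a <- status - chaz(time)
  n <- length(time)
  z <- vapply(candidates, function(cc) {
    g <- x <= cc
    n1 <- sum(g)
    sum(a[g]) / sqrt(n1 * (n - n1) / (n * (n - 1)) * sum(a^2))
  }, 0)
  z
}

# Small V-truth dataset without going through sim_scenario.
make_v_data <- function(n, k1 = -2, k2 = 2, a = 0, v = 1, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  s <- piecewise_log_hazard(x, k1, k2, a)
  data.frame(time = (-log(runif(n)) / exp(s))^(1 / v), status = 1L, x = x)
}

# Step-hazard dataset: hazard jumps by factor exp(b) at x > cut.
make_step_data <- function(n, cut = 0.3, b = 1.5, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  s <- ifelse(x > cut, b, 0)
  data.frame(time = -log(runif(n)) / exp(s), status = 1L, x = x)
}
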