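#' Harrell's concordance index
#'
#' Probability that, of two randomly chosen comparable subjects, the one
#' with the shorter survival time has the higher predicted risk. Pairs are
#' comparable when the smaller observed time is an event; ties in risk
#' count 1/2. Computed via [survival::concordance()].
#'
#' @param time,status Observed times and event indicators (1 = event).
#' @param risk Predicted risk scores (higher = worse prognosis).
#' @return Concordance in `[0, 1]`.
#' @export
harrell_cindex <- function(time, status, risk) {
  stopifnot(length(time) == length(status), length(time) == length(risk))
  fit <- survival::concordance(survival::Surv(time, status) ~ risk, reverse = TRUE)
  usable <- sum(fit$count[c("concordant", "discordant", "tied.x")])
  if (usable == 0) stop("no usable (comparable) pairs")
  unname(fit$concordance)
}

#' Gonen-Heller concordance probability estimate (CPE)
#'
#' Model-based concordance of a Cox model, computed from the pairwise
#' differences of linear predictors through the proportional-hazards
#' kernel: each pair contributes `1 / (1 + exp(-|lp_i - lp_j|))`, the
#' model-implied probability that the higher-risk subject fails first.
#' Unlike the c-index it does not depend on the censoring distribution.
#'
#' @param lp Cox linear predictors.
#' @return CPE in `[0.5, 1)`; `0.5` by convention when all `lp` are equal.
#' @export
gonen_heller_cpe <- function(lp) {
  n <- length(lp)
  if (n < 2) stop("need at least 2 subjects")
  if (all(lp == lp[1])) return(0.5)
  d <- abs(outer(lp, lp, "-"))
  k <- 1 / (1 + exp(-d))
  (sum(k) - n * 0.5) / (n * (n - 1))   # off-diagonal mean; diagonal contributes 0.5 each
}

# Step-function evaluation of a Kaplan-Meier curve; left = TRUE gives the
# left-continuous limit G(t-) used in IPCW weights.
km_step <- function(sf, t, left = FALSE) {
  if (!length(sf$time)) return(rep(1, length(t)))
  f <- stats::stepfun(sf$time, c(1, sf$surv), right = left)
  f(t)
}

#' Integrated Brier score (IPCW, Graf weights)
#'
#' Brier score `BS(t)` of predicted survival probabilities against observed
#' status, weighted by the inverse Kaplan-Meier estimate of the censoring
#' distribution (estimated on the training data), integrated over a time
#' grid by the trapezoid rule and normalized by the grid span.
#'
#' @param train Training data frame (`time`, `status`) supplying the
#'   censoring distribution and, for the null model, the survival curve.
#' @param test Test data frame whose subjects are scored.
#' @param model A fitted [survival::coxph()] model, or `NULL` for the null
#'   (Kaplan-Meier) model with no covariates.
#' @param newdata Covariate data frame for `model` predictions, one row per
#'   test subject (defaults to `test`).
#' @param times Evaluation grid; default 50 points up to the 95th
#'   percentile of observed test times. Times where the censoring curve
#'   reaches zero are dropped with a warning.
#' @param surv_matrix Optional matrix of predicted survival probabilities
#'   (test subjects by `times`), overriding `model`; used for externally
#'   supplied forecasts.
#' @return The integrated Brier score, a number in `[0, 1]`.
#' @export
integrated_brier_score <- function(train, test = train, model = NULL,
                                   newdata = test, times = NULL,
                                   surv_matrix = NULL) {
  stopifnot(is.data.frame(train), is.data.frame(test))
  if (is.null(times))
    times <- seq(0, stats::quantile(test$time, 0.95, names = FALSE),
                 length.out = 51)[-1]
  times <- sort(unique(times))
  cens_km <- survival::survfit(survival::Surv(time, 1 - status) ~ 1, data = train)
  g_at <- km_step(cens_km, times)
  keep <- g_at > 0
  if (any(!keep)) {
    warning("censoring survival reaches 0 inside the grid; truncating")
    times <- times[keep]
    g_at <- g_at[keep]
  }
  if (length(times) < 2) stop("fewer than 2 usable grid times")

  if (!is.null(surv_matrix)) {
    stopifnot(nrow(surv_matrix) == nrow(test))
    smat <- surv_matrix[, keep, drop = FALSE]
  } else if (is.null(model)) {
    sf <- survival::survfit(survival::Surv(time, status) ~ 1, data = train)
    smat <- matrix(km_step(sf, times), nrow(test), length(times), byrow = TRUE)
  } else {
    sf <- survival::survfit(model, newdata = newdata)
    ss <- summary(sf, times = times, extend = TRUE)$surv
    smat <- t(matrix(ss, ncol = nrow(test)))       # subjects x times
  }
  g_tminus <- km_step(cens_km, test$time, left = TRUE)

  bs <- vapply(seq_along(times), function(j) {
    t <- times[j]
    s <- smat[, j]
    died <- test$time <= t & test$status == 1
    alive <- test$time > t
    w_died <- ifelse(died, 1 / pmax(g_tminus, 1e-12), 0)
    contrib <- w_died * (0 - s)^2 + ifelse(alive, (1 - s)^2 / g_at[j], 0)
    mean(contrib)
  }, 0)
  span <- diff(range(times))
  sum(diff(times) * (bs[-1] + bs[-length(bs)]) / 2) / span
}

#' Kent-O'Quigley explained variation for a Cox model
#'
#' The proportion of explained variation on the linear-predictor scale,
#' `var(lp) / (var(lp) + pi^2 / 6)`, with `pi^2/6` the variance of the
#' extreme-value error implicit in the proportional-hazards model.
#'
#' @param lp Cox linear predictors.
#' @return A number in `[0, 1)`; 0 for a degenerate predictor.
#' @export
r2_pm <- function(lp) {
  if (length(lp) < 2) return(0)
  v <- stats::var(lp)
  if (!is.finite(v) || v == 0) return(0)
  v / (v + pi^2 / 6)
}

#' Royston-Sauerbrei R-squared based on the D statistic
#'
#' The prognostic index is rank-transformed to scaled normal scores
#' (Blom positions, scaled by `kappa = sqrt(8/pi)`), a Cox model is fitted
#' on the scores, and its coefficient `D` yields
#' `R2_D = (D^2/kappa^2) / (D^2/kappa^2 + pi^2/6)`. Invariant to monotone
#' increasing affine transformations of `lp`.
#'
#' @param time,status Observed times and event indicators.
#' @param lp Prognostic index (e.g. Cox linear predictors).
#' @return A number in `[0, 1)`; 0 for a degenerate ordering.
#' @export
r2_d <- function(time, status, lp) {
  n <- length(lp)
  stopifnot(length(time) == n, length(status) == n)
  if (n < 10) stop("need at least 10 subjects")
  kappa <- sqrt(8 / pi)
  rk <- rank(lp, ties.method = "average")
  z <- stats::qnorm((rk - 3 / 8) / (n + 1 / 4)) / kappa
  if (stats::sd(z) == 0) return(0)
  fit <- survival::coxph(survival::Surv(time, status) ~ z, ties = "breslow")
  d <- unname(stats::coef(fit))
  if (!is.finite(d)) return(0)
  (d^2 / kappa^2) / (d^2 / kappa^2 + pi^2 / 6)
}

# Assign discretized groups to new predictor values under a fitted rule.
assign_groups <- function(result, x) {
  switch(result$rule,
         three = cut_three(x, result$cuts[1], result$cuts[2]),
         lt = factor(ifelse(x < result$cuts[1], "low", "high"),
                     levels = c("low", "high")),
         le = factor(ifelse(x <= result$cuts[1], "low", "high"),
                     levels = c("low", "high")),
         stop("unknown grouping rule"))
}

make_folds <- function(status, n_folds) {
  fold <- integer(length(status))
  for (s in unique(status)) {
    idx <- which(status == s)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Cross-validated predictive performance of a discretization method
#'
#' Repeated k-fold cross-validation, stratified by event status: cut-points
#' and the categorical Cox model are estimated on the training folds only,
#' and the five performance measures (c-index, CPE, IBS, R2_PM, R2_D) are
#' evaluated on the held-out fold. The default is the two-fold scheme.
#' Rows are internally sorted by `(time, status, x)` before fold assignment
#' so the report does not depend on row order.
#'
#' @param data Data frame with `time`, `status`, `x` and optional covariates.
#' @param method One of `"median"`, `"q1q3"`, `"minp"`, `"oehr"`, or a
#'   function `train -> cutpoint_result`.
#' @param n_folds Number of folds (>= 2; default 2).
#' @param n_repeats Number of repeated fold draws (default 1).
#' @param seed Seed for the fold draws.
#' @param measures Subset of `c("cindex", "cpe", "ibs", "r2_pm", "r2_d")`.
#' @param min_group_frac Passed to the OEHR search.
#' @param max_retries Redraws allowed when a fold lacks events.
#' @return An object of class `performance_report` with per-measure `mean`
#'   and `se` (over all fold evaluations) and the raw fold-level values.
#' @export
cv_performance <- function(data, method = "oehr", n_folds = 2, n_repeats = 1,
                           seed = 1,
                           measures = c("cindex", "cpe", "ibs", "r2_pm", "r2_d"),
                           min_group_frac = 0.05, max_retries = 10) {
  data <- validate_survival_data(data)
  stopifnot(n_folds >= 2, n_repeats >= 1)
  measures <- match.arg(measures, several.ok = TRUE)
  data <- data[order(data$time, data$status, data$x), , drop = FALSE]
  estimator <- if (is.function(method)) method else switch(
    match.arg(method, c("median", "q1q3", "minp", "oehr")),
    median = median_cutpoint,
    q1q3 = quartile_cutpoints,
    minp = minp_cutpoint,
    oehr = function(d) oehr_cutpoints(d, check_u_shape = FALSE,
                                      min_group_frac = min_group_frac))
  set.seed(seed)
  rows <- list()
  for (rep in seq_len(n_repeats)) {
    fold <- NULL
    for (try in seq_len(max_retries)) {
      cand <- make_folds(data$status, n_folds)
      ev <- tapply(data$status, cand, sum)
      if (all(ev >= 1) && all(sum(data$status) - ev >= 20)) { fold <- cand; break }
    }
    if (is.null(fold)) stop("could not draw folds with enough events per fold")
    for (j in seq_len(n_folds)) {
      train <- data[fold != j, , drop = FALSE]
      test <- data[fold == j, , drop = FALSE]
      res <- estimator(train)
      test_df <- test
      test_df$.group <- assign_groups(res, test$x)
      lp <- unname(stats::predict(res$model, newdata = test_df, type = "lp"))
      vals <- c(
        cindex = if ("cindex" %in% measures)
          harrell_cindex(test$time, test$status, lp) else NA_real_,
        cpe = if ("cpe" %in% measures) gonen_heller_cpe(lp) else NA_real_,
        ibs = if ("ibs" %in% measures)
          integrated_brier_score(train, test, model = res$model,
                                 newdata = test_df) else NA_real_,
        r2_pm = if ("r2_pm" %in% measures) r2_pm(lp) else NA_real_,
        r2_d = if ("r2_d" %in% measures) r2_d(test$time, test$status, lp) else NA_real_)
      rows[[length(rows) + 1]] <- c(repeat_ = rep, fold = j, vals)
    }
  }
  raw <- as.data.frame(do.call(rbind, rows))
  vals <- raw[measures]
  structure(list(
    method = if (is.function(method)) "custom" else method,
    n_folds = n_folds, n_repeats = n_repeats,
    mean = colMeans(vals),
    se = apply(vals, 2, stats::sd) / sqrt(nrow(vals)),
    raw = raw), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("Cross-validated performance: method '%s', %d-fold x %d repeat(s)\n",
              x$method, x$n_folds, x$n_repeats))
  tab <- cbind(mean = x$mean, se = x$se)
  print(round(tab, 4))
  invisible(x)
}
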