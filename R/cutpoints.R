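#' @title Cut-point selection methods
#' @description Four discretization methods for a continuous predictor in a
#'   Cox model: the optimal equal-HR method ([oehr_cutpoints()]), the median
#'   split, the quartile (Q1/Q3) split, and the maximally selected log-rank
#'   (minimum p-value) split. Every method refits a categorical Cox model so
#'   that AIC/BIC and group hazard ratios are directly comparable.
#' @name cutpoint-methods
NULL

new_cutpoint_result <- function(method, cuts, model, data, groups,
                                rule = "three", extras = list()) {
  sm <- summary(model)
  coefs <- stats::coef(model)
  res <- structure(list(
    method = method,
    rule = rule,
    cuts = cuts,
    loglik = model$loglik[2],
    aic = -2 * model$loglik[2] + 2 * length(coefs),
    bic = -2 * model$loglik[2] + log(sum(data$status)) * length(coefs),
    coefficients = coefs,
    hrs = exp(coefs),
    se = sm$coefficients[, "se(coef)"],
    p_values = sm$coefficients[, "Pr(>|z|)"],
    group_counts = table(groups),
    n = nrow(data), n_events = sum(data$status),
    model = model), class = "cutpoint_result")
  res[names(extras)] <- extras
  res
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("Cut-point result: method '%s'\n", x$method))
  cat("  cut-point(s): ", paste(sprintf("%.4f", x$cuts), collapse = ", "), "\n")
  tab <- cbind(`log HR` = x$coefficients, HR = x$hrs, SE = x$se, p = x$p_values)
  print(round(tab, 4))
  cat("  group sizes: ",
      paste(sprintf("%s=%d", names(x$group_counts), x$group_counts), collapse = ", "), "\n")
  cat(sprintf("  AIC = %.3f, BIC = %.3f (n = %d, events = %d)\n",
              x$aic, x$bic, x$n, x$n_events))
  if (!is.null(x$p_naive))
    cat(sprintf("  minimum log-rank p = %.3g (naive, uncorrected for the search)\n", x$p_naive))
  invisible(x)
}

# Three groups: low (x < cut1), middle (reference), high (x > cut2).
cut_three <- function(x, cut1, cut2) {
  stopifnot(cut1 < cut2)
  factor(ifelse(x < cut1, "low", ifelse(x > cut2, "high", "middle")),
         levels = c("middle", "low", "high"))
}

cox_group_fit <- function(data, groups) {
  covs <- covariate_names(data)
  df <- data
  df$.group <- groups
  rhs <- paste(c(".group", covs), collapse = " + ")
  survival::coxph(stats::as.formula(paste("survival::Surv(time, status) ~", rhs)),
                  data = df, ties = "breslow")
}

#' Median-split cut-point
#'
#' Dichotomizes the predictor at its sample median (type-7 quantile) and
#' refits a two-group Cox model (reference: the low group).
#'
#' @param data Data frame with columns `time`, `status`, `x` and optional
#'   covariates.
#' @return A `cutpoint_result`.
#' @export
median_cutpoint <- function(data) {
  data <- validate_survival_data(data)
  if (length(unique(data$x)) < 2) stop("'x' is constant; no median split exists")
  cut <- stats::median(data$x)
  groups <- factor(ifelse(data$x < cut, "low", "high"), levels = c("low", "high"))
  if (any(table(groups) == 0)) stop("median split leaves an empty group")
  new_cutpoint_result("median", c(cut = cut), cox_group_fit(data, groups),
                      data, groups, rule = "lt")
}

#' Quartile (Q1/Q3) cut-points
#'
#' Cuts the predictor at its empirical 25th and 75th percentiles (type-7),
#' giving three groups in roughly 1:2:1 proportion with the middle range as
#' reference.
#'
#' @inheritParams median_cutpoint
#' @return A `cutpoint_result`.
#' @export
quartile_cutpoints <- function(data) {
  data <- validate_survival_data(data)
  q <- stats::quantile(data$x, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] >= q[2]) stop("degenerate quartiles (Q1 >= Q3)")
  fit_categorical_cox(data, q[1], q[2], min_group_frac = 0, method = "q1q3")
}

#' Fit the three-group categorical Cox model induced by a cut-point pair
#'
#' Discretizes `x` into low (`x < cut1`), middle (`cut1 <= x <= cut2`,
#' reference) and high (`x > cut2`) and fits a Cox model (Breslow ties) with
#' two dummy variables plus any adjustment covariates. `AIC = -2 pl + 2 k`
#' and `BIC = -2 pl + log(events) * k` with `k` the number of estimated
#' coefficients.
#'
#' @inheritParams median_cutpoint
#' @param cut1,cut2 Lower and upper cut-points, `cut1 < cut2`.
#' @param min_group_frac Minimum allowed group size as a fraction of `n`
#'   (default 0.05); an undersized group is an error naming the group.
#' @param method Method label stamped on the result (default `"pair"`).
#' @return A `cutpoint_result`.
#' @export
fit_categorical_cox <- function(data, cut1, cut2, min_group_frac = 0.05,
                                method = "pair") {
  data <- validate_survival_data(data)
  if (!(cut1 < cut2)) stop("need cut1 < cut2")
  groups <- cut_three(data$x, cut1, cut2)
  counts <- table(groups)
  min_size <- max(1, ceiling(min_group_frac * nrow(data)))
  bad <- names(counts)[counts < min_size]
  if (length(bad))
    stop(sprintf("group '%s' has %d observations (minimum %d)",
                 bad[1], counts[bad[1]], min_size))
  model <- cox_group_fit(data, groups)
  new_cutpoint_result(method, c(lower = cut1, upper = cut2), model, data, groups)
}

#' Candidate cut-point pairs with equal fitted log relative hazard
#'
#' For each integer percentile `k` in 5..95 of the n fitted log relative
#' hazard values, a horizontal line at that height is intersected with the
#' fitted U-shaped curve; the observed predictor values closest (in x) to
#' the left and right intersections form a candidate pair, subject to the
#' equal-height constraint `|log lam(x1) - log lam(x2)| <= 0.01`. When the
#' closest observations violate the constraint, the pair is replaced by
#' linearly interpolated points on the curve, which have exactly equal
#' heights. Percentiles whose line misses one arm of the curve are dropped.
#'
#' @param fit A `spline_cox` fit.
#' @param max_gap Equal-height tolerance on observed pairs (default 0.01).
#' @param grid_size Resolution of the curve grid used for intersections.
#' @return A data frame (class `candidate_pairs`) with columns
#'   `percentile`, `x1`, `x2`, `loglam1`, `loglam2`, `interpolated`.
#' @export
candidate_equal_hr_pairs <- function(fit, max_gap = 0.01, grid_size = 401) {
  stopifnot(inherits(fit, "spline_cox"))
  x_obs <- fit$data$x
  ll_obs <- fit$fitted
  grid <- seq(fit$range[1], fit$range[2], length.out = grid_size)
  y <- predict(fit, grid)
  imin <- which.min(y)
  x_min <- grid[imin]

  cross_near_min <- function(idx) {
    # innermost sign change of y - Q on one side of the minimum
    if (length(idx) < 2) return(NA_real_)
    f <- yq[idx]
    ch <- which(f[-length(f)] * f[-1] <= 0 & (f[-length(f)] != 0 | f[-1] != 0))
    if (!length(ch)) return(NA_real_)
    i <- if (idx[1] < imin) max(ch) else min(ch)    # closest to the minimum
    i1 <- idx[i]; i2 <- idx[i + 1]
    grid[i1] + (grid[i2] - grid[i1]) * (Q - y[i1]) / (y[i2] - y[i1])
  }

  left_obs <- which(x_obs < x_min)
  right_obs <- which(x_obs > x_min)
  out <- vector("list", 91)
  for (k in 5:95) {
    Q <- stats::quantile(ll_obs, k / 100, type = 7, names = FALSE)
    yq <- y - Q
    xl <- cross_near_min(seq_len(imin))
    xr <- cross_near_min(imin:grid_size)
    if (is.na(xl) || is.na(xr)) next
    pick <- function(obs_idx, target) {
      if (!length(obs_idx)) return(NA_integer_)
      dx <- abs(x_obs[obs_idx] - target)
      cand <- obs_idx[dx <= min(dx) + 1e-12]
      cand[which.min(abs(ll_obs[cand] - Q))]     # tie-break: closer in height
    }
    j1 <- pick(left_obs, xl)
    j2 <- pick(right_obs, xr)
    if (is.na(j1) || is.na(j2)) next
    if (abs(ll_obs[j1] - ll_obs[j2]) <= max_gap) {
      pair <- c(x_obs[j1], x_obs[j2], ll_obs[j1], ll_obs[j2], 0)
    } else {
      pair <- c(xl, xr, Q, Q, 1)                 # interpolated points: exactly equal heights
    }
    if (pair[1] < pair[2]) out[[k - 4]] <- c(k, pair)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no valid equal-height pair: the fitted curve is not U-shaped over the support")
  out <- as.data.frame(out)
  names(out) <- c("percentile", "x1", "x2", "loglam1", "loglam2", "interpolated")
  out$interpolated <- out$interpolated == 1
  out <- out[!duplicated(round(out[, c("x1", "x2")], 10)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_pairs", class(out))
  out
}

#' Optimal equal-HR cut-points
#'
#' The package's central method: among candidate cut-point pairs with equal
#' fitted log relative hazard ([candidate_equal_hr_pairs()]), returns the
#' pair whose three-group categorical Cox model minimizes AIC (or BIC).
#' Ties are broken toward the pair with the more balanced group sizes.
#'
#' @inheritParams median_cutpoint
#' @param fit Optional precomputed [fit_spline_cox()] result; fitted from
#'   `data` when missing.
#' @param criterion `"aic"` (default) or `"bic"`.
#' @param min_group_frac Minimum group size fraction passed to
#'   [fit_categorical_cox()].
#' @param check_u_shape If `TRUE` (default), refuse to run when
#'   [diagnose_u_shape()] does not flag a U shape.
#' @param max_gap,grid_size Passed to [candidate_equal_hr_pairs()].
#' @return A `cutpoint_result` with method `"oehr"` and a `candidates`
#'   data frame carrying the AIC/BIC of every evaluated pair.
#' @examples
#' sc <- sim_scenario(k1 = -2, k2 = 2, a = 0, n = 300, reps = 1, seed = 7)
#' d <- generate_dataset(sc, 1)
#' fit <- fit_spline_cox(d)
#' oehr_cutpoints(d, fit, check_u_shape = FALSE)
#' @export
oehr_cutpoints <- function(data, fit = NULL, criterion = c("aic", "bic"),
                           min_group_frac = 0.05, check_u_shape = TRUE,
                           max_gap = 0.01, grid_size = 401) {
  criterion <- match.arg(criterion)
  data <- validate_survival_data(data)
  if (is.null(fit)) fit <- fit_spline_cox(data)
  if (check_u_shape) {
    diag <- diagnose_u_shape(fit)
    if (!diag$is_u_shaped)
      stop("the fitted curve is not U-shaped; inspect diagnose_u_shape() ",
           "or rerun with check_u_shape = FALSE")
  }
  cands <- candidate_equal_hr_pairs(fit, max_gap = max_gap, grid_size = grid_size)
  cands$aic <- NA_real_
  cands$bic <- NA_real_
  fits <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    f <- tryCatch(fit_categorical_cox(data, cands$x1[i], cands$x2[i],
                                      min_group_frac = min_group_frac),
                  error = function(e) NULL)
    if (is.null(f)) next
    fits[[i]] <- f
    cands$aic[i] <- f$aic
    cands$bic[i] <- f$bic
  }
  crit <- cands[[criterion]]
  if (all(is.na(crit))) stop("all candidate pairs failed the categorical Cox refit")
  best_val <- min(crit, na.rm = TRUE)
  tied <- which(!is.na(crit) & crit <= best_val + 1e-10)
  if (length(tied) > 1) {
    balance <- vapply(fits[tied], function(f) min(f$group_counts), 0)
    tied <- tied[order(-balance, cands$percentile[tied])]
  }
  best <- tied[1]
  res <- fits[[best]]
  res$method <- "oehr"
  res$criterion <- criterion
  res$spline_fit <- fit
  res$candidates <- cands
  res$percentile <- cands$percentile[best]
  res
}

# Log-rank scores a_i = d_i - NelsonAalen(T_i); sum(a) == 0. The two-sample
# log-rank numerator O - E for the split x <= c equals sum of a over that group.
logrank_scores <- function(time, status) {
  cp <- cox_prep(time, status)
  n <- length(time)
  nrisk_u <- n - cp$first + 1
  na_u <- cumsum(cp$du / nrisk_u)           # Nelson-Aalen at unique sorted times
  a <- numeric(n)
  a[cp$o] <- cp$d - na_u[cp$grp]
  a
}

# Maximally selected rank-statistic sweep: the log-rank score sum of the
# low group, standardized by its conditional (permutation) moments.
logrank_sweep <- function(time, status, x, candidates) {
  a <- logrank_scores(time, status)
  n <- length(x)
  o <- order(x)
  cum_a <- cumsum(a[o])
  n1 <- findInterval(candidates, x[o])      # size of group x <= c
  s <- cum_a[n1]
  va <- sum(a^2) * n1 * (n - n1) / (n * (n - 1))
  z <- ifelse(va > 0, s / sqrt(va), 0)
  list(z = z, score_sum = s, n1 = n1)
}

#' Maximally selected log-rank (minimum p-value) cut-point
#'
#' Evaluates the standardized log-rank statistic at every admissible split
#' of the predictor (observed values inside the inner quantile `window`)
#' and returns the split maximizing the absolute statistic, i.e. minimizing
#' the log-rank p-value. The statistic is the maximally selected rank
#' statistic with log-rank scores: the score sum of the low group,
#' standardized by its conditional permutation mean and variance
#' (Lausen-Schumacher convention, as in the maxstat approach). The reported
#' p-value is the naive minimum, uncorrected for the multiplicity of the
#' search, and is flagged as such.
#'
#' @inheritParams median_cutpoint
#' @param window Admissible-split quantile window for the cut (default
#'   `c(0.1, 0.9)`).
#' @return A `cutpoint_result` with method `"minp"`, carrying the selected
#'   standardized statistic (`statistic`), the naive `p_naive` and the full
#'   sweep (`sweep`: candidate cuts and statistics).
#' @export
minp_cutpoint <- function(data, window = c(0.1, 0.9)) {
  data <- validate_survival_data(data)
  if (sum(data$status) < 20) stop("need at least 20 events")
  q <- stats::quantile(data$x, window, type = 7, names = FALSE)
  candidates <- sort(unique(data$x[data$x >= q[1] & data$x <= q[2]]))
  candidates <- candidates[candidates < max(data$x)]
  if (!length(candidates)) stop("no admissible split inside the quantile window")
  sw <- logrank_sweep(data$time, data$status, data$x, candidates)
  best <- which.max(abs(sw$z))
  cut <- candidates[best]
  groups <- factor(ifelse(data$x <= cut, "low", "high"), levels = c("low", "high"))
  res <- new_cutpoint_result(
    "minp", c(cut = cut), cox_group_fit(data, groups), data, groups, rule = "le",
    extras = list(statistic = abs(sw$z[best]),
                  p_naive = stats::pchisq(sw$z[best]^2, df = 1, lower.tail = FALSE),
                  p_note = "naive minimum p-value; not corrected for the split search",
                  sweep = data.frame(cut = candidates, z = sw$z)))
  res
}
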