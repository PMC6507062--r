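#' Cubic B-spline basis on evenly spaced knots
#'
#' Builds the design matrix of B-spline basis functions on `n_knots` evenly
#' spaced knots spanning the observed range of `x` (boundary knots extended
#' with the same spacing). With the defaults (degree 3, 22 knots) the basis
#' has `n_knots + degree - 1 = 24` columns and its rows sum to one at every
#' point of the knot range (partition of unity).
#'
#' @param x Numeric vector of predictor values (non-degenerate).
#' @param degree Spline degree (default 3, cubic).
#' @param n_knots Number of evenly spaced knots over `range(x)` (default 22).
#' @param xrange Optional range to span instead of `range(x)`.
#' @return A list with the design matrix `design`, the augmented knot vector
#'   `knots_aug`, `degree` and the spanned `range`.
#' @export
bspline_basis <- function(x, degree = 3, n_knots = 22, xrange = NULL) {
  stopifnot(n_knots >= degree + 2, degree >= 1)
  if (is.null(xrange)) xrange <- range(x)
  if (diff(xrange) <= 0) stop("'x' is constant; cannot build a spline basis")
  knots <- seq(xrange[1], xrange[2], length.out = n_knots)
  h <- knots[2] - knots[1]
  knots_aug <- c(xrange[1] - (degree:1) * h, knots, xrange[2] + (1:degree) * h)
  if (any(x < xrange[1] | x > xrange[2]))
    stop(sprintf("x outside the basis range [%.4g, %.4g]", xrange[1], xrange[2]))
  design <- splines::splineDesign(knots_aug, x, ord = degree + 1)
  list(design = design, knots_aug = knots_aug, degree = degree, range = xrange)
}

# Breslow bookkeeping: sort by time, group tied times, locate risk-set heads.
cox_prep <- function(time, status) {
  o <- order(time)
  ts <- time[o]
  grp <- cumsum(c(TRUE, ts[-1] != ts[-length(ts)]))
  first <- which(!duplicated(grp))
  d <- as.numeric(status[o])
  du <- as.vector(rowsum(d, grp))
  list(o = o, grp = grp, first = first, d = d, du = du)
}

mat_revcumsum <- function(m) {
  n <- nrow(m)
  m <- apply(m[n:1, , drop = FALSE], 2, cumsum)
  m[n:1, , drop = FALSE]
}

# Breslow partial log-likelihood, score and information for design X
# (already ordered by cp$o) at linear predictor eta = X %*% beta.
cox_loglik_parts <- function(cp, X, beta, hessian = TRUE) {
  eta <- drop(X %*% beta)
  eta <- eta - mean(eta)                      # numerical guard; pl is shift-invariant
  w <- exp(eta)
  s0 <- rev(cumsum(rev(w)))[cp$first]
  ev <- cp$d == 1
  ll <- sum(eta[ev]) - sum(cp$du * log(s0))
  s1 <- mat_revcumsum(w * X)[cp$first, , drop = FALSE]
  ebar <- s1 / s0
  g <- colSums(X[ev, , drop = FALSE]) - colSums(cp$du * ebar)
  out <- list(loglik = ll, gradient = g)
  if (hessian) {
    q <- cumsum(cp$du / s0)[cp$grp]           # sum over event times <= t_i of du/S0
    out$hessian <- crossprod(X * sqrt(w * q)) - crossprod(sqrt(cp$du) * ebar)
  }
  out
}

# Orthonormal basis of the complement of the constant coefficient direction.
# The Cox partial likelihood and the difference penalty are both invariant to
# adding a constant to all spline coefficients, so that direction is removed.
constant_null_basis <- function(p) {
  qr.Q(qr(cbind(rep(1, p), diag(p)[, -1])))[, -1, drop = FALSE]
}

#' Fit a Cox model with a penalized B-spline predictor effect at fixed smoothing
#'
#' Maximizes the Breslow partial log-likelihood minus
#' `(smoothing / 2) * b' D'D b`, where `D` is the second-order difference
#' matrix on adjacent spline coefficients, by Newton iteration with
#' step-halving. Optional adjustment covariates (any columns beyond
#' `time`, `status`, `x`) enter linearly and unpenalized. The effective
#' degrees of freedom are `tr((H + s P)^{-1} H)` with `H` the information of
#' the unpenalized fit, and `AIC = -2 pl + 2 edf`.
#'
#' @param data A data frame with columns `time`, `status`, `x` and optional
#'   covariate columns.
#' @param smoothing Non-negative penalty weight.
#' @param n_knots,degree Basis controls, see [bspline_basis()].
#' @param max_iter,tol Newton controls: iteration cap and convergence
#'   threshold on the max absolute penalized score.
#' @param init Optional starting coefficient vector (internal warm starts).
#' @return An object of class `spline_cox`; see [predict.spline_cox()],
#'   [diagnose_u_shape()].
#' @seealso [fit_spline_cox()] for AIC-based smoothing selection.
#' @export
fit_penalized_cox <- function(data, smoothing, n_knots = 22, degree = 3,
                              max_iter = 50, tol = 1e-6, init = NULL) {
  data <- validate_survival_data(data)
  stopifnot(length(smoothing) == 1, smoothing >= 0)
  if (sum(data$status) < 20) stop("need at least 20 events for a spline Cox fit")
  basis <- bspline_basis(data$x, degree = degree, n_knots = n_knots)
  B <- basis$design
  p <- ncol(B)
  Z <- constant_null_basis(p)
  covs <- covariate_names(data)
  C <- if (length(covs)) as.matrix(data[covs]) else NULL
  X <- cbind(B %*% Z, C)
  q <- ncol(X)
  D <- diff(diag(p), differences = 2)
  Pz <- crossprod(Z, crossprod(D) %*% Z)
  Pen <- matrix(0, q, q)
  Pen[seq_len(p - 1), seq_len(p - 1)] <- Pz

  cp <- cox_prep(data$time, data$status)
  Xo <- X[cp$o, , drop = FALSE]
  beta <- if (is.null(init)) rep(0, q) else init
  pen_ll <- function(parts, b) parts$loglik - smoothing / 2 * drop(crossprod(b, Pen %*% b))

  parts <- cox_loglik_parts(cp, Xo, beta)
  obj <- pen_ll(parts, beta)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g_pen <- parts$gradient - smoothing * drop(Pen %*% beta)
    if (max(abs(g_pen)) < tol) { converged <- TRUE; break }
    H_pen <- parts$hessian + smoothing * Pen
    step <- tryCatch(solve(H_pen, g_pen),
                     error = function(e) solve(H_pen + diag(1e-8, q), g_pen))
    ok <- FALSE
    for (half in 0:30) {                      # step-halving keeps the objective non-decreasing
      cand <- beta + step / 2^half
      parts_new <- cox_loglik_parts(cp, Xo, cand)
      obj_new <- pen_ll(parts_new, cand)
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) break
    beta <- cand
    parts <- parts_new
    obj <- obj_new
    trace <- c(trace, obj)
  }
  if (!converged) {
    g_pen <- parts$gradient - smoothing * drop(Pen %*% beta)
    if (max(abs(g_pen)) >= tol * 100)
      stop("penalized Cox fit did not converge; objective trace: ",
           paste(signif(trace, 8), collapse = ", "))
  }

  H <- parts$hessian
  H_pen <- H + smoothing * Pen
  edf <- sum(diag(solve(H_pen, H)))
  gamma <- beta[seq_len(p - 1)]
  beta_spline <- drop(Z %*% gamma)
  center <- mean(drop(B %*% beta_spline))
  fitted <- drop(B %*% beta_spline) - center
  Vpen <- solve(H_pen)

  structure(list(
    knots_aug = basis$knots_aug, degree = degree, n_knots = n_knots,
    range = basis$range, Z = Z, gamma = gamma, beta_spline = beta_spline,
    cov_coef = if (length(covs)) stats::setNames(beta[-seq_len(p - 1)], covs) else NULL,
    smoothing = smoothing, edf = edf, loglik = parts$loglik,
    aic = -2 * parts$loglik + 2 * edf,
    center = center, fitted = fitted, cov_spline = Vpen[seq_len(p - 1), seq_len(p - 1)],
    data = data, n_events = sum(data$status), iterations = length(trace),
    converged = converged), class = "spline_cox")
}

#' Fit a P-spline Cox model with AIC-selected smoothing
#'
#' Fits [fit_penalized_cox()] over a grid of smoothing weights and returns
#' the fit minimizing `AIC = -2 pl + 2 edf`; ties are broken toward the
#' larger smoothing weight (the smoother curve). The default log-spaced
#' grid spans effective degrees of freedom from roughly 15 down to the
#' linear limit.
#'
#' @inheritParams fit_penalized_cox
#' @param smoothing_grid Positive, sorted grid of penalty weights.
#' @return A `spline_cox` object with extra fields `smoothing_grid` and
#'   `aic_path`.
#' @export
fit_spline_cox <- function(data, smoothing_grid = 10^seq(-2, 5, length.out = 25),
                           n_knots = 22, degree = 3) {
  stopifnot(length(smoothing_grid) >= 1, all(smoothing_grid > 0),
            !is.unsorted(smoothing_grid))
  best <- NULL
  aics <- rep(NA_real_, length(smoothing_grid))
  init <- NULL
  fails <- character(0)
  for (i in seq_along(smoothing_grid)) {
    fit <- tryCatch(
      fit_penalized_cox(data, smoothing_grid[i], n_knots = n_knots,
                        degree = degree, init = init),
      error = function(e) e)
    if (inherits(fit, "error")) { fails <- c(fails, conditionMessage(fit)); next }
    init <- c(fit$gamma, fit$cov_coef)        # warm start along the grid
    aics[i] <- fit$aic
    if (is.null(best) || fit$aic <= best$aic + 1e-10) best <- fit
  }
  if (is.null(best))
    stop("all smoothing-grid fits failed; first error: ", fails[1])
  best$smoothing_grid <- smoothing_grid
  best$aic_path <- aics
  best
}

#' @export
print.spline_cox <- function(x, ...) {
  cat("Penalized B-spline Cox fit\n")
  cat(sprintf("  n = %d (%d events); basis: degree %d, %d evenly spaced knots\n",
              nrow(x$data), x$n_events, x$degree, x$n_knots))
  cat(sprintf("  smoothing = %.4g, edf = %.2f, partial loglik = %.3f, AIC = %.3f\n",
              x$smoothing, x$edf, x$loglik, x$aic))
  if (!is.null(x$cov_coef)) {
    cat("  adjustment covariates: ",
        paste(sprintf("%s = %.3f", names(x$cov_coef), x$cov_coef), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict the centered log relative hazard curve
#'
#' Evaluates the fitted spline effect at new predictor values, centered so
#' that its mean over the observed predictor values is zero (the relative
#' hazard is only defined up to a multiplicative constant). Values outside
#' the observed range are refused rather than extrapolated.
#'
#' @param object A `spline_cox` fit.
#' @param newx Numeric vector of predictor values inside the fitted range.
#' @param se.fit If `TRUE`, also return pointwise standard errors from the
#'   penalized-information covariance.
#' @param ... Unused.
#' @return A numeric vector, or a list with `fit` and `se.fit`.
#' @export
predict.spline_cox <- function(object, newx = object$data$x, se.fit = FALSE, ...) {
  if (any(newx < object$range[1] | newx > object$range[2]))
    stop(sprintf("newx outside the fitted range [%.4g, %.4g]; extrapolation is refused",
                 object$range[1], object$range[2]))
  B <- splines::splineDesign(object$knots_aug, newx, ord = object$degree + 1)
  fit <- drop(B %*% object$beta_spline) - object$center
  if (!se.fit) return(fit)
  BZ <- B %*% object$Z
  se <- sqrt(pmax(0, rowSums((BZ %*% object$cov_spline) * BZ)))
  list(fit = fit, se.fit = se)
}

#' Diagnose a U-shaped predictor effect
#'
#' Samples the fitted centered log relative hazard on a grid over the
#' central 90% of the observed predictor (boundary wiggle of splines is
#' excluded) and flags a U shape when the first differences change sign
#' exactly once, from negative to positive. A nonlinearity p-value compares
#' the spline fit with a linear Cox fit by a chi-square test on
#' `2 * (pl_spline - pl_linear)` with `edf - 1` degrees of freedom (minus
#' one per adjustment covariate).
#'
#' @param fit A `spline_cox` fit.
#' @param n_grid Grid size (default 200).
#' @param central Central probability mass of `x` to scan (default 0.90).
#' @return An object of class `u_shape_diagnosis`: `is_u_shaped`,
#'   `minimum` (location of the fitted minimum), `p_nonlinear`, and a
#'   `curve` data frame (`x`, `loglam`, `lower95`, `upper95`).
#' @export
diagnose_u_shape <- function(fit, n_grid = 200, central = 0.90) {
  stopifnot(inherits(fit, "spline_cox"))
  pr <- c((1 - central) / 2, 1 - (1 - central) / 2)
  qs <- stats::quantile(fit$data$x, pr, type = 7, names = FALSE)
  grid <- seq(qs[1], qs[2], length.out = n_grid)
  pred <- predict(fit, grid, se.fit = TRUE)
  y <- pred$fit
  s <- sign(diff(y))
  runs <- rle(s[s != 0])$values
  is_u <- length(runs) == 2 && runs[1] == -1 && runs[2] == 1

  covs <- covariate_names(fit$data)
  rhs <- paste(c("x", covs), collapse = " + ")
  lin <- survival::coxph(stats::as.formula(paste("survival::Surv(time, status) ~", rhs)),
                         data = fit$data, ties = "breslow")
  lr <- 2 * (fit$loglik - lin$loglik[2])
  df <- max(fit$edf - 1 - length(covs), 0.5)
  p_nl <- stats::pchisq(max(lr, 0), df = df, lower.tail = FALSE)

  structure(list(
    is_u_shaped = is_u,
    minimum = grid[which.min(y)],
    p_nonlinear = p_nl,
    lr_statistic = lr, df = df,
    curve = data.frame(x = grid, loglam = y,
                       lower95 = y - 1.96 * pred$se.fit,
                       upper95 = y + 1.96 * pred$se.fit)),
    class = "u_shape_diagnosis")
}

#' @export
print.u_shape_diagnosis <- function(x, ...) {
  cat(sprintf("U-shape diagnostic: %s\n",
              if (x$is_u_shaped) "U-shaped (single interior minimum)" else "not U-shaped"))
  cat(sprintf("  fitted minimum at x = %.3f\n", x$minimum))
  cat(sprintf("  nonlinearity: LR = %.2f on %.1f df, p = %.3g\n",
              x$lr_statistic, x$df, x$p_nonlinear))
  invisible(x)
}

#' Plot the fitted log relative hazard curve
#'
#' @param x A `spline_cox` fit.
#' @param n_grid Number of grid points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spline_cox <- function(x, n_grid = 200, ...) {
  grid <- seq(x$range[1], x$range[2], length.out = n_grid)
  pred <- predict(x, grid, se.fit = TRUE)
  graphics::plot(grid, pred$fit, type = "l",
                 xlab = "predictor", ylab = "log relative hazard", ...)
  graphics::lines(grid, pred$fit - 1.96 * pred$se.fit, lty = 2)
  graphics::lines(grid, pred$fit + 1.96 * pred$se.fit, lty = 2)
  graphics::rug(x$data$x)
  invisible(x)
}
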