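test_that("B-spline basis is a partition of unity with the documented dimension", {
  set.seed(2)
  x <- rnorm(200)
  b <- bspline_basis(x, degree = 3, n_knots = 22)
  expect_equal(ncol(b$design), 22 + 3 - 1)
  expect_equal(rowSums(b$design), rep(1, 200), tolerance = 1e-12)
  expect_error(bspline_basis(rep(1, 10)), "constant")
})

test_that("basis values match the de Boor recursion", {
  x <- seq(-1.7, 1.7, length.out = 11)
  b <- bspline_basis(x, degree = 3, n_knots = 8, xrange = c(-2, 2))
  mid <- (b$knots_aug[6] + b$knots_aug[7]) / 2   # a knot midpoint
  bm <- bspline_basis(mid, degree = 3, n_knots = 8, xrange = c(-2, 2))$design
  oracle <- vapply(seq_len(ncol(bm)),
                   function(i) deboor_basis(b$knots_aug, mid, i, 4), 0)
  expect_equal(drop(bm), oracle, tolerance = 1e-12)
})

test_that("unpenalized spline Cox fit matches a generic Cox routine on the same basis", {
  d <- make_v_data(150, seed = 5)
  fit <- fit_penalized_cox(d, smoothing = 0, n_knots = 6)
  # identical basis, fitted by survival::coxph (constant column dropped for identifiability)
  B <- bspline_basis(d$x, degree = 3, n_knots = 6)$design
  Bm <- B[, -1]
  cox <- survival::coxph(survival::Surv(d$time, d$status) ~ Bm, ties = "breslow")
  eta_cox <- drop(Bm %*% coef(cox))
  eta_cox <- eta_cox - mean(eta_cox)
  expect_equal(fit$fitted, eta_cox, tolerance = 1e-4)
  expect_equal(fit$loglik, cox$loglik[2], tolerance = 1e-6)
})

test_that("heavy smoothing drives the curve to a straight line", {
  d <- make_v_data(200, seed = 6)
  fit <- fit_penalized_cox(d, smoothing = 1e9)
  grid <- seq(quantile(d$x, 0.05), quantile(d$x, 0.95), length.out = 50)
  y <- predict(fit, grid)
  lin <- lm(y ~ grid)
  expect_lt(max(abs(residuals(lin))), 0.01)
  expect_lt(fit$edf, 1.2)
})

test_that("edf decreases monotonically with smoothing and AIC selection is exhaustive", {
  d <- make_v_data(300, seed = 7)
  grid <- 10^seq(-2, 5, length.out = 10)
  fits <- lapply(grid, function(s) fit_penalized_cox(d, s))
  edfs <- vapply(fits, `[[`, 0, "edf")
  expect_true(all(diff(edfs) <= 1e-6))

  sel <- fit_spline_cox(d, smoothing_grid = grid)
  expect_true(all(sel$aic <= vapply(fits, `[[`, 0, "aic") + 1e-8))
  expect_gt(sel$edf, 2)                       # nonlinearity detected on V-truth
  one <- fit_spline_cox(d, smoothing_grid = grid[4])
  expect_equal(one$smoothing, grid[4])
})

test_that("fitted curve recovers the V-truth minimum and is centered", {
  d <- make_v_data(500, k1 = -4/3, k2 = 4, a = 1, seed = 8)
  fit <- fit_spline_cox(d)
  expect_lt(abs(mean(predict(fit, d$x))), 1e-8)   # centering convention
  dg <- diagnose_u_shape(fit)
  expect_true(dg$is_u_shaped)
  expect_equal(dg$minimum, 1, tolerance = 0.3)
  expect_lt(dg$p_nonlinear, 1e-4)
  # monotone on each side of the fitted minimum over the central 90%
  y <- dg$curve$loglam
  im <- which.min(y)
  expect_true(all(diff(y[1:im]) <= 1e-8))
  expect_true(all(diff(y[im:length(y)]) >= -1e-8))
})

test_that("extrapolation is refused and predictions are reproducible", {
  d <- make_v_data(120, seed = 9)
  fit <- fit_spline_cox(d, smoothing_grid = 10^seq(0, 3, length.out = 5))
  expect_error(predict(fit, max(d$x) + 1), "range")
  p <- predict(fit, d$x[1:5], se.fit = TRUE)
  expect_length(p$fit, 5)
  expect_true(all(p$se.fit >= 0))
})

test_that("U-shape diagnostic separates linear from V-shaped truth", {
  flags <- vapply(1:10, function(i) {
    set.seed(100 + i)
    x <- rnorm(250)
    lin <- data.frame(time = -log(runif(250)) / exp(0.8 * x), status = 1L, x = x)
    diagnose_u_shape(fit_spline_cox(lin))$is_u_shaped
  }, NA)
  expect_lte(sum(flags), 1)                     # specificity on monotone truth

  flags_v <- vapply(1:10, function(i)
    diagnose_u_shape(fit_spline_cox(make_v_data(400, seed = 200 + i)))$is_u_shaped, NA)
  expect_gte(sum(flags_v), 9)                   # sensitivity on V-truth
})

test_that("spline fit requires enough events", {
  d <- make_v_data(30, seed = 10)
  d$status[1:15] <- 0L
  expect_error(fit_penalized_cox(d, 1), "events")
})
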