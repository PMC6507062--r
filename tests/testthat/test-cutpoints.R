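toy_data <- function(x, seed = 1) {
  set.seed(seed)
  data.frame(time = -log(runif(length(x))), status = 1L, x = x)
}

test_that("median split equals the order-statistic median", {
  d <- toy_data(c(1, 2, 3))
  # n = 3 makes the Cox refit degenerate (benign coxph convergence warning)
  expect_equal(unname(suppressWarnings(median_cutpoint(d))$cuts), 2)
  set.seed(3)
  x <- rnorm(101)
  expect_equal(unname(median_cutpoint(toy_data(x))$cuts), sort(x)[51])
  expect_error(median_cutpoint(toy_data(rep(1, 10))), "constant")
})

test_that("quartile cut-points use the type-7 percentile rule and recover N(0,1) quartiles", {
  d <- toy_data(c(1, 2, 3, 4))
  expect_equal(unname(suppressWarnings(quartile_cutpoints(d))$cuts),
               unname(quantile(c(1, 2, 3, 4), c(0.25, 0.75), type = 7)))
  set.seed(4)
  big <- toy_data(rnorm(1e5))
  expect_equal(unname(quartile_cutpoints(big)$cuts), c(-0.6745, 0.6745),
               tolerance = 0.02)
  expect_error(quartile_cutpoints(toy_data(c(1, 1, 1, 1, 2))), "degenerate")
})

test_that("minP sweep equals an independent brute-force maximally selected statistic", {
  sc <- sim_scenario(-8/5, 8/3, 1/2, Pc = 0.2, n = 200, reps = 1, seed = 31)
  d <- generate_dataset(sc, 1)
  res <- minp_cutpoint(d)
  z_oracle <- brute_maxsel(d$time, d$status, d$x, res$sweep$cut)
  expect_equal(res$sweep$z, z_oracle, tolerance = 1e-10)
  expect_equal(unname(res$cuts), res$sweep$cut[which.max(abs(z_oracle))])
  expect_equal(res$statistic, max(abs(z_oracle)))
  # the score sum equals the classical log-rank numerator O - E (survdiff)
  cc <- unname(res$cuts)
  sd <- survival::survdiff(survival::Surv(time, status) ~ I(x <= cc), data = d)
  s <- oehr:::logrank_sweep(d$time, d$status, d$x, cc)$score_sum
  expect_equal(s, sd$obs[2] - sd$exp[2], tolerance = 1e-8)
})

test_that("minP recovers a true step-change threshold", {
  hits <- vapply(1:10, function(i) {
    d <- make_step_data(500, cut = 0.3, b = 1.5, seed = 300 + i)
    abs(unname(minp_cutpoint(d)$cuts) - 0.3) <= 0.1
  }, NA)
  expect_gte(sum(hits), 9)
})

test_that("candidate pairs respect the equal-log-hazard constraint and percentile window", {
  d <- make_v_data(400, seed = 41)
  fit <- fit_spline_cox(d)
  cands <- candidate_equal_hr_pairs(fit)
  expect_lte(nrow(cands), 91)
  expect_true(all(cands$percentile %in% 5:95))
  expect_true(all(cands$x1 < cands$x2))
  expect_true(all(abs(cands$loglam1 - cands$loglam2) <= 0.01))
  # heights re-evaluated on the fitted curve stay within the constraint
  gap <- abs(predict(fit, cands$x1) - predict(fit, cands$x2))
  expect_true(all(gap <= 0.011))
})

test_that("candidate pairs of a symmetric fit are mirror images", {
  set.seed(42)
  x <- rnorm(250)
  t0 <- -log(runif(250)) / exp(piecewise_log_hazard(x, -2, 2, 0))
  # mirrored copy with the same times: the dataset is invariant under x -> -x
  d <- data.frame(time = rep(t0, 2), status = 1L, x = c(x, -x))
  fit <- fit_spline_cox(d)
  cands <- candidate_equal_hr_pairs(fit)
  expect_lt(median(abs(cands$x1 + cands$x2)), 0.05)
})

test_that("categorical Cox refit: definitions, conservation, group-size guard", {
  d <- make_v_data(400, seed = 43)
  res <- fit_categorical_cox(d, -0.9, 0.9)
  expect_equal(res$aic, -2 * res$model$loglik[2] + 2 * 2)
  expect_equal(res$bic, -2 * res$model$loglik[2] + log(sum(d$status)) * 2)
  expect_equal(sum(res$group_counts), nrow(d))
  expect_equal(res$n_events, sum(d$status))
  expect_equal(unname(res$hrs), unname(exp(res$coefficients)))
  expect_error(fit_categorical_cox(d, -0.9, max(d$x) - 1e-9), "group 'high'")
  # equal-height construction: cuts at +-0.9 on a symmetric V give equal HRs
  ratios <- vapply(1:10, function(i) {
    di <- make_v_data(400, seed = 430 + i)
    r <- fit_categorical_cox(di, -0.9, 0.9)
    (r$coefficients[1] - r$coefficients[2]) / sqrt(sum(r$se^2))
  }, 0)
  expect_gte(mean(abs(ratios) < 2), 0.9)
})

test_that("categorical Cox refit is well calibrated under the null", {
  z <- sapply(1:15, function(i) {
    set.seed(440 + i)
    d <- data.frame(time = -log(runif(300)), status = 1L, x = rnorm(300))
    r <- fit_categorical_cox(d, -0.7, 0.7)
    r$coefficients / r$se
  })
  # pooled Wald statistics: about 95% within +-2 under the null
  expect_gte(mean(abs(z) < 2), 0.85)
})

test_that("OEHR selection minimizes AIC over all candidates and sits inside support", {
  d <- make_v_data(500, k1 = -8/5, k2 = 8/3, a = 1/2, seed = 44)
  fit <- fit_spline_cox(d)
  res <- oehr_cutpoints(d, fit)
  # exhaustive independent re-check of the AIC over every candidate pair
  aics <- vapply(seq_len(nrow(res$candidates)), function(i) {
    tryCatch(fit_categorical_cox(d, res$candidates$x1[i], res$candidates$x2[i])$aic,
             error = function(e) Inf)
  }, 0)
  expect_equal(res$aic, min(aics))
  expect_true(res$cuts[1] > min(d$x) && res$cuts[2] < max(d$x))
  expect_lte(abs(predict(fit, res$cuts[1]) - predict(fit, res$cuts[2])), 0.011)
  expect_equal(sum(res$group_counts), nrow(d))
})

test_that("OEHR refuses a non-U-shaped curve unless overridden", {
  set.seed(46)
  x <- rnorm(250)
  d <- data.frame(time = -log(runif(250)) / exp(0.9 * x), status = 1L, x = x)
  fit <- fit_spline_cox(d)
  expect_error(oehr_cutpoints(d, fit), "not U-shaped")
})

test_that("AIC and BIC selections usually agree on symmetric-scenario data", {
  agree <- vapply(1:10, function(i) {
    d <- make_v_data(400, seed = 470 + i)
    fit <- fit_spline_cox(d)
    a <- oehr_cutpoints(d, fit, criterion = "aic", check_u_shape = FALSE)
    b <- oehr_cutpoints(d, fit, criterion = "bic", check_u_shape = FALSE)
    isTRUE(all.equal(a$cuts, b$cuts))
  }, NA)
  expect_gte(sum(agree), 9)
})

test_that("OEHR cut heights match on the true V within Monte-Carlo error", {
  # |k1| (a - cut1) and k2 (cut2 - a) estimate the same height
  sc <- sim_scenario(-8/5, 8/3, 1/2, Pc = 0, n = 500, reps = 15, seed = 48)
  dd <- vapply(1:15, function(i) {
    d <- generate_dataset(sc, i)
    r <- oehr_cutpoints(d, check_u_shape = FALSE)
    abs(sc$k1) * (sc$a - r$cuts[1]) - sc$k2 * (r$cuts[2] - sc$a)
  }, 0)
  expect_lt(abs(mean(dd)), 2 * sd(dd))
})
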