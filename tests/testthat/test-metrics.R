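test_that("c-index: perfect ordering, permutation null, brute-force equivalence", {
  set.seed(51)
  t <- sort(rexp(40))
  expect_equal(harrell_cindex(t, rep(1, 40), rev(seq_len(40))), 1)

  null_c <- vapply(1:50, function(i) {
    set.seed(510 + i)
    harrell_cindex(rexp(200), rbinom(200, 1, 0.8), rnorm(200))
  }, 0)
  expect_equal(mean(null_c), 0.5, tolerance = 0.02)

  set.seed(52)
  tm <- rexp(50); st <- rbinom(50, 1, 0.7); rk <- rnorm(50)
  expect_equal(harrell_cindex(tm, st, rk), brute_cindex(tm, st, rk),
               tolerance = 1e-12)
  expect_error(harrell_cindex(c(1, 2), c(0, 0), c(1, 2)), "usable")
})

test_that("CPE: convention for ties and brute-force double-summation equivalence", {
  expect_equal(gonen_heller_cpe(rep(1.3, 20)), 0.5)
  set.seed(53)
  lp <- rnorm(50)
  expect_equal(gonen_heller_cpe(lp), brute_cpe(lp), tolerance = 1e-12)
  expect_gte(gonen_heller_cpe(lp), 0.5)
  expect_lt(gonen_heller_cpe(lp), 1)
  # censoring-free: depends on the model only, so any time vector is irrelevant
})

test_that("integrated Brier score: closed forms and model dominance", {
  set.seed(54)
  n <- 120
  d <- data.frame(time = rexp(n), status = 1L, x = rnorm(n))
  times <- seq(0.05, quantile(d$time, 0.9), length.out = 40)
  # constant predicted survival 1/2 with no censoring: BS(t) = 1/4 at every t
  half <- matrix(0.5, n, length(times))
  expect_equal(integrated_brier_score(d, d, surv_matrix = half, times = times), 0.25,
               tolerance = 1e-10)
  # oracle predictions: indicator of the true survival status
  oracle <- outer(d$time, times, ">") * 1
  expect_equal(integrated_brier_score(d, d, surv_matrix = oracle, times = times), 0)

  wins <- vapply(1:10, function(i) {
    di <- make_v_data(300, seed = 540 + i)
    tr <- di[1:150, ]; te <- di[151:300, ]
    res <- fit_categorical_cox(tr, -0.9, 0.9)
    te_df <- te; te_df$.group <- oehr:::assign_groups(res, te$x)
    ibs_model <- integrated_brier_score(tr, te, model = res$model, newdata = te_df)
    ibs_null <- integrated_brier_score(tr, te)
    ibs_model <= ibs_null
  }, NA)
  expect_gte(sum(wins), 9)
})

test_that("R2_PM follows its closed form and is monotone in lp variance", {
  expect_equal(r2_pm(rep(2, 30)), 0)
  set.seed(55)
  lp <- rnorm(100)
  lp <- (lp - mean(lp)) / sd(lp) * sqrt(pi^2 / 6)   # sample variance pi^2/6 exactly
  expect_equal(r2_pm(lp), 0.5, tolerance = 1e-12)
  expect_lt(r2_pm(lp), r2_pm(2 * lp))
})

test_that("R2_D: null behavior, affine invariance, monotone in signal", {
  set.seed(56)
  d <- make_v_data(300, seed = 56)
  lp_null <- rnorm(300)
  expect_lt(r2_d(d$time, d$status, lp_null), 0.05)
  lp <- piecewise_log_hazard(d$x, -2, 2, 0)
  expect_equal(r2_d(d$time, d$status, lp), r2_d(d$time, d$status, 3 * lp + 7))
  r_small <- vapply(1:8, function(i) {
    di <- make_v_data(300, k1 = -1, k2 = 1, seed = 560 + i)
    r2_d(di$time, di$status, piecewise_log_hazard(di$x, -1, 1, 0))
  }, 0)
  r_big <- vapply(1:8, function(i) {
    di <- make_v_data(300, k1 = -3, k2 = 3, seed = 560 + i)
    r2_d(di$time, di$status, piecewise_log_hazard(di$x, -3, 3, 0))
  }, 0)
  expect_lt(median(r_small), median(r_big))
})

test_that("cross-validation honours fold structure, determinism and row order", {
  d <- make_v_data(240, seed = 57)
  rep1 <- cv_performance(d, "q1q3", n_folds = 2, seed = 99)
  expect_equal(nrow(rep1$raw), 2)
  shuffled <- d[sample(nrow(d)), ]
  rep2 <- cv_performance(shuffled, "q1q3", n_folds = 2, seed = 99)
  expect_equal(rep1$mean, rep2$mean, tolerance = 1e-12)

  rep5 <- cv_performance(d, "median", n_folds = 5, n_repeats = 2, seed = 7,
                         measures = c("cindex", "cpe"))
  expect_equal(nrow(rep5$raw), 10)
  expect_true(all(is.finite(rep5$mean[c("cindex", "cpe")])))
  expect_true(all(rep5$se >= 0))
})

test_that("cross-validated metrics stay in range on scenario data", {
  sc <- sim_scenario(-2, 2, 0, Pc = 0.2, n = 300, reps = 1, seed = 58)
  d <- generate_dataset(sc, 1)
  rep <- cv_performance(d, "q1q3", n_folds = 2, seed = 1)
  expect_true(rep$mean["cindex"] > 0.5 && rep$mean["cindex"] < 1)
  expect_true(rep$mean["cpe"] >= 0.5 && rep$mean["cpe"] < 1)
  expect_true(rep$mean["ibs"] > 0 && rep$mean["ibs"] < 1)
  expect_true(rep$mean["r2_pm"] >= 0 && rep$mean["r2_pm"] < 1)
  expect_true(rep$mean["r2_d"] >= 0 && rep$mean["r2_d"] < 1)
})
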