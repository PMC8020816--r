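test_that("trapezoidal AUC matches hand-computed areas", {
  expect_equal(auc_trapezoid(c(0, 10), c(0, 1)), 5)
  expect_equal(auc_trapezoid(seq(0, 100, 10), rep(2, 11)), 200)
  expect_equal(auc_trapezoid(c(0, 10, 30), c(1, 3, 2)), 70)
  expect_error(auc_trapezoid(c(0), c(1)), "length")
  expect_error(auc_trapezoid(c(0, 0, 10), c(1, 2, 3)), "increasing")
})

test_that("subject indices follow their definitions", {
  # glucagon never below basal: zero deficit area
  rising <- ogtt_series(t2_times, c(50, 53, 57, 60, 62), t2_cp)
  fit <- fake_fit(params = model_params(0.01, 0.155, c(2, 2, 2, 2, 2)))
  idx <- subject_indices(rising, fit, step = 1)
  expect_identical(idx$auc_gluca_below_basal, 0)

  # constant knots give the same mean in every window
  expect_identical(idx$mean_sgluca_full, 2)
  expect_identical(idx$mean_sgluca_3h, 2)
  expect_identical(idx$mean_sgluca_2h, 2)

  # windows are nested: 2h mean uses knots at t <= 120, 3h at t <= 180
  s5 <- ogtt_series(t5_times, rep(60, 11), t5_cp)
  fit5 <- fake_fit(params = model_params(0.01, 0.155, 1:11))
  idx5 <- subject_indices(s5, fit5, step = 1)
  expect_equal(idx5$mean_sgluca_2h, mean(1:7))
  expect_equal(idx5$mean_sgluca_3h, mean(1:9))
  expect_equal(idx5$mean_sgluca_full, mean(1:11))

  # deficit area: trapezoid of max(basal - observed, 0) over sample times
  dipped <- ogtt_series(t2_times, c(60, 50, 40, 55, 65), t2_cp)
  idx_d <- subject_indices(dipped, fit, step = 1)
  expect_equal(idx_d$auc_gluca_below_basal,
               auc_trapezoid(t2_times, c(0, 10, 20, 5, 0)))
})

test_that("remote C-peptide AUC matches the analytic integral", {
  # constant input A: integral of (A/K)(1 - e^{-Kt}) over [0, T]
  A <- 0.31; K <- 0.155; Tend <- 30
  s <- constant_input_series(A, t_end = Tend)
  fit <- fake_fit(params = model_params(0.01, K, rep(1, 4)))
  idx <- subject_indices(s, fit, step = 1)
  analytic <- (A / K) * (Tend - (1 - exp(-K * Tend)) / K)
  expect_equal(idx$auc_dcp_remote, analytic, tolerance = 0.005)
})

test_that("sensitivity-vs-AUC-ratio regression handles exact and noisy data", {
  # collinear points recover the line exactly, with |r| = 1
  ratio <- exp(seq(-1, 1, length.out = 10))
  idx <- lapply(ratio, function(q)
    make_indices(mean_full = exp(0.30 - 0.62 * log(q)), auc_dcp = q))
  reg <- sgluca_auc_regression(idx)
  expect_equal(reg$slope, -0.62)
  expect_equal(reg$intercept, 0.30)
  expect_identical(reg$r, -1)
  expect_identical(reg$r_ci, c(-1, -1))

  # constant response is degenerate
  idx_c <- lapply(ratio, function(q) make_indices(2, auc_dcp = q))
  expect_true(sgluca_auc_regression(idx_c)$degenerate)

  # non-positive means are excluded and counted
  idx_m <- c(idx, list(make_indices(-0.5), make_indices(1, auc_dcp = 0)))
  reg_m <- sgluca_auc_regression(idx_m)
  expect_identical(reg_m$n_used, 10L)
  expect_identical(reg_m$n_excluded, 2L)

  expect_error(sgluca_auc_regression(idx[1:2]), "fewer than 3")
})

test_that("regression recovers a known generative power law", {
  set.seed(31)
  q <- exp(rnorm(100, 0, 0.8))
  s_mean <- q^(-0.6) * exp(rnorm(100, 0, 0.1))
  idx <- mapply(function(si, qi) make_indices(si, auc_dcp = qi),
                s_mean, q, SIMPLIFY = FALSE)
  reg <- sgluca_auc_regression(idx)
  expect_gt(reg$slope, -0.75)
  expect_lt(reg$slope, -0.45)
  expect_lt(reg$p, 1e-6)
})

test_that("duration sensitivity picks the right paired test", {
  # identical windows: all-zero differences, degenerate, p = 1
  idx_same <- lapply(1:10, function(i) make_indices(i))
  tab <- duration_sensitivity(idx_same)
  expect_identical(tab$p, c(1, 1))
  expect_true(all(tab$degenerate))

  # a large constant shift (plus normal noise) is detected by either test
  set.seed(5)
  base <- rnorm(30, 2, 0.3)
  idx_shift <- mapply(function(f, w) make_indices(f, mean_3h = w,
                                                  mean_2h = w),
                      base + 3, base, SIMPLIFY = FALSE)
  tab_s <- duration_sensitivity(idx_shift)
  expect_true(all(tab_s$p < 0.001))

  # minimal input runs
  expect_s3_class(duration_sensitivity(lapply(c(1, 2, 3.5), make_indices)),
                  "data.frame")
})

test_that("flipping a window pair flips the t statistic but not p", {
  set.seed(6)
  base <- rnorm(20, 2, 0.5)
  d <- rnorm(20, 0.4, 0.2)
  fwd <- mapply(function(f, w) make_indices(f, mean_3h = w, mean_2h = w),
                base + d, base, SIMPLIFY = FALSE)
  rev <- mapply(function(f, w) make_indices(f, mean_3h = w, mean_2h = w),
                base, base + d, SIMPLIFY = FALSE)
  tf <- duration_sensitivity(fwd)
  tr <- duration_sensitivity(rev)
  expect_equal(tf$p, tr$p, tolerance = 1e-12)
  if (tf$test[1] == "paired t" && tr$test[1] == "paired t") {
    expect_equal(tf$statistic[1], -tr$statistic[1], tolerance = 1e-12)
  }
})

test_that("normality check calibrates on normal and skewed samples", {
  set.seed(11)
  reject_norm <- mean(vapply(1:100, function(i) {
    !ks_normality(rnorm(500))$is_normal_at_5pct
  }, logical(1)))
  expect_lte(reject_norm, 0.10)

  reject_lnorm <- mean(vapply(1:100, function(i) {
    # lognormal with CV 1: sdlog = sqrt(log(2))
    !ks_normality(rlnorm(500, 0, sqrt(log(2))))$is_normal_at_5pct
  }, logical(1)))
  expect_gte(reject_lnorm, 0.95)

  expect_true(ks_normality(rep(3, 10))$degenerate)
  expect_error(ks_normality(c(1, 2)), "at least 3")
})
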