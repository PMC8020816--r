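test_that("cost decomposition matches hand-computed penalty terms", {
  # a perfect noise-free fit with K = 0 and constant non-negative S
  sub <- make_truth_subject(rep(2, 11), k_gluca = 0)
  ct <- cost_terms(sub$series, sub$truth, reg_weights(0.5, 2))
  expect_equal(ct$rss, 0, tolerance = 1e-18)
  expect_identical(ct$term_k, 0)
  expect_identical(ct$term_smooth, 0)
  expect_identical(ct$term_neg, 0)
  expect_equal(ct$total, 0, tolerance = 1e-18)

  # one interior knot: second difference (4 - 2*2 + 1) = 1, times w1 = 0.5
  s3 <- ogtt_series(c(0, 30, 60), c(70, 60, 55), c(0.5, 1.5, 2.0))
  ct3 <- cost_terms(s3, model_params(0, 0.1, c(1, 2, 4)), reg_weights(0.5, 0))
  expect_equal(ct3$term_smooth, 0.5)

  # flipping one knot negative adds exactly w2 to the negativity term
  ct_neg <- cost_terms(s3, model_params(0, 0.1, c(1, -2, 4)),
                       reg_weights(0, 2))
  expect_identical(ct_neg$term_neg, 2)
})

test_that("total cost always equals the sum of its four terms", {
  s <- ogtt_series(t2_times, c(70, 55, 45, 48, 52), t2_cp)
  set.seed(8)
  for (i in 1:20) {
    p <- model_params(runif(1), runif(1), runif(5, -3, 3))
    w <- reg_weights(10^runif(1, -3, 2), 10^runif(1, -3, 2))
    ct <- cost_terms(s, p, w)
    expect_identical(ct$total, ct$rss + ct$term_k + ct$term_smooth +
                       ct$term_neg)
  }
})

test_that("mean relative residual follows its definition", {
  s <- ogtt_series(c(0, 30, 60), c(50, 40, 30), c(0.5, 1.5, 2.0))
  fit <- fake_fit(residuals = c(5, -4, -3))
  expect_equal(mean_residual_pct(s, fit), 10.0)

  expect_equal(mean_residual_pct(s, fake_fit(residuals = c(0, 0, 0))), 0)
  expect_equal(mean_residual_pct(s, fake_fit(residuals = c(50, 40, 30))), 100)

  s0 <- ogtt_series(c(0, 30, 60), c(50, 0, 30), c(0.5, 1.5, 2.0))
  expect_warning(v <- mean_residual_pct(s0, fake_fit(residuals = c(5, 1, -3))),
                 "zero observed glucagon")
  expect_equal(v, 100 * mean(c(5 / 50, 3 / 30)))
})

test_that("noise-free data round-trip through the estimator", {
  sub <- make_truth_subject(rep(2, 5), times = t2_times, cp = t2_cp)
  fit <- fit_subject(sub$series, n_starts = 12, seed = 3)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params$s_gluca - 2)) / 2, 0.05)
  expect_lt(abs(fit$params$k_dcprem - 0.155) / 0.155, 0.05)
  expect_lt(fit$rss, 1e-4)
  # CI bounds bracket every estimate
  est <- c(fit$params$k_gluca, fit$params$k_dcprem, fit$params$s_gluca)
  expect_true(all(fit$ci_low <= est + 1e-12 & est <= fit$ci_high + 1e-12))
})

test_that("rate estimates always respect the [0, 1] box", {
  set.seed(21)
  for (i in 1:3) {
    sub <- make_truth_subject(runif(5, -1, 3), times = t2_times, cp = t2_cp,
                              noise_cv = 0.1, seed = 40 + i)
    fit <- fit_subject(sub$series, n_starts = 3, seed = i, compute_ci = FALSE)
    expect_gte(fit$params$k_gluca, 0)
    expect_lte(fit$params$k_gluca, 1)
    expect_gte(fit$params$k_dcprem, 0)
    expect_lte(fit$params$k_dcprem, 1)
  }
})

test_that("multistart selection is stable across seeds", {
  sub <- make_truth_subject(rep(2, 5), times = t2_times, cp = t2_cp)
  f1 <- fit_subject(sub$series, n_starts = 10, seed = 1, compute_ci = FALSE)
  f2 <- fit_subject(sub$series, n_starts = 10, seed = 99, compute_ci = FALSE)
  expect_lt(abs(f1$cost_terms$total - f2$cost_terms$total), 1e-6)
  expect_equal(nrow(f1$multistart_log), 10)
})

test_that("degenerate flat input yields a near-zero-residual fit", {
  flat <- ogtt_series(t2_times, rep(65, 5), rep(0.8, 5))
  fit <- fit_subject(flat, n_starts = 3, seed = 2, compute_ci = FALSE)
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-6)
  # with no signal the cost is carried by the regularization terms
  expect_gte(fit$cost_terms$total - fit$rss, 0)
})

test_that("raising the smoothness weight never roughens the optimum", {
  sub <- make_truth_subject(c(2.5, 1.5, 0.8, 0.6, 0.9),
                            times = t2_times, cp = t2_cp)
  rough <- vapply(c(0.01, 1, 100), function(w1) {
    fit <- fit_subject(sub$series, weights = reg_weights(w1, 1),
                       n_starts = 4, seed = 5, compute_ci = FALSE)
    sum(diff(fit$params$s_gluca, differences = 2)^2)
  }, numeric(1))
  expect_true(all(diff(rough) <= 1e-8))
})

test_that("the CI core reproduces the textbook OLS interval", {
  # scalar linear model y = theta x through the same code path
  set.seed(12)
  x <- runif(20, 1, 3)
  y <- 1.7 * x + rnorm(20, 0, 0.3)
  theta_hat <- sum(x * y) / sum(x * x)
  ci <- glucakin:::.ci_from_fn(function(th) th * x - y, theta_hat)
  s2 <- sum((theta_hat * x - y)^2) / (20 - 1)
  half <- qt(0.975, 19) * sqrt(s2 / sum(x * x))
  expect_equal(ci$ci_low, theta_hat - half, tolerance = 1e-5)
  expect_equal(ci$ci_high, theta_hat + half, tolerance = 1e-5)
})

test_that("an exact solution gives (near-)zero-width intervals", {
  sub <- make_truth_subject(rep(2, 11), k_gluca = 0)
  fit <- fake_fit(params = sub$truth, weights = reg_weights(0.1, 1))
  ci <- confidence_intervals(sub$series, fit, step = 1)
  expect_lt(max(ci$ci_high - ci$ci_low), 1e-10)
})

test_that("weight selection honours threshold and tie rules", {
  sub <- make_truth_subject(rep(2, 5), times = t2_times, cp = t2_cp)

  sel <- select_weights(sub$series, n_candidates_per_weight = 2, seed = 4,
                        n_starts = 3)
  expect_s3_class(sel$weights, "reg_weights")
  expect_equal(nrow(sel$table), 4)
  expect_lt(min(sel$table$mean_residual_pct[sel$table$acceptable]), 10)

  # disabled filter returns the global minimiser of the mean residual
  sel_inf <- select_weights(sub$series, n_candidates_per_weight = 2, seed = 4,
                            threshold_pct = Inf, n_starts = 3)
  best <- which.min(sel_inf$table$mean_residual_pct)
  expect_identical(sel_inf$weights$w1, sel_inf$table$w1[best])
  expect_identical(sel_inf$weights$w2, sel_inf$table$w2[best])

  # an unattainable threshold fails with the table attached
  err <- tryCatch(
    select_weights(sub$series, n_candidates_per_weight = 1, seed = 4,
                   threshold_pct = 1e-9, n_starts = 2),
    glucakin_weight_selection_error = function(e) e)
  expect_s3_class(err, "glucakin_weight_selection_error")
  expect_s3_class(err$table, "data.frame")
})
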