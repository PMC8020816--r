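test_that("input interpolation is linear and keeps sample times on the grid", {
  s <- ogtt_series(c(0, 10, 20), c(60, 60, 60), c(0.5, 0.7, 0.7))
  g <- interpolate_input(s, step = 5)
  expect_equal(g$times, c(0, 5, 10, 15, 20))
  expect_equal(g$cp_suprabasal, c(0, 0.1, 0.2, 0.2, 0.2))

  flat <- ogtt_series(t5_times, rep(60, 11), rep(0.9, 11))
  expect_true(all(interpolate_input(flat, 1)$cp_suprabasal == 0))

  s5 <- ogtt_series(t5_times, rep(60, 11), t5_cp)
  g5 <- interpolate_input(s5, step = 1)
  expect_length(g5$times, 301)
  expect_true(all(t5_times %in% g5$times))
})

test_that("remote compartment solves the linear delay ODE", {
  # constant suprabasal input A: closed form (A/K) (1 - exp(-K t))
  s <- constant_input_series(A = 0.31)
  rc <- remote_cpeptide(s, k_dcprem = 0.155, step = 1)
  got <- rc$dcp_remote[which(abs(rc$times - 20) < 1e-9)]
  expect_equal(got, (0.31 / 0.155) * (1 - exp(-0.155 * 20)), tolerance = 1e-5)

  # zero input stays zero
  flat <- ogtt_series(t5_times, rep(60, 11), rep(0.9, 11))
  expect_true(all(remote_cpeptide(flat, 0.155, 1)$dcp_remote == 0))

  # K = 0 is a pure integrator: constant input A gives A * t
  rc0 <- remote_cpeptide(s, k_dcprem = 0, step = 1)
  got0 <- rc0$dcp_remote[which(abs(rc0$times - 20) < 1e-9)]
  expect_equal(got0, 0.31 * 20, tolerance = 1e-5)

  expect_error(remote_cpeptide(s, k_dcprem = -0.1), "non-negative")
})

test_that("remote compartment response is linear in its input", {
  base <- ogtt_series(t5_times, rep(60, 11), t5_cp)
  doubled <- ogtt_series(t5_times, rep(60, 11),
                         t5_cp[1] + 2 * (t5_cp - t5_cp[1]))
  x1 <- remote_cpeptide(base, 0.155, 1)$dcp_remote
  x2 <- remote_cpeptide(doubled, 0.155, 1)$dcp_remote
  expect_equal(x2, 2 * x1, tolerance = 1e-12)
})

test_that("glucagon simulation matches the analytic limit cases", {
  s <- ogtt_series(t5_times, rep(60, 11), t5_cp)

  # no elimination, no coupling: glucagon constant at basal
  tr0 <- simulate_glucagon(s, model_params(0, 0.155, rep(0, 11)), 1)
  expect_true(all(tr0$gluca == 60))

  # pure exponential elimination
  tr1 <- simulate_glucagon(s, model_params(0.005, 0.155, rep(0, 11)), 1)
  expect_equal(sample_at(tr1, 100), 60 * exp(-0.5), tolerance = 1e-12)

  # no elimination, constant sensitivity: Gluca = Gluca_b - S * dCP_remote
  trS <- simulate_glucagon(s, model_params(0, 0.155, rep(2, 11)), 1)
  expect_equal(trS$gluca, 60 - 2 * trS$dcp_remote, tolerance = 1e-12)
})

test_that("every trajectory starts at (gluca_b, 0) exactly", {
  s <- ogtt_series(t2_times, c(70, 55, 45, 48, 52), t2_cp)
  for (seed in 1:5) {
    set.seed(seed)
    p <- model_params(runif(1), runif(1), runif(5, -2, 3))
    tr <- suppressWarnings(simulate_glucagon(s, p, 1))
    expect_identical(tr$gluca[1], 70)
    expect_identical(tr$dcp_remote[1], 0)
  }
})

test_that("discrete propagation agrees with adaptive integration", {
  s <- ogtt_series(t5_times, rep(70, 11), t5_cp)
  set.seed(4)
  for (i in 1:5) {
    p <- model_params(runif(1), runif(1), runif(11, -2, 3))
    d <- suppressWarnings(simulate_glucagon(s, p, 1, method = "discrete"))
    o <- suppressWarnings(simulate_glucagon(s, p, 1, method = "ode"))
    gd <- sample_at(d, t5_times)
    go <- sample_at(o, t5_times)
    expect_lt(max(abs(gd - go) / abs(go)), 1e-3)
    expect_lt(max(abs(d$dcp_remote - o$dcp_remote)), 1e-6)
  }
})

test_that("sample_at reads grid points and rejects off-grid times", {
  s <- ogtt_series(t5_times, rep(60, 11), t5_cp)
  tr <- simulate_glucagon(s, model_params(0.01, 0.155, rep(1, 11)), 1)

  expect_identical(sample_at(tr, tr$grid_times), tr$gluca)
  expect_identical(sample_at(tr, 0), 60)

  # index arithmetic on the 1-min grid: sample i sits at position t_i + 1
  expect_identical(sample_at(tr, t5_times), tr$gluca[t5_times + 1])
  expect_error(sample_at(tr, 10.5), "not on the trajectory grid")
})

test_that("negative simulated glucagon is permitted but warned about", {
  s <- ogtt_series(t5_times, rep(20, 11), t5_cp)
  expect_warning(simulate_glucagon(s, model_params(0, 0.155, rep(15, 11)), 1),
                 "negative")
})
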