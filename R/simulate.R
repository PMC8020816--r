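# ---- internal grid / input machinery --------------------------------------

# Fine simulation grid: each inter-sample interval is subdivided with the
# requested step; a final partial step inside an interval is truncated to the
# interval's right endpoint, so every sampling time is a grid point exactly.
.sim_grid <- function(times, step) {
  if (!is.finite(step) || step <= 0) {
    stop("step must be a positive number of minutes", call. = FALSE)
  }
  pieces <- lapply(seq_len(length(times) - 1L), function(i) {
    g <- seq(times[i], times[i + 1L], by = step)
    if (g[length(g)] < times[i + 1L] - 1e-9) g <- c(g, times[i + 1L])
    g[-length(g)]
  })
  c(unlist(pieces), times[length(times)])
}

# Precompute everything about a (series, step) pair that does not depend on
# the parameters: grid, per-step widths, linear-input coefficients of the
# suprabasal C-peptide (u(s) = a + b*s within a step) and the sample-interval
# index of each step. This is the hot-path setup shared by all solver calls.
.sim_pre <- function(series, step) {
  g <- .sim_grid(series$times, step)
  n_grid <- length(g)
  h <- diff(g)
  uniform <- (max(h) - min(h)) < 1e-12
  u <- stats::approx(series$times, series$cpeptide - series$cp_b,
                     xout = g, method = "linear")$y
  a <- u[-n_grid]
  b <- (u[-1L] - a) / h
  s_idx <- findInterval(g[-n_grid], series$times)
  sample_idx <- vapply(series$times, function(t) {
    j <- which(abs(g - t) < 1e-8)
    if (length(j) != 1L) stop("internal: sample time off grid", call. = FALSE)
    j
  }, integer(1))
  list(grid = g, h = h, uniform = uniform, a = a, b = b,
       s_idx = s_idx, sample_idx = sample_idx, n_steps = n_grid - 1L,
       gluca_b = series$gluca_b)
}

# (1 - exp(-k h)) / k with a series expansion for k*h -> 0
.c1_coef <- function(k, h) {
  kh <- k * h
  ifelse(kh < 1e-8, h * (1 - kh / 2), (1 - exp(-kh)) / k)
}

# h/k - (1 - exp(-k h))/k^2  ==  (k h - 1 + exp(-k h))/k^2, small-k safe
.c2_coef <- function(k, h) {
  kh <- k * h
  ifelse(kh < 1e-8, h^2 / 2 * (1 - kh / 3), (kh - 1 + exp(-kh)) / k^2)
}

# y[j+1] = e[j] * y[j] + d[j], y[1] = y0; e scalar => C-level filter()
.propagate <- function(d, e, y0 = 0) {
  n <- length(d)
  if (length(e) == 1L) {
    forced <- as.numeric(stats::filter(d, e, method = "recursive"))
    c(y0, y0 * exp(log(e) * seq_len(n)) + forced)
  } else {
    y <- numeric(n + 1L)
    y[1L] <- y0
    for (j in seq_len(n)) y[j + 1L] <- e[j] * y[j] + d[j]
    y
  }
}

# Remote-compartment suprabasal C-peptide on the grid, exact per step for the
# piecewise-linear plasma input:  x' = -k x + u(t), x(0) = 0.
.remote_cp_grid <- function(pre, k) {
  e <- exp(-k * pre$h)
  d <- pre$a * .c1_coef(k, pre$h) + pre$b * .c2_coef(k, pre$h)
  if (pre$uniform) .propagate(d, e[1L]) else .propagate(d, e)
}

# Glucagon on the grid given x (remote C-peptide on the grid):
#   G' = -K G - S(t) x'(t),  G(0) = gluca_b,
# propagated exactly per step using the in-step closed form of x.
.gluca_grid <- function(pre, x, k, K, s_gluca) {
  h <- pre$h
  n <- pre$n_steps
  xl <- x[seq_len(n)]
  c1K <- .c1_coef(K, h)
  if (k * max(h) < 1e-8) {
    # integrator limit: x'(s) ~ -k x_j + a + b s within the step
    I <- (pre$a - k * xl) * c1K + pre$b * .c2_coef(K, h)
  } else {
    alpha <- (pre$a - pre$b / k) / k
    beta <- pre$b / k
    c1 <- xl - alpha
    dk <- K - k
    E <- ifelse(abs(dk) * h < 1e-8,
                h * exp(-k * h) * (1 - dk * h / 2),
                (exp(-k * h) - exp(-K * h)) / dk)
    I <- -k * c1 * E + beta * c1K
  }
  d <- -s_gluca[pre$s_idx] * I
  eK <- exp(-K * h)
  if (pre$uniform) .propagate(d, eK[1L], y0 = pre$gluca_b)
  else .propagate(d, eK, y0 = pre$gluca_b)
}

# ---- exported operations ---------------------------------------------------

#' Interpolate the suprabasal C-peptide input onto a fine grid
#'
#' Builds the uniform simulation grid (step minutes; a final partial step in
#' any inter-sample interval is truncated to the sample time, so every
#' original sampling time is a grid point) and linearly interpolates the
#' suprabasal plasma C-peptide `cpeptide - cp_b` onto it.
#'
#' @param series An [ogtt_series()].
#' @param step Grid step in minutes (default 1).
#' @return A list with `times` (the grid) and `cp_suprabasal` (nmol/L).
#' @export
interpolate_input <- function(series, step = 1) {
  stopifnot(inherits(series, "ogtt_series"))
  g <- .sim_grid(series$times, step)
  list(times = g,
       cp_suprabasal = stats::approx(series$times,
                                     series$cpeptide - series$cp_b,
                                     xout = g, method = "linear")$y)
}

#' Suprabasal C-peptide in the remote compartment
#'
#' Solves the delay compartment
#' \deqn{d\Delta CP_{remote}/dt = -K_{\Delta CPREM} \cdot \Delta CP_{remote}
#'   + (CP_{plasma}(t) - Cp_b), \quad \Delta CP_{remote}(0) = 0}
#' on the fine grid, with the plasma input linearly interpolated between
#' samples. The propagation is exact per grid step for this piecewise-linear
#' input (scalar matrix-exponential update), so the result matches an
#' adaptive high-accuracy integration to solver tolerance.
#'
#' @param series An [ogtt_series()].
#' @param k_dcprem Elimination rate from the remote compartment (1/min),
#'   `>= 0`. With `k_dcprem = 0` the compartment is a pure integrator.
#' @param step Grid step in minutes (default 1).
#' @return A list with `times` (grid) and `dcp_remote` (nmol/L).
#' @export
remote_cpeptide <- function(series, k_dcprem, step = 1) {
  stopifnot(inherits(series, "ogtt_series"))
  if (!is.finite(k_dcprem) || k_dcprem < 0) {
    stop("k_dcprem must be a finite non-negative rate", call. = FALSE)
  }
  pre <- .sim_pre(series, step)
  list(times = pre$grid, dcp_remote = .remote_cp_grid(pre, k_dcprem))
}

#' Simulate plasma glucagon during an OGTT
#'
#' Simulates the two-compartment glucagon kinetics model
#' \deqn{dGluca/dt = -K_{GLUCA} \cdot Gluca
#'   - S_{GLUCA}(t) \cdot d\Delta CP_{remote}/dt, \quad Gluca(0) = Gluca_b}
#' with the remote C-peptide compartment of [remote_cpeptide()] as the
#' driving signal and `s_gluca` piecewise constant between consecutive
#' sampling times (knot `i` holds on `[times[i], times[i+1])`).
#'
#' @param series An [ogtt_series()] supplying the C-peptide input, basal
#'   glucagon and the sampling schedule.
#' @param params A [model_params()] object whose `s_gluca` has one knot per
#'   sampling time of `series`.
#' @param step Grid step in minutes (default 1).
#' @param method `"discrete"` (default) for the exact per-step discrete-time
#'   propagation, or `"ode"` for an independent adaptive integration with
#'   [deSolve::lsoda()] (rtol 1e-10), used as a cross-check of the discrete
#'   solver.
#' @return An object of class `gluca_trajectory`: list with `grid_times`,
#'   `gluca` (ng/L) and `dcp_remote` (nmol/L). Simulated glucagon may go
#'   negative (the model is linear); a warning is emitted if it does.
#' @examples
#' s <- ogtt_series(c(0, 30, 60, 90, 120), c(70, 55, 45, 48, 52),
#'                  c(0.5, 1.6, 2.2, 2.3, 2.1))
#' tr <- simulate_glucagon(s, model_params(0.005, 0.155, rep(2, 5)))
#' head(tr$gluca)
#' @export
simulate_glucagon <- function(series, params, step = 1,
                              method = c("discrete", "ode")) {
  stopifnot(inherits(series, "ogtt_series"), inherits(params, "gluca_params"))
  method <- match.arg(method)
  .check_params_series(params, series)
  pre <- .sim_pre(series, step)
  if (method == "discrete") {
    x <- .remote_cp_grid(pre, params$k_dcprem)
    g <- .gluca_grid(pre, x, params$k_dcprem, params$k_gluca, params$s_gluca)
  } else {
    sol <- .ode_solve(series, params, pre)
    x <- sol$x
    g <- sol$g
  }
  if (any(g < 0)) {
    warning("simulated glucagon goes negative (model is linear; ",
            "concentrations are physically non-negative)", call. = FALSE)
  }
  structure(list(grid_times = pre$grid, gluca = g, dcp_remote = x),
            class = "gluca_trajectory")
}

# Adaptive-integration route: lsoda restarted at each sampling time so the
# piecewise-constant s_gluca and the kinks of the linear input never sit
# inside an integration span.
.ode_solve <- function(series, params, pre) {
  ufun <- stats::approxfun(series$times, series$cpeptide - series$cp_b,
                           method = "linear", rule = 2)
  x <- numeric(length(pre$grid))
  g <- numeric(length(pre$grid))
  x[1] <- 0
  g[1] <- series$gluca_b
  k <- params$k_dcprem
  K <- params$k_gluca
  for (i in seq_len(length(series$times) - 1L)) {
    s_i <- params$s_gluca[i]
    rhs <- function(t, y, parms) {
      dx <- -k * y[1] + ufun(t)
      list(c(dx, -K * y[2] - s_i * dx))
    }
    j0 <- pre$sample_idx[i]
    j1 <- pre$sample_idx[i + 1L]
    tt <- pre$grid[j0:j1]
    out <- deSolve::lsoda(y = c(x[j0], g[j0]), times = tt, func = rhs,
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
    x[j0:j1] <- out[, 2]
    g[j0:j1] <- out[, 3]
  }
  list(x = x, g = g)
}

#' @export
print.gluca_trajectory <- function(x, ...) {
  n <- length(x$grid_times)
  cat(sprintf("glucagon trajectory: %d grid points, %g-%g min\n",
              n, x$grid_times[1], x$grid_times[n]))
  cat(sprintf("  glucagon %.4g -> %.4g ng/L (min %.4g), remote C-peptide peak %.4g nmol/L\n",
              x$gluca[1], x$gluca[n], min(x$gluca), max(x$dcp_remote)))
  invisible(x)
}

#' Read trajectory values at requested times
#'
#' Extracts simulated values at times that must lie on the trajectory grid
#' (typically the OGTT sampling times, for residual computation).
#'
#' @param traj A `gluca_trajectory` from [simulate_glucagon()].
#' @param times Times (minutes) to read; each must be a grid point.
#' @param what `"gluca"` (default) or `"dcp_remote"`.
#' @return Numeric vector of trajectory values at `times`.
#' @export
sample_at <- function(traj, times, what = c("gluca", "dcp_remote")) {
  stopifnot(inherits(traj, "gluca_trajectory"))
  what <- match.arg(what)
  idx <- vapply(times, function(t) {
    j <- which(abs(traj$grid_times - t) < 1e-8)
    if (length(j) != 1L) {
      stop("requested time ", t, " min is not on the trajectory grid",
           call. = FALSE)
    }
    j
  }, integer(1))
  traj[[what]][idx]
}

#' Write a simulated trajectory to CSV
#'
#' @param traj A `gluca_trajectory`.
#' @param path Output file path (columns
#'   `time_min,gluca_ng_L,dcp_remote_nmol_L`).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "gluca_trajectory"))
  utils::write.csv(data.frame(time_min = traj$grid_times,
                              gluca_ng_L = traj$gluca,
                              dcp_remote_nmol_L = traj$dcp_remote),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
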