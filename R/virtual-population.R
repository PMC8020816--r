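#' Population template for virtual-subject generation
#'
#' Per-time-point mean and SD curves of glucagon and C-peptide from which
#' virtual OGTT subjects are drawn.
#'
#' @param times Sampling times (minutes), strictly increasing, first 0.
#' @param gluca_mean,gluca_sd Mean and SD of plasma glucagon (ng/L) per
#'   time; SDs `>= 0`.
#' @param cp_mean,cp_sd Mean and SD of plasma C-peptide (nmol/L) per time;
#'   SDs `>= 0`.
#' @return An object of class `population_template`.
#' @export
population_template <- function(times, gluca_mean, gluca_sd,
                                cp_mean, cp_sd) {
  n <- length(times)
  lens <- c(length(gluca_mean), length(gluca_sd),
            length(cp_mean), length(cp_sd))
  if (any(lens != n)) {
    stop("template curves must all have the length of times", call. = FALSE)
  }
  if (n < 3L || any(diff(times) <= 0) || times[1] != 0) {
    stop("times must be strictly increasing from 0 with >= 3 points",
         call. = FALSE)
  }
  if (any(gluca_sd < 0) || any(cp_sd < 0)) {
    stop("template SDs must be non-negative", call. = FALSE)
  }
  structure(list(times = as.numeric(times),
                 gluca_mean = as.numeric(gluca_mean),
                 gluca_sd = as.numeric(gluca_sd),
                 cp_mean = as.numeric(cp_mean),
                 cp_sd = as.numeric(cp_sd)),
            class = "population_template")
}

#' @export
print.population_template <- function(x, ...) {
  cat(sprintf("OGTT population template: %d time points, %g-%g min\n",
              length(x$times), min(x$times), max(x$times)))
  print(data.frame(time_min = x$times,
                   gluca_mean = x$gluca_mean, gluca_sd = x$gluca_sd,
                   cp_mean = x$cp_mean, cp_sd = x$cp_sd),
        row.names = FALSE, ...)
  invisible(x)
}

#' Packaged synthetic OGTT templates
#'
#' Returns one of the package's built-in templates: an 11-sample 5-hour
#' OGTT (samples at 0, 10, 20, 30, 60, 90, 120, 150, 180, 240, 300 min)
#' with the canonical glucagon suppression-then-recovery and C-peptide
#' rise-then-decay shapes, or one of four 5-sample 2-hour OGTT archetypes
#' (samples at 0, 30, 60, 90, 120 min) representing commonly reported
#' clusters of glucagon-curve shapes: 1 high fasting glucagon with delayed
#' suppression, 2 high fasting with rapid suppression, 3 low fasting with
#' rapid suppression, 4 low fasting with a curve rising after glucose
#' ingestion.
#'
#' These values are synthetic package fixtures shaped after the qualitative
#' patterns described in the clinical literature; they are not measured
#' data from any published cohort.
#'
#' @param kind One of `"fivehour"`, `"twohour-cluster1"` ...
#'   `"twohour-cluster4"`.
#' @return A [population_template()].
#' @examples
#' default_template("fivehour")$times
#' @export
default_template <- function(kind = c("fivehour", "twohour-cluster1",
                                      "twohour-cluster2", "twohour-cluster3",
                                      "twohour-cluster4")) {
  kind <- match.arg(kind)
  t5 <- c(0, 10, 20, 30, 60, 90, 120, 150, 180, 240, 300)
  t2 <- c(0, 30, 60, 90, 120)
  switch(kind,
    "fivehour" = population_template(
      times = t5,
      gluca_mean = c(70, 66, 60, 54, 44, 40, 38, 40, 44, 52, 62),
      gluca_sd   = c(8, 7.5, 7, 6.5, 5.5, 5, 5, 5, 5.5, 6.5, 7.5),
      cp_mean = c(0.50, 0.80, 1.30, 1.80, 2.40, 2.60, 2.50, 2.20, 1.90,
                  1.30, 0.80),
      cp_sd   = c(0.08, 0.12, 0.18, 0.22, 0.28, 0.30, 0.28, 0.25, 0.22,
                  0.18, 0.12)),
    "twohour-cluster1" = population_template(
      times = t2,
      gluca_mean = c(85, 82, 72, 62, 56),
      gluca_sd   = c(8, 8, 7, 6, 6),
      cp_mean = c(0.60, 1.40, 2.10, 2.40, 2.30),
      cp_sd   = c(0.08, 0.18, 0.25, 0.28, 0.26)),
    "twohour-cluster2" = population_template(
      times = t2,
      gluca_mean = c(85, 60, 50, 47, 46),
      gluca_sd   = c(8, 6.5, 5.5, 5, 5),
      cp_mean = c(0.60, 1.80, 2.40, 2.40, 2.20),
      cp_sd   = c(0.08, 0.20, 0.28, 0.28, 0.25)),
    "twohour-cluster3" = population_template(
      times = t2,
      gluca_mean = c(55, 38, 39, 41, 43),
      gluca_sd   = c(6, 4.5, 4.5, 4.5, 5),
      cp_mean = c(0.50, 1.60, 2.20, 2.30, 2.20),
      cp_sd   = c(0.07, 0.18, 0.25, 0.26, 0.24)),
    "twohour-cluster4" = population_template(
      times = t2,
      gluca_mean = c(50, 53, 57, 60, 62),
      gluca_sd   = c(6, 6, 6, 6.5, 6.5),
      cp_mean = c(0.40, 0.90, 1.30, 1.50, 1.55),
      cp_sd   = c(0.06, 0.12, 0.16, 0.18, 0.18))
  )
}

# Draw one curve under the truncation + derivative-sign constraints.
# Each point is drawn from Normal(mean, sd) restricted to
# [max(0, mean - 1.96 sd), mean + 1.96 sd]; a point whose difference from
# the previous point disagrees in sign with the template difference is
# redrawn; a stuck point triggers a whole-curve restart. `budget` counts
# every draw; exhausting it is a generation failure.
.draw_curve <- function(mean, sd, budget_env, point_cap = 1000L) {
  n <- length(mean)
  lo <- pmax(0, mean - 1.96 * sd)
  hi <- mean + 1.96 * sd
  dsign <- sign(diff(mean))
  repeat {
    y <- numeric(n)
    ok <- TRUE
    for (i in seq_len(n)) {
      tries <- 0L
      repeat {
        budget_env$draws <- budget_env$draws + 1L
        if (budget_env$draws > budget_env$max_draws) {
          cond <- structure(
            class = c("glucakin_generation_error", "error", "condition"),
            list(message = paste("virtual-subject constraints unsatisfied",
                                 "after", budget_env$max_draws, "draws"),
                 call = NULL))
          stop(cond)
        }
        tries <- tries + 1L
        v <- stats::rnorm(1, mean[i], sd[i])
        if (sd[i] == 0) v <- mean[i]
        inside <- v >= lo[i] && v <= hi[i]
        sign_ok <- i == 1L || dsign[i - 1L] == 0 ||
          sign(v - y[i - 1L]) %in% c(0, dsign[i - 1L])
        if (inside && sign_ok) break
        if (tries >= point_cap) { ok <- FALSE; break }
      }
      if (!ok) break
      y[i] <- v
    }
    if (ok) return(y)
  }
}

#' Generate one virtual OGTT subject
#'
#' Draws a plausible subject from a [population_template()]: each
#' concentration comes from a normal distribution with the template's mean
#' and SD, truncated to the 95% band `mean +/- 1.96 SD` (and to
#' non-negative values), and the sign of every consecutive difference must
#' match that of the template mean curve (flat template segments allow
#' either sign). Glucagon and C-peptide curves are constrained
#' independently. Sampling is by rejection; if the constraints are not
#' satisfied within 1e4 draws an error of class
#' `glucakin_generation_error` is thrown.
#'
#' @param template A [population_template()].
#' @param seed Integer seed.
#' @param id Optional subject identifier.
#' @return An [ogtt_series()].
#' @export
generate_virtual_subject <- function(template, seed = 1, id = NULL) {
  stopifnot(inherits(template, "population_template"))
  set.seed(seed)
  budget <- new.env()
  budget$draws <- 0L
  budget$max_draws <- 10000L
  gluca <- .draw_curve(template$gluca_mean, template$gluca_sd, budget)
  cp <- .draw_curve(template$cp_mean, template$cp_sd, budget)
  ogtt_series(template$times, gluca, cp, id = id)
}

#' Generate a virtual population
#'
#' Draws `n` independent virtual subjects from a template; per-subject
#' seeds are derived deterministically from the root seed, so the whole
#' population is reproducible.
#'
#' @param template A [population_template()].
#' @param n Number of subjects (`>= 1`).
#' @param seed Integer root seed.
#' @return A list of `n` [ogtt_series()] objects with ids `"vs001"`, ...
#' @export
generate_population <- function(template, n = 100, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    generate_virtual_subject(template, seed = sub_seeds[i],
                             id = sprintf("vs%03d", i))
  })
}

#' Synthesize a ground-truth subject from known parameters
#'
#' Simulates glucagon from known model parameters and a C-peptide curve,
#' samples the trajectory at the OGTT times, and perturbs the sampled
#' glucagon with multiplicative Gaussian noise of coefficient of variation
#' `noise_cv` (floored at zero). Used for estimator validation, where the
#' generating parameters are known exactly.
#'
#' @param true_params A [model_params()] (one `s_gluca` knot per time).
#' @param times Sampling times (minutes), first 0.
#' @param cpeptide Plasma C-peptide (nmol/L) at `times`.
#' @param gluca_b Basal glucagon (ng/L).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (`>= 0`; 0 gives the noise-free samples).
#' @param seed Integer seed for the noise draws.
#' @param step Simulation grid step in minutes (default 1).
#' @return A list with `series` (the noisy [ogtt_series()]) and
#'   `trajectory` (the noise-free `gluca_trajectory`).
#' @export
synthesize_from_truth <- function(true_params, times, cpeptide, gluca_b,
                                  noise_cv = 0.05, seed = 1, step = 1) {
  stopifnot(inherits(true_params, "gluca_params"))
  if (!is.finite(noise_cv) || noise_cv < 0) {
    stop("noise_cv must be a finite non-negative fraction", call. = FALSE)
  }
  scaffold <- ogtt_series(times, rep(gluca_b, length(times)), cpeptide)
  traj <- suppressWarnings(
    simulate_glucagon(scaffold, true_params, step = step))
  g_true <- sample_at(traj, times)
  set.seed(seed)
  g_noisy <- g_true * (1 + stats::rnorm(length(g_true), 0, noise_cv))
  g_noisy <- pmax(g_noisy, 0)
  list(series = ogtt_series(times, g_noisy, cpeptide),
       trajectory = traj)
}
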