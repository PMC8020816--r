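#' Composite trapezoidal area under a curve
#'
#' @param times Strictly increasing times (minutes), length `>= 2`.
#' @param values Curve values, same length as `times`.
#' @return The composite trapezoidal integral.
#' @examples
#' auc_trapezoid(c(0, 10, 30), c(1, 3, 2)) # 70
#' @export
auc_trapezoid <- function(times, values) {
  if (length(times) < 2L || length(times) != length(values)) {
    stop("times and values must have equal length >= 2", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  sum(diff(times) * (values[-length(values)] + values[-1]) / 2)
}

#' Per-subject derived indices
#'
#' Computes the quantities summarizing one fitted subject: the arithmetic
#' mean of the `s_gluca` knots over the full test and restricted to the
#' first 3 h (knots with time <= 180 min) and 2 h (<= 120 min) windows; the
#' area under the suprabasal remote C-peptide curve (simulated on the fine
#' grid with the fitted `k_dcprem`); and the area of observed glucagon
#' below the basal level, i.e. the trapezoidal integral of
#' `max(gluca_b - glucagon_obs, 0)` over the sampling times.
#'
#' @param series The fitted [ogtt_series()].
#' @param fit The subject's `gluca_fit` from [fit_subject()].
#' @param step Simulation grid step in minutes (default: the fit's step).
#' @return A list of class `gluca_indices` with `mean_sgluca_full`,
#'   `mean_sgluca_3h`, `mean_sgluca_2h`, `auc_dcp_remote`
#'   (nmol/L * min) and `auc_gluca_below_basal` (ng/L * min).
#' @export
subject_indices <- function(series, fit, step = fit$step) {
  stopifnot(inherits(series, "ogtt_series"), inherits(fit, "gluca_fit"))
  rc <- remote_cpeptide(series, fit$params$k_dcprem, step = step)
  s <- fit$params$s_gluca
  tt <- series$times
  deficit <- pmax(series$gluca_b - series$glucagon, 0)
  structure(list(
    mean_sgluca_full = mean(s),
    mean_sgluca_3h = mean(s[tt <= 180]),
    mean_sgluca_2h = mean(s[tt <= 120]),
    auc_dcp_remote = auc_trapezoid(rc$times, rc$dcp_remote),
    auc_gluca_below_basal = auc_trapezoid(tt, deficit)
  ), class = "gluca_indices")
}

# Collect a list of gluca_indices into a data frame
.indices_df <- function(indices) {
  stopifnot(length(indices) >= 1,
            all(vapply(indices, inherits, TRUE, "gluca_indices")))
  do.call(rbind, lapply(indices, function(z) as.data.frame(unclass(z))))
}

#' Regression of alpha-cell sensitivity on the AUC ratio
#'
#' Regresses the log of each subject's mean `s_gluca` on the log of the
#' ratio of the suprabasal remote C-peptide AUC to the below-basal glucagon
#' AUC. Subjects with non-positive mean sensitivity or a non-positive AUC
#' ratio cannot be log-transformed and are excluded (their count is
#' reported). Returns the ordinary-least-squares slope and intercept, the
#' Pearson correlation with its Fisher-z 95% confidence interval, and the
#' two-sided p-value.
#'
#' @param indices A list of `gluca_indices` from [subject_indices()].
#' @return A list with `slope`, `intercept`, `r`, `r_ci` (length 2), `p`,
#'   `n_used`, `n_excluded` and `degenerate` (`TRUE` when either
#'   log-variable has zero variance, in which case `r` is `NA`).
#' @export
sgluca_auc_regression <- function(indices) {
  df <- .indices_df(indices)
  ratio <- df$auc_dcp_remote / df$auc_gluca_below_basal
  usable <- is.finite(ratio) & ratio > 0 & df$mean_sgluca_full > 0
  n_used <- sum(usable)
  if (n_used < 3L) {
    stop("fewer than 3 subjects with positive mean s_gluca and AUC ratio",
         call. = FALSE)
  }
  x <- log(ratio[usable])
  y <- log(df$mean_sgluca_full[usable])
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                r_ci = c(NA_real_, NA_real_), p = NA_real_,
                n_used = n_used, n_excluded = sum(!usable),
                degenerate = TRUE))
  }
  coefs <- stats::coef(stats::lm(y ~ x))
  r <- stats::cor(x, y)
  if (1 - r^2 < 1e-12) {
    # exactly collinear: |r| = 1, zero-width CI, p -> 0
    r <- sign(r)
    r_ci <- c(r, r)
    p <- 0
  } else {
    ct <- stats::cor.test(x, y)
    r <- unname(ct$estimate)
    # cor.test reports a Fisher-z CI only for n >= 4
    r_ci <- if (is.null(ct$conf.int)) c(NA_real_, NA_real_)
            else as.numeric(ct$conf.int)
    p <- ct$p.value
  }
  list(slope = unname(coefs[2]), intercept = unname(coefs[1]),
       r = r, r_ci = r_ci, p = p,
       n_used = n_used, n_excluded = sum(!usable), degenerate = FALSE)
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of normality with mean and SD estimated from the
#' data, using the Lilliefors correction ([nortest::lillie.test()], which
#' requires at least 5 values; for 3-4 values an uncorrected KS test on the
#' standardized sample is used and the result flagged approximate).
#'
#' @param values Numeric vector, `n >= 3`.
#' @return A list with `statistic`, `p`, `is_normal_at_5pct` and
#'   `degenerate` (`TRUE` for zero-variance input, where the test is
#'   undefined and `p` is `NA`).
#' @export
ks_normality <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  if (stats::sd(values) < 1e-12) {
    return(list(statistic = NA_real_, p = NA_real_,
                is_normal_at_5pct = NA, degenerate = TRUE))
  }
  if (length(values) >= 5L) {
    kt <- nortest::lillie.test(values)
  } else {
    z <- (values - mean(values)) / stats::sd(values)
    kt <- suppressWarnings(stats::ks.test(z, "pnorm"))
  }
  list(statistic = unname(kt$statistic), p = kt$p.value,
       is_normal_at_5pct = kt$p.value >= 0.05, degenerate = FALSE)
}

#' Sensitivity of mean alpha-cell sensitivity to OGTT duration
#'
#' Compares, across subjects, the mean `s_gluca` over the full test with
#' the means restricted to the 3-h and 2-h windows. For each pair the
#' paired differences are checked for normality ([ks_normality()]); a
#' paired Student t-test is used when they pass, a Wilcoxon signed-rank
#' test otherwise. Identical windows (all differences zero) are degenerate
#' and reported with `p = 1`.
#'
#' @param indices A list of `gluca_indices` from [subject_indices()]
#'   (`>= 3` subjects).
#' @return A data frame with one row per window pair (`full_vs_3h`,
#'   `full_vs_2h`) and columns `pair`, `test` (`"paired t"`,
#'   `"wilcoxon signed-rank"` or `"none"`), `statistic`, `p`,
#'   `normality_p` and `degenerate`.
#' @export
duration_sensitivity <- function(indices) {
  df <- .indices_df(indices)
  if (nrow(df) < 3L) stop("need at least 3 subjects", call. = FALSE)
  pairs <- list(full_vs_3h = df$mean_sgluca_full - df$mean_sgluca_3h,
                full_vs_2h = df$mean_sgluca_full - df$mean_sgluca_2h)
  rows <- lapply(names(pairs), function(nm) {
    d <- pairs[[nm]]
    if (all(d == 0)) {
      return(data.frame(pair = nm, test = "none", statistic = 0, p = 1,
                        normality_p = NA_real_, degenerate = TRUE))
    }
    ks <- ks_normality(d)
    normal <- isTRUE(ks$is_normal_at_5pct)
    if (normal) {
      ht <- stats::t.test(d)
      test <- "paired t"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(d))
      test <- "wilcoxon signed-rank"
    }
    data.frame(pair = nm, test = test, statistic = unname(ht$statistic),
               p = ht$p.value,
               normality_p = if (is.null(ks$p)) NA_real_ else ks$p,
               degenerate = FALSE)
  })
  do.call(rbind, rows)
}
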