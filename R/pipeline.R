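#' Pipeline run configuration
#'
#' Assembles and validates the configuration of a full
#' simulate-fit-analyze run. Any field may be overridden by a flat
#' key-value config file (see [read_config()]).
#'
#' @param template Template kind for [default_template()].
#' @param n_subjects Number of virtual subjects to generate.
#' @param seed Integer root seed; every random draw of the run derives
#'   from it.
#' @param step Simulation grid step in minutes.
#' @param n_starts Multistart runs per fit.
#' @param w1,w2 Regularization weights, or `"auto"` to select them with
#'   [select_weights()] on the first `select_subset` subjects.
#' @param threshold_pct Acceptance threshold for weight selection (%).
#' @param n_candidates_per_weight Candidate values per weight when
#'   `w1 = "auto"`.
#' @param select_subset Number of subjects used during weight selection.
#' @param out_dir Output directory (created if missing).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(template = "fivehour", n_subjects = 100, seed = 1,
                       step = 1, n_starts = 10, w1 = 0.1, w2 = 1,
                       threshold_pct = 10, n_candidates_per_weight = 10,
                       select_subset = 5, out_dir = "glucakin-run") {
  cfg <- list(template = template, n_subjects = n_subjects, seed = seed,
              step = step, n_starts = n_starts, w1 = w1, w2 = w2,
              threshold_pct = threshold_pct,
              n_candidates_per_weight = n_candidates_per_weight,
              select_subset = select_subset, out_dir = out_dir)
  auto <- identical(cfg$w1, "auto") || identical(cfg$w2, "auto")
  if (auto && !(identical(cfg$w1, "auto") && identical(cfg$w2, "auto"))) {
    stop("w1 and w2 must both be numeric or both \"auto\"", call. = FALSE)
  }
  if (!auto) {
    if (!is.numeric(cfg$w1) || !is.numeric(cfg$w2) ||
        cfg$w1 < 0 || cfg$w2 < 0) {
      stop("w1 and w2 must be non-negative numbers or \"auto\"",
           call. = FALSE)
    }
  }
  for (f in c("n_subjects", "step", "n_starts", "threshold_pct",
              "n_candidates_per_weight", "select_subset")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0) {
      stop("config field '", f, "' must be a positive number", call. = FALSE)
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    stop("config field 'seed' must be an integer", call. = FALSE)
  }
  template <- match.arg(cfg$template,
                        c("fivehour", paste0("twohour-cluster", 1:4)))
  cfg$template <- template
  cfg$auto_weights <- auto
  class(cfg) <- "run_config"
  cfg
}

#' Read a flat key-value configuration file
#'
#' Parses lines of the form `key = value` (or `key: value`; `#` starts a
#' comment) and merges them over the [run_config()] defaults. Numeric
#' values are converted; everything else stays character.
#'
#' @param path Path to the config file.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) {
      stop("cannot parse config line: '", ln, "'", call. = FALSE)
    }
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    kv[[m[2]]] <- if (!is.na(num)) num else val
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(kv), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, kv)
}

# Flatten a fit into plain lists for JSON
.fit_to_list <- function(fit) {
  list(
    package = "glucakin",
    version = as.character(utils::packageVersion("glucakin")),
    params = list(k_gluca = fit$params$k_gluca,
                  k_dcprem = fit$params$k_dcprem,
                  s_gluca = fit$params$s_gluca),
    ci_low = fit$ci_low, ci_high = fit$ci_high,
    times = fit$times,
    residuals = fit$residuals,
    rss = fit$rss,
    cost_terms = fit$cost_terms,
    mean_residual_pct = fit$mean_residual_pct,
    n_starts = fit$n_starts,
    best_start_index = fit$best_start_index,
    converged = fit$converged,
    multistart_log = fit$multistart_log,
    weights = list(w1 = fit$weights$w1, w2 = fit$weights$w2),
    seed = fit$seed, step = fit$step
  )
}

#' Write a fit report to JSON
#'
#' Serializes a `gluca_fit` (parameters, confidence bounds, residuals,
#' cost decomposition, multistart log, seed and configuration echo,
#' package version) with full numeric precision so numeric fields survive
#' a write-then-read round trip exactly.
#'
#' @param fit A `gluca_fit` from [fit_subject()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "gluca_fit"))
  # I(17) = 17 *significant* digits, enough for an exact double round trip
  jsonlite::write_json(.fit_to_list(fit), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", na = "null",
                       dataframe = "rows")
  invisible(path)
}

#' Read a fit report written by [write_fit_report()]
#'
#' @param path Path to the JSON report.
#' @return A `gluca_fit` object reconstructed from the report.
#' @export
read_fit_report <- function(path) {
  if (!file.exists(path)) stop("fit report not found: ", path, call. = FALSE)
  z <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    params = model_params(z$params$k_gluca, z$params$k_dcprem,
                          z$params$s_gluca),
    ci_low = z$ci_low, ci_high = z$ci_high,
    residuals = z$residuals,
    rss = z$rss,
    cost_terms = as.list(z$cost_terms),
    mean_residual_pct = z$mean_residual_pct,
    n_starts = z$n_starts,
    best_start_index = z$best_start_index,
    converged = z$converged,
    multistart_log = as.data.frame(z$multistart_log),
    weights = reg_weights(z$weights$w1, z$weights$w2),
    seed = z$seed, step = z$step,
    times = z$times
  ), class = "gluca_fit")
}

#' Run the full simulate-fit-analyze pipeline
#'
#' Generates a virtual population from a packaged template, fits the
#' glucagon model to every subject (optionally selecting the
#' regularization weights on a subset first), computes per-subject indices
#' and the population statistics, and writes all artifacts under
#' `config$out_dir`: one OGTT CSV and one fit JSON per subject, a
#' population summary CSV (one row per subject) and a `stats.json` with
#' the regression and duration-sensitivity results. The run is fully
#' reproducible from the configuration alone.
#'
#' @param config A [run_config()] (or path handled by [read_config()]).
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return A list (invisibly) with `config`, `weights`, `fits`, `indices`,
#'   `summary` (data frame), `regression` and `duration`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(config$out_dir, "ogtt"), showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "fits"), showWarnings = FALSE)

  say("simulate: ", config$n_subjects, " virtual subjects from template '",
      config$template, "'")
  template <- default_template(config$template)
  subjects <- generate_population(template, n = config$n_subjects,
                                  seed = config$seed)
  for (s in subjects) {
    write_ogtt_csv(s, file.path(config$out_dir, "ogtt",
                                paste0(s$id, ".csv")))
  }

  if (config$auto_weights) {
    k <- min(config$select_subset, length(subjects))
    say("select weights: ", config$n_candidates_per_weight, "^2 candidates ",
        "on ", k, " subjects")
    sel <- select_weights(subjects[seq_len(k)],
                          n_candidates_per_weight =
                            config$n_candidates_per_weight,
                          seed = config$seed + 1L,
                          threshold_pct = config$threshold_pct,
                          n_starts = config$n_starts, step = config$step)
    weights <- sel$weights
    utils::write.csv(sel$table,
                     file.path(config$out_dir, "weight_selection.csv"),
                     row.names = FALSE)
  } else {
    weights <- reg_weights(config$w1, config$w2)
  }

  say("fit: ", length(subjects), " subjects, ", config$n_starts,
      " starts each (w1 = ", signif(weights$w1, 3),
      ", w2 = ", signif(weights$w2, 3), ")")
  set.seed(config$seed + 2L)
  fit_seeds <- sample.int(.Machine$integer.max - 1L, length(subjects))
  fits <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    fits[[i]] <- fit_subject(subjects[[i]], weights = weights,
                             n_starts = config$n_starts,
                             seed = fit_seeds[i], step = config$step)
    write_fit_report(fits[[i]],
                     file.path(config$out_dir, "fits",
                               paste0(subjects[[i]]$id, ".json")))
  }

  say("analyze: per-subject indices + population statistics")
  indices <- lapply(seq_along(subjects), function(i) {
    subject_indices(subjects[[i]], fits[[i]], step = config$step)
  })
  summary_df <- cbind(
    data.frame(id = vapply(subjects, function(s) s$id, character(1)),
               k_gluca = vapply(fits, function(f) f$params$k_gluca, 1),
               k_dcprem = vapply(fits, function(f) f$params$k_dcprem, 1),
               mean_residual_pct = vapply(fits, function(f)
                 f$mean_residual_pct, 1),
               converged = vapply(fits, function(f) f$converged, TRUE)),
    .indices_df(indices))
  utils::write.csv(summary_df,
                   file.path(config$out_dir, "population_summary.csv"),
                   row.names = FALSE)

  regression <- sgluca_auc_regression(indices)
  duration <- duration_sensitivity(indices)
  jsonlite::write_json(list(config = unclass(config)[!vapply(config, is.function, TRUE)],
                            weights = list(w1 = weights$w1, w2 = weights$w2),
                            regression = regression,
                            duration = duration),
                       file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  say(sprintf("done: r = %.3f (p = %.3g), slope = %.3f",
              regression$r, regression$p, regression$slope))
  invisible(list(config = config, weights = weights, fits = fits,
                 indices = indices, summary = summary_df,
                 regression = regression, duration = duration))
}
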