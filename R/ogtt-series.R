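#' One subject's sampled OGTT curves
#'
#' Container for a single subject's oral glucose tolerance test (OGTT) time
#' series: sampling times in minutes, plasma glucagon (ng/L) and plasma
#' C-peptide (nmol/L) at each sample. Basal (fasting) values are taken from
#' the sample at time 0, which must be present and first.
#'
#' @param times Numeric vector of sampling times in minutes, strictly
#'   increasing, first element 0.
#' @param glucagon Numeric vector of plasma glucagon concentrations (ng/L),
#'   one per sampling time, all non-negative.
#' @param cpeptide Numeric vector of plasma C-peptide concentrations
#'   (nmol/L), one per sampling time, all non-negative.
#' @param id Optional subject identifier (character scalar).
#'
#' @return An object of class `ogtt_series`: a list with elements `times`,
#'   `glucagon`, `cpeptide`, `gluca_b` (basal glucagon, equal to
#'   `glucagon[1]`), `cp_b` (basal C-peptide, equal to `cpeptide[1]`) and
#'   `id`.
#'
#' @examples
#' s <- ogtt_series(times = c(0, 30, 60, 90, 120),
#'                  glucagon = c(70, 55, 45, 48, 52),
#'                  cpeptide = c(0.5, 1.6, 2.2, 2.3, 2.1))
#' s$gluca_b
#' @export
ogtt_series <- function(times, glucagon, cpeptide, id = NULL) {
  times <- as.numeric(times)
  glucagon <- as.numeric(glucagon)
  cpeptide <- as.numeric(cpeptide)
  n <- length(times)
  if (n < 3L) {
    stop("an OGTT series needs at least 3 sampling times", call. = FALSE)
  }
  if (length(glucagon) != n || length(cpeptide) != n) {
    stop("times, glucagon and cpeptide must have equal length", call. = FALSE)
  }
  if (anyNA(times) || anyNA(glucagon) || anyNA(cpeptide)) {
    stop("OGTT series values must not contain NA", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("sampling times must be strictly increasing", call. = FALSE)
  }
  if (times[1] != 0) {
    stop("the first sampling time must be 0 (fasting sample)", call. = FALSE)
  }
  if (any(glucagon < 0) || any(cpeptide < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  structure(
    list(times = times, glucagon = glucagon, cpeptide = cpeptide,
         gluca_b = glucagon[1], cp_b = cpeptide[1],
         id = if (is.null(id)) NA_character_ else as.character(id)),
    class = "ogtt_series"
  )
}

#' @export
print.ogtt_series <- function(x, ...) {
  cat(sprintf("OGTT series%s: %d samples over %g min\n",
              if (is.na(x$id)) "" else paste0(" '", x$id, "'"),
              length(x$times), max(x$times)))
  cat(sprintf("  basal glucagon %.4g ng/L, basal C-peptide %.4g nmol/L\n",
              x$gluca_b, x$cp_b))
  print(data.frame(time_min = x$times, glucagon_ng_L = x$glucagon,
                   cpeptide_nmol_L = x$cpeptide), row.names = FALSE, ...)
  invisible(x)
}

.ogtt_columns <- c("time_min", "glucagon_ng_L", "cpeptide_nmol_L")

#' Read an OGTT series from CSV
#'
#' Reads one subject's OGTT from a comma-separated file with header
#' `time_min,glucagon_ng_L,cpeptide_nmol_L`, one row per sample, decimal
#' point. The file must contain a row at time 0; basal values are taken
#' from it.
#'
#' @param path Path to the CSV file.
#' @return An [ogtt_series()] object; its `id` is the file name without
#'   extension.
#' @export
read_ogtt_csv <- function(path) {
  if (!file.exists(path)) {
    stop("OGTT file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.ogtt_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("OGTT file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cl in .ogtt_columns) {
    bad <- which(!is.finite(df[[cl]]))
    if (length(bad) > 0) {
      stop("OGTT file ", path, ": non-numeric or missing value in column '",
           cl, "', row ", bad[1], call. = FALSE)
    }
  }
  if (any(diff(df$time_min) <= 0)) {
    row <- which(diff(df$time_min) <= 0)[1] + 1L
    stop("OGTT file ", path, ": times not strictly increasing at row ", row,
         call. = FALSE)
  }
  neg <- which(df$glucagon_ng_L < 0 | df$cpeptide_nmol_L < 0)
  if (length(neg) > 0) {
    stop("OGTT file ", path, ": negative concentration at row ", neg[1],
         call. = FALSE)
  }
  if (df$time_min[1] != 0) {
    stop("OGTT file ", path, ": no row at time 0 (fasting sample required)",
         call. = FALSE)
  }
  ogtt_series(df$time_min, df$glucagon_ng_L, df$cpeptide_nmol_L,
              id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write an OGTT series to CSV
#'
#' Inverse of [read_ogtt_csv()]; numeric values are written with full
#' precision so a write-then-read round trip reproduces the series exactly.
#'
#' @param series An [ogtt_series()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ogtt_csv <- function(series, path) {
  stopifnot(inherits(series, "ogtt_series"))
  df <- data.frame(time_min = series$times,
                   glucagon_ng_L = series$glucagon,
                   cpeptide_nmol_L = series$cpeptide)
  # format() with 17 significant digits keeps the decimal round trip exact
  df[] <- lapply(df, function(v) format(v, digits = 17, trim = TRUE,
                                        scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
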