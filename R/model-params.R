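#' Model parameters of the glucagon kinetics minimal model
#'
#' Bundles the three quantities estimated per subject: the plasma glucagon
#' elimination rate `k_gluca` (1/min), the elimination rate of suprabasal
#' C-peptide from the remote compartment `k_dcprem` (1/min), and the
#' time-varying alpha-cell insulin sensitivity `s_gluca` (ng glucagon per
#' nmol C-peptide), one value per OGTT sampling time. During simulation
#' `s_gluca[i]` holds, piecewise constant, on the interval
#' `[times[i], times[i + 1])`; the value attached to the last sampling time
#' therefore has no dynamic effect and is pinned only by the smoothness
#' penalty during estimation.
#'
#' Estimation constrains both rates to `[0, 1]`; simulation accepts any
#' non-negative rate. `s_gluca` is unbounded and may be negative (periods
#' where glucagon rises while insulin secretion is not falling).
#'
#' @param k_gluca Glucagon elimination rate from plasma (1/min), `>= 0`.
#' @param k_dcprem Remote-compartment C-peptide elimination rate (1/min),
#'   `>= 0`.
#' @param s_gluca Numeric vector of sensitivities, one per sampling time of
#'   the series the parameters will be paired with.
#'
#' @return An object of class `gluca_params`.
#' @examples
#' model_params(0.005, 0.155, rep(2, 11))
#' @export
model_params <- function(k_gluca, k_dcprem, s_gluca) {
  k_gluca <- as.numeric(k_gluca)
  k_dcprem <- as.numeric(k_dcprem)
  s_gluca <- as.numeric(s_gluca)
  if (length(k_gluca) != 1L || length(k_dcprem) != 1L) {
    stop("k_gluca and k_dcprem must be scalar rates", call. = FALSE)
  }
  if (!is.finite(k_gluca) || k_gluca < 0) {
    stop("k_gluca must be a finite non-negative rate", call. = FALSE)
  }
  if (!is.finite(k_dcprem) || k_dcprem < 0) {
    stop("k_dcprem must be a finite non-negative rate", call. = FALSE)
  }
  if (length(s_gluca) < 1L || anyNA(s_gluca)) {
    stop("s_gluca must be a numeric vector without NA", call. = FALSE)
  }
  structure(list(k_gluca = k_gluca, k_dcprem = k_dcprem, s_gluca = s_gluca),
            class = "gluca_params")
}

#' @export
print.gluca_params <- function(x, ...) {
  cat(sprintf("glucagon model parameters: k_gluca = %.4g /min, k_dcprem = %.4g /min\n",
              x$k_gluca, x$k_dcprem))
  cat("  s_gluca knots (ng/nmol): ",
      paste(formatC(x$s_gluca, digits = 3, format = "fg"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# check params against a series; stops on mismatch
.check_params_series <- function(params, series) {
  if (length(params$s_gluca) != length(series$times)) {
    stop("length of s_gluca (", length(params$s_gluca),
         ") must equal the number of sampling times (",
         length(series$times), ")", call. = FALSE)
  }
  invisible(TRUE)
}
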