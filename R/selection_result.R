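#' Construct a selection result
#'
#' Common return type of [run_opwc], [search_mwpls], [run_mcuve] and the
#' full-spectrum baseline: the chosen wavelengths plus the fitted-model
#' summary (factor count, SECV, cross-validated correlation). The summary is
#' always recomputable from `wavelengths` and `n_factors` via
#' [loocv_predict].
#'
#' @param method Method label, e.g. `"OPWC-PLS"`.
#' @param wavelengths Selected wavelengths (nm).
#' @param n_factors PLS factor count of the reported model.
#' @param secv LOOCV root-mean-square error (g/L).
#' @param r_pcv Cross-validated correlation coefficient.
#' @param trace Optional method-specific trace (projection sequence, search
#'   surface, stability profile, ...).
#' @param extra Optional list of additional diagnostics.
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(method, wavelengths, n_factors, secv, r_pcv,
                             trace = NULL, extra = list()) {
  structure(
    list(method = method, wavelengths = as.numeric(wavelengths),
         n_wavelengths = length(wavelengths),
         n_factors = as.integer(n_factors),
         secv = as.numeric(secv), r_pcv = as.numeric(r_pcv),
         trace = trace, extra = extra),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s\n", x$method))
  cat(sprintf("  wavelengths: %d  factors: %d  SECV: %.4f  R_P,CV: %.4f\n",
              x$n_wavelengths, x$n_factors, x$secv, x$r_pcv))
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' Writes the self-describing JSON form (method, wavelengths in nm, factor
#' count, SECV, correlation, seed and any trace), sufficient to re-verify
#' the reported statistics independently.
#'
#' @param x A `selection_result`.
#' @param path Output path; if `NULL` the JSON string is returned.
#' @param seed Seed recorded in the output (for provenance).
#' @return The JSON string, invisibly when written to `path`.
#' @export
selection_to_json <- function(x, path = NULL, seed = NULL) {
  stopifnot(inherits(x, "selection_result"))
  obj <- list(method = x$method, wavelengths = x$wavelengths,
              N = x$n_wavelengths, F = x$n_factors,
              SECV = x$secv, R_P_CV = x$r_pcv)
  if (!is.null(seed)) obj$seed <- as.integer(seed)
  if (!is.null(x$trace)) {
    tr <- x$trace
    tr$sets <- NULL  # full per-iteration sets can be large; counts suffice
    obj$trace <- tr
  }
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
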