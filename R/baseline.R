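#' Full-spectrum PLS baseline
#'
#' The no-selection reference model: [select_factors] on all wavelengths.
#'
#' @param data A [spectra_set].
#' @param factor_grid Candidate factor counts; default `1:20`.
#' @return A `selection_result` with method `"PLS"`.
#' @export
run_pls_baseline <- function(data, factor_grid = 1:20) {
  validate_spectra_set(data)
  fit <- select_factors(data$absorbance, data$reference, factor_grid)
  selection_result(method = "PLS", wavelengths = data$wavelengths,
                   n_factors = fit$n_factors, secv = fit$secv,
                   r_pcv = fit$r_pcv)
}
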