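#' Construct a spectra set
#'
#' A `spectra_set` bundles a wavelength grid, an absorbance matrix (rows =
#' samples, columns = wavelengths) and one reference value per sample (the
#' analyte concentration the calibration predicts, in g/L). It is the
#' container every selection method in the package operates on.
#'
#' @param wavelengths Strictly increasing numeric vector of grid points (nm).
#' @param absorbance Numeric matrix, `n_samples x length(wavelengths)`.
#' @param reference Numeric vector of length `n_samples`.
#' @param sample_ids Optional character vector of sample labels.
#' @return An object of class `spectra_set`.
#' @export
#' @examples
#' s <- spectra_set(c(780, 782), matrix(rnorm(6), 3), reference = c(1, 2, 3))
#' n_samples(s)
spectra_set <- function(wavelengths, absorbance, reference, sample_ids = NULL) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  reference <- as.numeric(reference)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(absorbance)))
  x <- structure(
    list(wavelengths = wavelengths, absorbance = absorbance,
         reference = reference, sample_ids = as.character(sample_ids)),
    class = "spectra_set")
  validate_spectra_set(x)
  x
}

#' @rdname spectra_set
#' @param x A `spectra_set`.
#' @export
validate_spectra_set <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  if (length(x$wavelengths) != ncol(x$absorbance))
    stop("number of wavelengths must equal number of absorbance columns",
         call. = FALSE)
  if (length(x$reference) != nrow(x$absorbance))
    stop("number of reference values must equal number of absorbance rows",
         call. = FALSE)
  if (length(x$sample_ids) != nrow(x$absorbance))
    stop("number of sample ids must equal number of absorbance rows",
         call. = FALSE)
  if (length(x$wavelengths) > 1L && any(diff(x$wavelengths) <= 0))
    stop("wavelengths must be strictly increasing with no duplicates",
         call. = FALSE)
  if (anyNA(x$absorbance) || anyNA(x$reference) || anyNA(x$wavelengths))
    stop("spectra_set must not contain missing values", call. = FALSE)
  invisible(x)
}

#' @rdname spectra_set
#' @export
n_samples <- function(x) nrow(x$absorbance)

#' @rdname spectra_set
#' @export
n_wavelengths <- function(x) length(x$wavelengths)

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf(
    "<spectra_set> %d samples x %d wavelengths (%g-%g nm)\n",
    n_samples(x), n_wavelengths(x), min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("reference: mean %.3f, sd %.3f, range [%.3f, %.3f]\n",
              mean(x$reference), stats::sd(x$reference),
              min(x$reference), max(x$reference)))
  invisible(x)
}

#' Restrict a spectra set to a wavelength selection
#'
#' @param data A `spectra_set`.
#' @param selection Wavelengths (nm) to keep; every value must be on the grid.
#' @return A `spectra_set` with exactly the requested wavelengths, in
#'   increasing order; samples and reference values are unchanged.
#' @export
subset_wavelengths <- function(data, selection) {
  validate_spectra_set(data)
  selection <- sort(unique(as.numeric(selection)))
  idx <- match(selection, data$wavelengths)
  if (anyNA(idx))
    stop("wavelength(s) not on grid: ",
         paste(selection[is.na(idx)], collapse = ", "), call. = FALSE)
  spectra_set(data$wavelengths[idx], data$absorbance[, idx, drop = FALSE],
              data$reference, data$sample_ids)
}

#' Average replicate measurements
#'
#' Collapses replicate rows to per-group arithmetic means of both absorbance
#' and reference value, the usual treatment when each specimen is scanned
#' several times.
#'
#' @param data A `spectra_set`.
#' @param group_labels Vector with one label per row; rows sharing a label are
#'   averaged. Output order follows first appearance.
#' @return A `spectra_set` with one row per group.
#' @export
average_replicates <- function(data, group_labels) {
  validate_spectra_set(data)
  if (length(group_labels) != n_samples(data))
    stop("group_labels must have one entry per sample", call. = FALSE)
  g <- factor(group_labels, levels = unique(as.character(group_labels)))
  A <- rowsum(data$absorbance, g, reorder = FALSE)
  cnt <- as.vector(table(g)[levels(g)])
  A <- A / cnt
  ref <- as.vector(rowsum(data$reference, g, reorder = FALSE)) / cnt
  spectra_set(data$wavelengths, A, ref, levels(g))
}
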