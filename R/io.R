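# Wide-table CSV dialect: first column sample id, one column per wavelength
# (header is the wavelength in nm), plus one named reference column. This is
# the simplest interoperable format for spectra paired with a lab value.

#' Read a wide spectra table
#'
#' Reads a comma-delimited wide table (one row per sample, one column per
#' wavelength) into a [spectra_set]. Wavelength columns are identified by a
#' numeric header; columns are reordered so wavelengths increase.
#'
#' @param path File path.
#' @param reference_column Name of the column holding the analyte reference
#'   value (g/L).
#' @param id_column Name of the sample-id column; default `"id"`. If absent,
#'   row numbers are used.
#' @return A [spectra_set].
#' @export
read_spectra_table <- function(path, reference_column = "ref",
                               id_column = "id") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  if (!reference_column %in% nm)
    stop("reference column '", reference_column, "' not found in ", path,
         call. = FALSE)
  if (anyDuplicated(nm))
    stop("duplicate columns in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  ids <- if (id_column %in% nm) as.character(df[[id_column]])
         else as.character(seq_len(nrow(df)))
  wl_cols <- setdiff(nm, c(reference_column, id_column))
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl))
    stop("non-numeric wavelength column header(s): ",
         paste(wl_cols[is.na(wl)], collapse = ", "), call. = FALSE)
  A <- as.matrix(df[wl_cols])
  if (!is.numeric(A)) {
    bad <- which(!vapply(df[wl_cols], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(df[[wl_cols[bad]]]))))[1]
    stop("non-numeric absorbance value at row ", badrow, ", column '",
         wl_cols[bad], "'", call. = FALSE)
  }
  ord <- order(wl)
  spectra_set(wl[ord], A[, ord, drop = FALSE],
              as.numeric(df[[reference_column]]), ids)
}

#' Write a spectra set as a wide table
#'
#' Emits the comma-delimited wide format accepted by [read_spectra_table]:
#' columns `id`, one per wavelength (header in nm), and the reference column.
#'
#' @param data A [spectra_set] with at least one sample.
#' @param path Output file path.
#' @param reference_column Header for the reference column; default `"ref"`.
#' @param digits Significant digits written; default 15 keeps a read/write
#'   round trip exact for doubles in practice.
#' @return Invisibly, `path`.
#' @export
write_spectra_table <- function(data, path, reference_column = "ref",
                                digits = 15) {
  validate_spectra_set(data)
  if (n_samples(data) < 1L)
    stop("cannot write a spectra_set with no samples", call. = FALSE)
  df <- data.frame(id = data$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  A <- signif(data$absorbance, digits)
  for (j in seq_along(data$wavelengths))
    df[[format(data$wavelengths[j], trim = TRUE)]] <- A[, j]
  df[[reference_column]] <- signif(data$reference, digits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
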