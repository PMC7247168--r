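# Pairwise scoring of wavelengths by binary-linear-regression LOOCV and the
# best-partner mapping derived from it. The scan over all unordered pairs is
# the computational core of partner-based selection: on a full 860-point NIR
# grid it evaluates 369,370 regressions, so it uses the hat-matrix
# leave-one-out identity (validated against naive per-fold refitting in the
# test suite) inside a compiled loop.

#' LOOCV SECV of a two-wavelength linear regression
#'
#' Scores the model `y ~ b0 + b1 * x_i + b2 * x_k` by leave-one-out cross
#' validation, using the closed-form identity
#' `loo residual = residual / (1 - leverage)`.
#'
#' @param x_i,x_k Absorbance vectors at the two wavelengths.
#' @param y Reference values; at least 4 samples (the model has three
#'   parameters).
#' @return LOOCV SECV (g/L), or `Inf` if the pair is non-identifiable
#'   (collinear or constant columns, or a leverage numerically at 1).
#' @export
blr_loocv_secv <- function(x_i, x_k, y) {
  x_i <- as.numeric(x_i); x_k <- as.numeric(x_k); y <- as.numeric(y)
  n <- length(y)
  if (length(x_i) != n || length(x_k) != n)
    stop("x_i, x_k and y must have equal length", call. = FALSE)
  if (n < 4L) stop("binary linear regression LOOCV requires n >= 4",
                   call. = FALSE)
  pair_secv_cpp(cbind(x_i, x_k), y)[1, 2]
}

#' Score every unordered wavelength pair
#'
#' Computes the symmetric matrix of [blr_loocv_secv] scores over all
#' unordered pairs of wavelengths. Each pair is evaluated once and mirrored,
#' so the matrix is exactly symmetric; the diagonal is `NaN` and
#' non-identifiable pairs are `Inf`.
#'
#' @param data A [spectra_set] with at least 4 samples and 2 wavelengths.
#' @return An object of class `pair_score_matrix`: list with `wavelengths`
#'   and the `scores` matrix.
#' @export
pairwise_scores <- function(data) {
  validate_spectra_set(data)
  if (n_samples(data) < 4L) stop("pairwise scoring requires n >= 4 samples",
                                 call. = FALSE)
  if (n_wavelengths(data) < 2L)
    stop("pairwise scoring requires at least 2 wavelengths", call. = FALSE)
  S <- pair_secv_cpp(data$absorbance, data$reference)
  pair_score_matrix(data$wavelengths, S)
}

#' @rdname pairwise_scores
#' @param wavelengths Wavelength grid (nm).
#' @param scores Symmetric score matrix (diagonal ignored).
#' @export
pair_score_matrix <- function(wavelengths, scores) {
  wavelengths <- as.numeric(wavelengths)
  scores <- as.matrix(scores)
  if (nrow(scores) != ncol(scores) || nrow(scores) != length(wavelengths))
    stop("scores must be square with one row per wavelength", call. = FALSE)
  off <- scores[upper.tri(scores)]
  if (any(off < 0, na.rm = TRUE))
    stop("pair scores must be non-negative", call. = FALSE)
  if (!isTRUE(all.equal(scores[upper.tri(scores)], t(scores)[upper.tri(scores)])))
    stop("scores must be symmetric", call. = FALSE)
  structure(list(wavelengths = wavelengths, scores = scores),
            class = "pair_score_matrix")
}

#' Best-partner mapping
#'
#' For each wavelength, the partner minimising the pairwise LOOCV score:
#' `f(lambda_i) = argmin over k != i of scores[i, k]`. Ties are broken toward
#' the smallest wavelength; `f` has no fixed points by construction.
#'
#' @param scores A `pair_score_matrix`.
#' @return An object of class `partner_map`: list with `wavelengths`,
#'   `partner_index` (integer vector, `partner_index[i]` indexes `f(lambda_i)`),
#'   `partner` (the partner wavelengths in nm) and `score`
#'   (`scores[i, partner_index[i]]`).
#' @export
best_partner_map <- function(scores) {
  stopifnot(inherits(scores, "pair_score_matrix"))
  S <- scores$scores
  N <- nrow(S)
  idx <- integer(N)
  val <- numeric(N)
  for (i in seq_len(N)) {
    row <- S[i, ]
    row[i] <- Inf
    row[is.na(row)] <- Inf
    j <- which.min(row)  # first minimum: ties go to the smallest wavelength
    if (!is.finite(row[j]))
      stop("wavelength ", scores$wavelengths[i],
           " nm has no identifiable partner", call. = FALSE)
    idx[i] <- j
    val[i] <- row[j]
  }
  structure(list(wavelengths = scores$wavelengths, partner_index = idx,
                 partner = scores$wavelengths[idx], score = val),
            class = "partner_map")
}

#' @export
print.partner_map <- function(x, ...) {
  cat(sprintf("<partner_map> %d wavelengths, %d distinct partners\n",
              length(x$wavelengths), length(unique(x$partner_index))))
  invisible(x)
}
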