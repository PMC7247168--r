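# PLS1 regression (NIPALS on column-centred, unscaled data) and the
# leave-one-out cross-validation protocol used as the selection objective by
# every method in the package. No variance scaling is applied anywhere: raw
# absorbance enters the models.

#' Fit a PLS1 regression model
#'
#' NIPALS partial least squares with a single response, on column-centred and
#' unscaled data. Component extraction stops early if the X residual norm
#' falls below `1e-12`; remaining factors contribute nothing.
#'
#' @param X Numeric matrix (rows = samples).
#' @param y Numeric response vector.
#' @param n_factors Number of latent factors `F`; must satisfy
#'   `F <= min(nrow(X) - 1, ncol(X))`.
#' @param wavelengths Optional wavelengths (nm) labelling the columns.
#' @return An object of class `pls_model` with elements `coefficients`
#'   (length-`ncol(X)` regression vector on raw absorbance), `x_mean`,
#'   `y_mean`, `n_factors` (requested) and `n_components` (extracted).
#' @export
fit_pls <- function(X, y, n_factors, wavelengths = NULL) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (ncol(X) < 1L) stop("X must have at least one column", call. = FALSE)
  n_factors <- as.integer(n_factors)
  if (n_factors < 1L || n_factors > min(nrow(X) - 1L, ncol(X)))
    stop("n_factors must be in 1..min(nrow(X) - 1, ncol(X))", call. = FALSE)
  if (stats::var(y) == 0) stop("response has zero variance", call. = FALSE)
  fit <- pls1_fit_cpp(X, y, n_factors)
  structure(
    list(coefficients = as.numeric(fit$coefficients),
         x_mean = as.numeric(fit$x_mean), y_mean = fit$y_mean,
         n_factors = n_factors, n_components = fit$n_components,
         wavelengths = wavelengths),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d factor(s) on %d wavelength(s)\n",
              x$n_factors, length(x$coefficients)))
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Numeric matrix with the same number of columns the model
#'   was trained on.
#' @param ... Unused.
#' @return Numeric vector of predictions (centred `newdata` times the
#'   regression vector, plus `y_mean`).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$coefficients), call. = FALSE)
  drop(sweep(newdata, 2, object$x_mean) %*% object$coefficients) +
    object$y_mean
}

#' Leave-one-out cross-validated predictions
#'
#' Each sample is predicted by a PLS model fitted on all other samples.
#'
#' @inheritParams fit_pls
#' @param n_factors Factor count; must satisfy
#'   `n_factors <= min(nrow(X) - 2, ncol(X))` so every fold is feasible.
#' @return A `prediction_record`: list with `measured` and `predicted`
#'   vectors of equal length.
#' @export
loocv_predict <- function(X, y, n_factors) {
  P <- loocv_predict_all(X, y, n_factors)
  prediction_record(y, P[, n_factors])
}

# LOO predictions for every factor count 1..Fmax at the cost of one pass.
loocv_predict_all <- function(X, y, Fmax) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("LOOCV requires at least 3 samples", call. = FALSE)
  Fmax <- as.integer(Fmax)
  if (Fmax < 1L || Fmax > min(n - 2L, ncol(X)))
    stop("n_factors must be in 1..min(n - 2, ncol(X))", call. = FALSE)
  pls1_loocv_cpp(X, y, Fmax)
}

#' Build a prediction record
#'
#' @param measured,predicted Equal-length numeric vectors of measured and
#'   cross-validated predicted values.
#' @return An object of class `prediction_record`.
#' @export
prediction_record <- function(measured, predicted) {
  measured <- as.numeric(measured); predicted <- as.numeric(predicted)
  if (length(measured) != length(predicted))
    stop("measured and predicted must have equal length", call. = FALSE)
  structure(list(measured = measured, predicted = predicted),
            class = "prediction_record")
}

#' Root-mean-square error of cross validation
#'
#' `SECV = sqrt(mean((predicted - measured)^2))`, in the units of the
#' reference value (g/L).
#'
#' @param record A `prediction_record`, or a measured vector if `predicted`
#'   is supplied.
#' @param predicted Optional predicted vector.
#' @return Non-negative scalar; zero iff the two vectors are equal.
#' @export
secv <- function(record, predicted = NULL) {
  if (!is.null(predicted)) record <- prediction_record(record, predicted)
  stopifnot(inherits(record, "prediction_record"))
  sqrt(mean((record$predicted - record$measured)^2))
}

#' Cross-validated correlation coefficient
#'
#' Pearson correlation between measured and cross-validated predicted values.
#'
#' @inheritParams secv
#' @return Scalar in `[-1, 1]`.
#' @export
r_pcv <- function(record, predicted = NULL) {
  if (!is.null(predicted)) record <- prediction_record(record, predicted)
  stopifnot(inherits(record, "prediction_record"))
  m <- record$measured - mean(record$measured)
  p <- record$predicted - mean(record$predicted)
  den <- sqrt(sum(m^2) * sum(p^2))
  if (den == 0)
    stop("correlation undefined: a vector has zero variance", call. = FALSE)
  sum(m * p) / den
}

#' Choose the factor count minimising LOOCV SECV
#'
#' Evaluates each feasible factor count in `factor_grid` by leave-one-out
#' cross validation and returns the one attaining minimum SECV, ties broken
#' toward the smaller count (parsimony).
#'
#' @inheritParams fit_pls
#' @param factor_grid Integer vector of candidate factor counts; infeasible
#'   entries (`F > min(nrow(X) - 2, ncol(X))`) are skipped.
#' @return List with `n_factors`, `record` (the winning
#'   `prediction_record`), `secv`, `r_pcv`, and `secv_by_factor` (named by
#'   the feasible grid entries).
#' @export
select_factors <- function(X, y, factor_grid) {
  X <- as.matrix(X)
  factor_grid <- sort(unique(as.integer(factor_grid)))
  feasible <- factor_grid[factor_grid >= 1L &
                            factor_grid <= min(nrow(X) - 2L, ncol(X))]
  if (length(feasible) == 0L)
    stop("no feasible factor count in grid", call. = FALSE)
  P <- loocv_predict_all(X, y, max(feasible))
  sec <- vapply(feasible, function(f) secv(y, P[, f]), numeric(1))
  best <- feasible[which.min(sec)]  # first minimum = smallest F on ties
  rec <- prediction_record(y, P[, best])
  list(n_factors = best, record = rec, secv = secv(rec), r_pcv = r_pcv(rec),
       secv_by_factor = stats::setNames(sec, feasible))
}
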