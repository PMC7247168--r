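# Monte Carlo uninformative variable elimination: artificial noise variables
# are appended to the spectra, many PLS models are fitted on random sample
# subsets, and each variable is judged by the stability of its regression
# coefficient (mean across runs divided by standard deviation). Real
# variables whose |stability| does not beat the noise variables' are deemed
# uninformative and removed.

#' Append artificial noise variables
#'
#' Adds `n_noise` columns of uniform random noise scaled to `1e-10` of the
#' mean absolute absorbance, the conventional magnitude that cannot carry
#' predictive information yet still yields finite coefficient stabilities.
#'
#' @param X Absorbance matrix.
#' @param n_noise Number of noise columns; default `ncol(X)`.
#' @param seed Integer seed (the augmentation is bit-reproducible).
#' @return List with `X_aug` (the augmented matrix) and `noise_mask`
#'   (logical, `TRUE` for noise columns).
#' @export
augment_noise <- function(X, n_noise = ncol(X), seed = 1L) {
  X <- as.matrix(X)
  n_noise <- as.integer(n_noise)
  if (n_noise < 1L) stop("n_noise must be >= 1", call. = FALSE)
  scale <- 1e-10 * mean(abs(X))
  noise <- with_seed(seed,
    matrix(stats::runif(nrow(X) * n_noise), nrow(X), n_noise)) * scale
  list(X_aug = cbind(X, noise),
       noise_mask = c(rep(FALSE, ncol(X)), rep(TRUE, n_noise)))
}

#' Coefficient stability across Monte Carlo subsets
#'
#' Fits `n_runs` PLS models, each on a random subset (without replacement) of
#' `round(fraction * n)` samples, and returns per-variable stability =
#' mean(coefficient) / sd(coefficient) across runs.
#'
#' @param X_aug (Augmented) predictor matrix.
#' @param y Reference values.
#' @param n_runs Number of Monte Carlo samplings (>= 2).
#' @param fraction Calibration fraction per run, in (0, 1).
#' @param n_factors PLS factor count used in every run.
#' @param seed Integer seed.
#' @param noise_mask Optional logical vector labelling noise columns; carried
#'   through to the profile.
#' @return An object of class `stability_profile`: list with `stability`,
#'   `coef_mean`, `coef_sd`, `noise_mask`, `n_runs`, `fraction`, `n_factors`.
#'   Variables with zero coefficient spread get `NA` stability and are
#'   flagged in `degenerate`.
#' @export
compute_stability <- function(X_aug, y, n_runs, fraction, n_factors,
                              seed = 1L, noise_mask = NULL) {
  X_aug <- as.matrix(X_aug)
  y <- as.numeric(y)
  n <- nrow(X_aug)
  n_runs <- as.integer(n_runs)
  if (n_runs < 2L) stop("n_runs must be >= 2", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  m <- as.integer(round(fraction * n))
  if (m < n_factors + 2L)
    stop("fraction * n must be at least n_factors + 2", call. = FALSE)
  B <- with_seed(seed, {
    out <- matrix(NA_real_, n_runs, ncol(X_aug))
    for (r in seq_len(n_runs)) {
      repeat {  # resample the rare all-equal-y subset
        idx <- sample.int(n, m)
        if (stats::var(y[idx]) > 0) break
      }
      fit <- pls1_fit_cpp(X_aug[idx, , drop = FALSE], y[idx],
                          as.integer(n_factors))
      out[r, ] <- fit$coefficients
    }
    out
  })
  cm <- colMeans(B)
  cs <- apply(B, 2, stats::sd)
  stab <- ifelse(cs > 0, cm / cs, NA_real_)
  structure(
    list(stability = stab, coef_mean = cm, coef_sd = cs,
         noise_mask = noise_mask %||% rep(FALSE, ncol(X_aug)),
         degenerate = cs == 0, n_runs = n_runs, fraction = fraction,
         n_factors = as.integer(n_factors)),
    class = "stability_profile")
}

#' MC-UVE-PLS wavelength selection
#'
#' One rerun: append noise variables, compute coefficient stability over
#' `n_runs` Monte Carlo samplings, retain real wavelengths whose |stability|
#' exceeds the cutoff derived from the noise variables (by default their
#' maximum |stability|), then fit the retained set with [select_factors].
#' The whole procedure is repeated `n_reruns` times with fresh seeds and the
#' rerun with minimum final SECV is reported.
#'
#' @param data A [spectra_set].
#' @param n_runs Monte Carlo samplings per rerun; default 500.
#' @param n_reruns Independent reruns; default 50.
#' @param fraction Calibration fraction per sampling; default 0.8.
#' @param factor_grid Factor grid for the final model; default `1:30`. The
#'   factor count used inside the Monte Carlo runs is fixed beforehand at the
#'   value minimising full-data LOOCV SECV over this grid.
#' @param n_noise Number of artificial noise variables; default the number of
#'   real wavelengths.
#' @param cutoff_quantile Quantile of the noise variables' |stability| used
#'   as retention cutoff; default 1 (their maximum).
#' @param seed Master seed; rerun `r` uses `seed + r`.
#' @return A `selection_result`; `extra` holds the winning rerun's
#'   `stability_profile`, cutoff and rerun index.
#' @export
run_mcuve <- function(data, n_runs = 500L, n_reruns = 50L, fraction = 0.8,
                      factor_grid = 1:30, n_noise = NULL,
                      cutoff_quantile = 1, seed = 1L) {
  validate_spectra_set(data)
  X <- data$absorbance
  y <- data$reference
  n_noise <- n_noise %||% ncol(X)
  F_mc <- select_factors(X, y, factor_grid)$n_factors
  best <- NULL
  n_discarded <- 0L
  for (r in seq_len(n_reruns)) {
    seed_r <- as.integer(seed) + r
    aug <- augment_noise(X, n_noise, seed = seed_r)
    prof <- compute_stability(aug$X_aug, y, n_runs, fraction, F_mc,
                              seed = seed_r, noise_mask = aug$noise_mask)
    noise_stab <- abs(prof$stability[prof$noise_mask])
    cutoff <- stats::quantile(noise_stab, probs = cutoff_quantile,
                              na.rm = TRUE, names = FALSE)
    keep <- which(!prof$noise_mask &
                    !is.na(prof$stability) & abs(prof$stability) > cutoff)
    if (length(keep) == 0L) { n_discarded <- n_discarded + 1L; next }
    fit <- select_factors(X[, keep, drop = FALSE], y, factor_grid)
    if (is.null(best) || fit$secv < best$secv)
      best <- list(keep = keep, secv = fit$secv, r_pcv = fit$r_pcv,
                   n_factors = fit$n_factors, profile = prof,
                   cutoff = cutoff, rerun = r)
  }
  if (is.null(best))
    stop("every rerun retained an empty wavelength set", call. = FALSE)
  if (n_discarded > 0L)
    message("MC-UVE: ", n_discarded, " rerun(s) discarded (empty retention)")
  selection_result(
    method = "MC-UVE-PLS", wavelengths = data$wavelengths[best$keep],
    n_factors = best$n_factors, secv = best$secv, r_pcv = best$r_pcv,
    extra = list(profile = best$profile, cutoff = best$cutoff,
                 rerun = best$rerun, F_mc = F_mc,
                 n_discarded = n_discarded))
}
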