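# Moving-window PLS: exhaustive search over window start I, width N and
# factor count F, scored by LOOCV SECV. The window is N consecutive grid
# points starting at I; infeasible factor counts (F > min(n - 2, N)) are
# skipped rather than rejected, since grids routinely pair narrow windows
# with large factor ranges.

#' Enumerate feasible moving windows
#'
#' All `(I, N)` combinations whose window of `N` consecutive grid points
#' starting at wavelength `I` fits on the grid, in deterministic I-major,
#' N-minor order. Out-of-range windows are silently excluded.
#'
#' @param grid Full wavelength grid (nm), strictly increasing.
#' @param I_set Candidate initial wavelengths; must lie on the grid.
#' @param N_set Candidate window widths (number of wavelengths).
#' @return Data frame with columns `I`, `N`, `start` (grid index).
#' @export
window_grid <- function(grid, I_set, N_set) {
  grid <- as.numeric(grid)
  I_set <- sort(unique(as.numeric(I_set)))
  N_set <- sort(unique(as.integer(N_set)))
  start <- match(I_set, grid)
  if (anyNA(start))
    stop("initial wavelength(s) not on grid: ",
         paste(I_set[is.na(start)], collapse = ", "), call. = FALSE)
  out <- do.call(rbind, lapply(seq_along(I_set), function(ii) {
    ok <- N_set >= 1L & (start[ii] + N_set - 1L) <= length(grid)
    if (!any(ok)) return(NULL)
    data.frame(I = I_set[ii], N = N_set[ok], start = start[ii])
  }))
  if (is.null(out) || nrow(out) == 0L)
    stop("no feasible window for the given I_set/N_set", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Moving-window PLS search
#'
#' Evaluates every feasible `(I, N, F)` combination by PLS LOOCV and returns
#' the one with minimum SECV. Ties are broken toward smaller `N`, then
#' smaller `I`, then smaller `F`.
#'
#' @param data A [spectra_set].
#' @param I_set Candidate window starts (nm); default the full grid.
#' @param N_set Candidate window widths.
#' @param F_set Candidate factor counts; default `1:20`.
#' @param stride Subsample every `stride`-th entry of `I_set` (runtime
#'   control for large grids); default 1 traverses all starts.
#' @param keep_surface If `TRUE`, the per-window minimum-SECV surface is
#'   attached to the result trace.
#' @return A `selection_result`; its wavelengths are the winning window's
#'   grid points and `extra` holds `I` and `N`.
#' @export
search_mwpls <- function(data, I_set = NULL, N_set, F_set = 1:20, stride = 1L,
                         keep_surface = FALSE) {
  validate_spectra_set(data)
  grid <- data$wavelengths
  I_set <- I_set %||% grid
  stride <- max(1L, as.integer(stride))
  if (stride > 1L) I_set <- sort(I_set)[seq(1L, length(I_set), by = stride)]
  wins <- window_grid(grid, I_set, N_set)
  F_set <- sort(unique(as.integer(F_set)))
  n <- n_samples(data)
  best <- NULL
  surface <- if (keep_surface) vector("list", nrow(wins)) else NULL
  for (w in seq_len(nrow(wins))) {
    cols <- wins$start[w]:(wins$start[w] + wins$N[w] - 1L)
    feas <- F_set[F_set >= 1L & F_set <= min(n - 2L, wins$N[w])]
    if (length(feas) == 0L) next
    P <- loocv_predict_all(data$absorbance[, cols, drop = FALSE],
                           data$reference, max(feas))
    sec <- vapply(feas, function(f)
      sqrt(mean((P[, f] - data$reference)^2)), numeric(1))
    fbest <- which.min(sec)  # ties toward smaller F
    cand <- list(I = wins$I[w], N = wins$N[w], F = feas[fbest],
                 secv = sec[fbest], cols = cols)
    if (keep_surface)
      surface[[w]] <- data.frame(I = wins$I[w], N = wins$N[w],
                                 F = feas[fbest], secv = sec[fbest])
    if (is.null(best) || cand$secv < best$secv ||
        (cand$secv == best$secv &&
           (cand$N < best$N || (cand$N == best$N &&
              (cand$I < best$I || (cand$I == best$I && cand$F < best$F))))))
      best <- cand
  }
  if (is.null(best))
    stop("no feasible (I, N, F) combination", call. = FALSE)
  rec <- loocv_predict(data$absorbance[, best$cols, drop = FALSE],
                       data$reference, best$F)
  selection_result(
    method = "MW-PLS", wavelengths = grid[best$cols], n_factors = best$F,
    secv = secv(rec), r_pcv = r_pcv(rec),
    trace = if (keep_surface) list(surface = do.call(rbind, surface)) else NULL,
    extra = list(I = best$I, N = best$N))
}
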