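# Optimal partner wavelength combination: iterate the image of the fixed
# best-partner mapping f until the wavelength set stops shrinking. Because
# the images are nested (PWS^(t+1) is a subset of PWS^(t)) the iteration
# terminates in at most N steps, and the stable set is exactly the set of
# f-periodic wavelengths — the set on which f restricts to a bijection.

#' Project a wavelength subset through the best-partner mapping
#'
#' Returns the image `{f(lambda) : lambda in current}` of a wavelength
#' subset under a fixed [best_partner_map]. The mapping is never recomputed:
#' all iterations use the partners determined on the full grid.
#'
#' @param current Numeric vector of wavelengths (nm), a subset of
#'   `map$wavelengths`.
#' @param map A `partner_map`.
#' @return Sorted numeric vector: the deduplicated image.
#' @export
project_partners <- function(current, map) {
  stopifnot(inherits(map, "partner_map"))
  if (length(current) == 0L) return(numeric(0))
  idx <- match(current, map$wavelengths)
  if (anyNA(idx))
    stop("wavelength(s) outside map domain: ",
         paste(current[is.na(idx)], collapse = ", "), call. = FALSE)
  sort(unique(map$partner[idx]))
}

#' Run the OPWC selection
#'
#' Scores all wavelength pairs ([pairwise_scores]), builds the best-partner
#' mapping ([best_partner_map]), iterates [project_partners] starting from
#' the full grid until the set is stable, and fits the final PLS model on the
#' stable set with [select_factors].
#'
#' @param data A [spectra_set] (`n >= 4` samples, `N >= 2` wavelengths).
#' @param factor_grid Candidate PLS factor counts for the final model (and,
#'   if `trace_pls = TRUE`, for each intermediate subset); default `1:20`.
#' @param trace_pls If `TRUE`, every intermediate subset is also evaluated by
#'   PLS LOOCV so the shrinkage trace carries a per-iteration minimum SECV.
#'   Diagnostic only; does not affect the selection.
#' @param scores Optional precomputed `pair_score_matrix` (its wavelengths
#'   must match `data`), so reruns can skip the pair scan.
#' @return A `selection_result` whose `trace` holds the projection sequence:
#'   `sets` (list of wavelength vectors, starting with the full grid),
#'   `counts`, and (if traced) `per_set_secv` / `per_set_F`.
#' @export
run_opwc <- function(data, factor_grid = 1:20, trace_pls = TRUE,
                     scores = NULL) {
  validate_spectra_set(data)
  if (is.null(scores)) {
    scores <- pairwise_scores(data)
  } else {
    stopifnot(inherits(scores, "pair_score_matrix"))
    if (!identical(as.numeric(scores$wavelengths),
                   as.numeric(data$wavelengths)))
      stop("supplied scores were computed on a different wavelength grid",
           call. = FALSE)
  }
  map <- best_partner_map(scores)
  sets <- list(data$wavelengths)
  current <- data$wavelengths
  for (step in seq_len(length(data$wavelengths))) {
    nxt <- project_partners(current, map)
    if (!all(nxt %in% current))
      stop("internal error: projection image is not nested", call. = FALSE)
    sets[[length(sets) + 1L]] <- nxt
    if (length(nxt) == length(current)) break  # nested + equal count = equal set
    current <- nxt
  }
  counts <- lengths(sets)
  per_set_secv <- per_set_F <- NULL
  if (isTRUE(trace_pls)) {
    ev <- lapply(sets, function(s) {
      sel <- select_factors(subset_wavelengths(data, s)$absorbance,
                            data$reference, factor_grid)
      c(secv = sel$secv, F = sel$n_factors)
    })
    per_set_secv <- vapply(ev, `[[`, numeric(1), "secv")
    per_set_F <- as.integer(vapply(ev, `[[`, numeric(1), "F"))
  }
  stable <- sets[[length(sets)]]
  fit <- select_factors(subset_wavelengths(data, stable)$absorbance,
                        data$reference, factor_grid)
  selection_result(
    method = "OPWC-PLS", wavelengths = stable, n_factors = fit$n_factors,
    secv = fit$secv, r_pcv = fit$r_pcv,
    trace = list(sets = sets, counts = counts,
                 per_set_secv = per_set_secv, per_set_F = per_set_F),
    extra = list(map = map))
}

#' Cycle decomposition of the stable set
#'
#' Partitions a set closed under the best-partner mapping into its disjoint
#' f-cycles. On the OPWC stable set, when all finite pair scores are
#' distinct, every cycle has length exactly 2: mutual best-partner pairs.
#'
#' @param map A `partner_map`.
#' @param stable_set Wavelengths (nm) closed under the mapping.
#' @return List of numeric vectors, one per cycle, each in traversal order.
#' @export
cycle_decomposition <- function(map, stable_set) {
  stopifnot(inherits(map, "partner_map"))
  idx <- match(stable_set, map$wavelengths)
  if (anyNA(idx)) stop("stable_set contains wavelengths outside the map",
                       call. = FALSE)
  img <- map$partner_index[idx]
  if (!all(map$wavelengths[img] %in% stable_set))
    stop("stable_set is not closed under the mapping", call. = FALSE)
  if (anyDuplicated(img))
    stop("mapping is not a bijection on stable_set; run the projection to ",
         "convergence first", call. = FALSE)
  nxt <- stats::setNames(map$wavelengths[img], stable_set)
  seen <- character(0)
  cycles <- list()
  for (w in as.character(sort(stable_set))) {
    if (w %in% seen) next
    cyc <- numeric(0)
    cur <- w
    while (!cur %in% seen) {
      seen <- c(seen, cur)
      cyc <- c(cyc, as.numeric(cur))
      cur <- as.character(nxt[[cur]])
    }
    if (length(cyc) == 1L)
      stop("internal error: fixed point in partner mapping", call. = FALSE)
    cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}
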