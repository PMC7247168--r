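# Beer-Lambert synthetic spectra with known ground truth. Each mixture
# component has a pure-component absorptivity built from Gaussian bands; a
# sample's spectrum is the concentration-weighted sum of component spectra
# plus a per-sample linear baseline and additive Gaussian noise whose
# standard deviation is inflated inside declared wavelength regions (the
# detector-limited ends of a real NIR scan).

#' Build a synthetic-spectra configuration
#'
#' @param grid Numeric `c(start, stop, step)` in nm.
#' @param n_samples Number of samples.
#' @param analyte Component spec for the analyte: `list(bands, conc)`, where
#'   `bands` is a data frame with columns `center` (nm), `width` (nm, Gaussian
#'   sigma) and `height` (peak absorptivity, AU per g/L), and `conc` is
#'   `list(mean, sd, range)` (g/L, truncation range).
#' @param interferents List of component specs shaped like `analyte`.
#' @param baseline `list(offset = c(mean, sd), slope = c(mean, sd))`:
#'   per-sample additive baseline, the slope applied over the grid scaled to
#'   `[-0.5, 0.5]`.
#' @param noise `list(base_sd, regions)`: additive Gaussian noise SD (AU) and
#'   a data frame `regions` with columns `start`, `stop`, `mult` inflating
#'   the SD inside those nm ranges.
#' @param informative_threshold Fraction of the analyte's peak absorptivity
#'   above which a grid point counts as ground-truth informative; default
#'   0.05.
#' @param seed Integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(grid, n_samples, analyte, interferents = list(),
                         baseline = list(offset = c(0, 0), slope = c(0, 0)),
                         noise = list(base_sd = 0, regions = NULL),
                         informative_threshold = 0.05, seed = 1L) {
  stopifnot(length(grid) == 3, grid[3] > 0, grid[2] > grid[1], n_samples >= 1)
  wl <- seq(grid[1], grid[2], by = grid[3])
  check_component <- function(comp, label) {
    b <- comp$bands
    stopifnot(is.data.frame(b), all(c("center", "width", "height") %in% names(b)))
    if (any(b$center < min(wl) | b$center > max(wl)))
      stop("band center outside grid for component '", label, "'",
           call. = FALSE)
    if (any(b$width <= 0) || any(b$height < 0))
      stop("bands need positive width and non-negative height (", label, ")",
           call. = FALSE)
    cc <- comp$conc
    stopifnot(is.list(cc), !is.null(cc$mean), !is.null(cc$sd))
    rng <- cc$range %||% c(-Inf, Inf)
    if (cc$mean < rng[1] || cc$mean > rng[2])
      stop("truncation range excludes the mean for component '", label, "'",
           call. = FALSE)
    invisible(TRUE)
  }
  check_component(analyte, "analyte")
  for (i in seq_along(interferents))
    check_component(interferents[[i]], paste0("interferent", i))
  if (!is.null(noise$regions))
    stopifnot(all(c("start", "stop", "mult") %in% names(noise$regions)))
  stopifnot(noise$base_sd >= 0)
  structure(
    list(grid = grid, wavelengths = wl, n_samples = as.integer(n_samples),
         analyte = analyte, interferents = interferents, baseline = baseline,
         noise = noise, informative_threshold = informative_threshold,
         seed = as.integer(seed)),
    class = "synth_config")
}

#' Pure-component spectrum from Gaussian bands
#'
#' @param bands Data frame with columns `center`, `width`, `height`.
#' @param wavelengths Grid (nm).
#' @return Non-negative absorptivity vector over the grid (sum of bands).
#' @export
component_spectrum <- function(bands, wavelengths) {
  out <- numeric(length(wavelengths))
  for (i in seq_len(nrow(bands)))
    out <- out + bands$height[i] *
      exp(-0.5 * ((wavelengths - bands$center[i]) / bands$width[i])^2)
  out
}

rtruncnorm1 <- function(n, mean, sd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Simulate a spectra set with ground truth
#'
#' Draws concentrations for every component, builds absorbance as the
#' Beer-Lambert mixture plus baseline and heteroscedastic noise, and reports
#' the ground-truth informative wavelength mask (grid points where the
#' analyte absorptivity exceeds `informative_threshold` of its peak).
#'
#' @param config A [synth_config].
#' @return List with `data` (a [spectra_set], reference = analyte
#'   concentration), `concentrations` (matrix, one column per component),
#'   `informative_mask` (logical over the grid) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  wl <- config$wavelengths
  n <- config$n_samples
  comps <- c(list(analyte = config$analyte), config$interferents)
  eps <- vapply(comps, function(cp) component_spectrum(cp$bands, wl),
                numeric(length(wl)))
  out <- with_seed(config$seed, {
    conc <- vapply(comps, function(cp) {
      cc <- cp$conc
      rtruncnorm1(n, cc$mean, cc$sd, cc$range %||% c(-Inf, Inf))
    }, numeric(n))
    A <- conc %*% t(eps)
    off <- stats::rnorm(n, config$baseline$offset[1], config$baseline$offset[2])
    slp <- stats::rnorm(n, config$baseline$slope[1], config$baseline$slope[2])
    u <- (wl - min(wl)) / (max(wl) - min(wl)) - 0.5
    A <- A + outer(off, rep(1, length(wl))) + outer(slp, u)
    sd_wl <- rep(config$noise$base_sd, length(wl))
    reg <- config$noise$regions
    if (!is.null(reg)) for (i in seq_len(nrow(reg)))
      sd_wl[wl >= reg$start[i] & wl <= reg$stop[i]] <-
        config$noise$base_sd * reg$mult[i]
    if (any(sd_wl > 0))
      A <- A + matrix(stats::rnorm(n * length(wl)), n) %*% diag(sd_wl)
    list(conc = conc, A = A)
  })
  mask <- eps[, 1] >= config$informative_threshold * max(eps[, 1])
  list(data = spectra_set(wl, out$A, out$conc[, 1]),
       concentrations = out$conc, informative_mask = mask, config = config)
}

#' Serum-like preset configuration
#'
#' A 780-2498 nm grid with a 2 nm step (860 points), 230 samples, an analyte
#' distributed as a truncated normal matching a clinical serum-globulin
#' panel (mean 27.477, SD 3.953, range 18.70-41.60 g/L), analyte absorption
#' bands inside 1500-1850 and 2100-2350 nm, two partially overlapping
#' interferents (an albumin-like protein and a dominant water-like matrix),
#' and strongly inflated noise near 2000 and 2400 nm.
#'
#' @param seed Integer seed stored in the configuration.
#' @return A [synth_config].
#' @export
serum_preset <- function(seed = 42L) {
  synth_config(
    grid = c(780, 2498, 2), n_samples = 230L,
    analyte = list(
      bands = data.frame(
        center = c(1540, 1690, 1740, 2180, 2290),
        width  = c(25, 40, 30, 30, 35),
        height = c(0.0030, 0.0040, 0.0035, 0.0030, 0.0025)),
      conc = list(mean = 27.477, sd = 3.953, range = c(18.70, 41.60))),
    interferents = list(
      albumin = list(
        bands = data.frame(
          center = c(1515, 1700, 2170, 2310),
          width  = c(35, 45, 40, 30),
          height = c(0.0025, 0.0030, 0.0025, 0.0020)),
        conc = list(mean = 45, sd = 3.5, range = c(30, 60))),
      lipid = list(
        bands = data.frame(
          center = c(1725, 2145, 2255),
          width  = c(25, 35, 40),
          height = c(0.0040, 0.0045, 0.0035)),
        conc = list(mean = 6, sd = 1.5, range = c(2, 12))),
      protein_residual = list(
        bands = data.frame(
          center = c(1555, 1660, 1760, 2210, 2330),
          width  = c(28, 35, 30, 32, 28),
          height = c(0.0020, 0.0025, 0.0020, 0.0025, 0.0020)),
        conc = list(mean = 10, sd = 2, range = c(4, 16))),
      glucose = list(
        bands = data.frame(
          center = c(1585, 2125, 2275),
          width  = c(25, 28, 30),
          height = c(0.0040, 0.0050, 0.0040)),
        conc = list(mean = 1.4, sd = 0.4, range = c(0.4, 3))),
      water = list(
        bands = data.frame(
          center = c(980, 1440, 1970),
          width  = c(50, 50, 60),
          height = c(0.0004, 0.0008, 0.0025)),
        conc = list(mean = 950, sd = 10, range = c(900, 1000)))),
    baseline = list(offset = c(0.10, 0.05), slope = c(0, 0.05)),
    noise = list(base_sd = 0.003,
                 regions = data.frame(start = c(1950, 2350),
                                      stop = c(2050, 2450),
                                      mult = c(100, 100))),
    seed = seed)
}

#' Tiny preset configuration
#'
#' A small, fast analogue of [serum_preset] (40-point grid, 30 samples) used
#' for smoke tests and command-line examples.
#'
#' @param seed Integer seed.
#' @return A [synth_config].
#' @export
tiny_preset <- function(seed = 42L) {
  synth_config(
    grid = c(1500, 1578, 2), n_samples = 30L,
    analyte = list(
      bands = data.frame(center = c(1520, 1560), width = c(8, 6),
                         height = c(0.004, 0.003)),
      conc = list(mean = 27.477, sd = 3.953, range = c(18.70, 41.60))),
    interferents = list(
      one = list(
        bands = data.frame(center = 1540, width = 12, height = 0.003),
        conc = list(mean = 45, sd = 3.5, range = c(30, 60)))),
    baseline = list(offset = c(0.05, 0.01), slope = c(0, 0.005)),
    noise = list(base_sd = 0.002, regions = NULL),
    seed = seed)
}
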