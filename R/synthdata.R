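#' Compound specification for the synthetic design
#'
#' Describes one drug's physicochemical descriptors, its factorial
#' temperature-pressure design, and the solubility range the noiseless
#' surface is calibrated to attain over that design.
#'
#' @param name Compound label.
#' @param molecular_weight g/mol, positive.
#' @param melting_point Degrees Celsius.
#' @param temperature_levels Strictly increasing kelvin levels.
#' @param pressure_levels Strictly increasing MPa levels.
#' @param target_min,target_max Solubility calibration anchors, (g/L) x 10,
#'   with 0 < target_min < target_max.
#' @param cells Optional two-column matrix/data.frame of (temperature,
#'   pressure) design cells; defaults to the full factorial grid. Used for
#'   non-factorial designs.
#' @return A `compound_spec` list.
#' @export
compound_spec <- function(name, molecular_weight, melting_point,
                          temperature_levels, pressure_levels,
                          target_min, target_max, cells = NULL) {
  stopifnot(molecular_weight > 0,
            all(diff(temperature_levels) > 0), all(diff(pressure_levels) > 0),
            target_min > 0, target_max > target_min)
  if (is.null(cells)) {
    cells <- expand.grid(temperature = temperature_levels,
                         pressure = pressure_levels)
  }
  cells <- as.data.frame(cells)
  names(cells) <- c("temperature", "pressure")
  structure(list(name = name, molecular_weight = molecular_weight,
                 melting_point = melting_point,
                 temperature_levels = temperature_levels,
                 pressure_levels = pressure_levels,
                 target_min = target_min, target_max = target_max,
                 cells = cells),
            class = "compound_spec")
}

# The 19-run non-factorial design for the fourth compound: the unique 5-cell
# removal from the 4 x 6 grid (grid corners pinned) whose remaining 19 cells
# reproduce the published per-level means and population SDs of temperature
# (321.4211, 5.6318) and pressure (19.4736, 3.8541) to < 1e-4.
sirolimus_cells <- function() {
  grid <- expand.grid(temperature = c(313, 318, 323, 328),
                      pressure = c(12.5, 15, 17.5, 20, 22.5, 25))
  removed <- data.frame(temperature = c(318, 323, 313, 318, 313),
                        pressure = c(12.5, 12.5, 15, 15, 25))
  keep <- !(paste(grid$temperature, grid$pressure) %in%
              paste(removed$temperature, removed$pressure))
  grid[keep, ]
}

#' Default compound specifications of the study design
#'
#' Four lipophilic drugs on their factorial temperature-pressure grids:
#' three compounds on {308,318,328,338} K x {12,15,...,30} MPa (28 cells
#' each) and Sirolimus on a fixed 19-cell subset of {313..328} K x
#' {12.5..25} MPa, 103 design cells in total. Solubility anchors are each
#' compound's published min/max in (g/L) x 10.
#'
#' @return List of [compound_spec()] objects.
#' @export
default_compounds <- function() {
  T4 <- c(308, 318, 328, 338)
  P7 <- c(12, 15, 18, 21, 24, 27, 30)
  list(
    compound_spec("Tacrolimus", 804.03, 128, T4, P7, 0.029, 0.235),
    compound_spec("Rifampin", 822.95, 185, T4, P7, 0.109, 2.983),
    compound_spec("Teriflunomide", 270.21, 230, T4, P7, 0.127, 3.212),
    compound_spec("Sirolimus", 914.172, 183,
                  c(313, 318, 323, 328), c(12.5, 15, 17.5, 20, 22.5, 25),
                  0.2122, 0.4567, cells = sirolimus_cells())
  )
}

#' Generator configuration
#'
#' @param compounds List of [compound_spec()]; default [default_compounds()].
#' @param noise_cv Multiplicative lognormal noise as a coefficient of
#'   variation; default 0.05 (5% relative scatter, typical of static
#'   gravimetric solubility measurements). 0 gives the noiseless surface.
#' @param seed Integer master seed; one RNG stream is derived per compound
#'   so adding compounds never perturbs existing ones.
#' @return A `generator_config` list.
#' @export
generator_config <- function(compounds = default_compounds(),
                             noise_cv = 0.05, seed = 1) {
  stopifnot(noise_cv >= 0, length(compounds) >= 1)
  structure(list(compounds = compounds, noise_cv = noise_cv, seed = seed),
            class = "generator_config")
}

#' CO2 density proxy
#'
#' Smooth analytic surrogate for supercritical CO2 density: a logistic rise
#' in pressure centered at the critical pressure (7.38 MPa), scaled by the
#' inverse reduced temperature Tc/T (Tc = 304.1 K). Strictly increasing in
#' pressure at fixed temperature, strictly decreasing in temperature at
#' fixed pressure, and positive — the only properties downstream code relies
#' on; it is not an equation of state.
#'
#' @param temperature Kelvin, positive.
#' @param pressure MPa, positive.
#' @return Dimensionless positive proxy.
#' @export
density_proxy <- function(temperature, pressure) {
  if (any(temperature <= 0) || any(pressure <= 0)) {
    stop_ghef("temperature and pressure must be positive")
  }
  stats::plogis((pressure - 7.38) / 5) * (304.1 / temperature)
}

#' Calibrate the log-linear solubility surface of a compound
#'
#' The noiseless surface is Chrastil-style log-linear,
#' `ln y = a * ln(proxy(T, P)) + b / T + c`. Calibration pins the surface to
#' `target_min` at the (min T, min P) design corner and `target_max` at
#' (max T, max P): the density exponent `a` is fixed from the pressure-range
#' log-ratio at the mid temperature (scaled by 0.8 so pressure carries 80%
#' of the dynamic range and temperature the rest), then (b, c) solve the
#' 2 x 2 linear anchor system. The resulting surface is strictly increasing
#' in pressure and, for the default designs, in temperature, so the design
#' corners are its grid extremes.
#'
#' @param spec A [compound_spec()].
#' @return List with elements a, b, c (class `surface_coefficients`).
#' @export
calibrate_surface <- function(spec) {
  stopifnot(inherits(spec, "compound_spec"))
  if (nrow(spec$cells) < 2) stop_ghef("degenerate design: need at least 2 cells")
  Tmin <- min(spec$temperature_levels); Tmax <- max(spec$temperature_levels)
  Pmin <- min(spec$pressure_levels); Pmax <- max(spec$pressure_levels)
  Tmid <- (Tmin + Tmax) / 2
  log_range <- log(spec$target_max / spec$target_min)
  a <- 0.8 * log_range /
    log(density_proxy(Tmid, Pmax) / density_proxy(Tmid, Pmin))
  a <- max(a, 1e-12)
  # anchor system for (b, c):
  #   log(ymin) = a*log(proxy(Tmin,Pmin)) + b/Tmin + c
  #   log(ymax) = a*log(proxy(Tmax,Pmax)) + b/Tmax + c
  r1 <- log(spec$target_min) - a * log(density_proxy(Tmin, Pmin))
  r2 <- log(spec$target_max) - a * log(density_proxy(Tmax, Pmax))
  b <- (r2 - r1) / (1 / Tmax - 1 / Tmin)
  c <- r1 - b / Tmin
  structure(list(a = a, b = b, c = c), class = "surface_coefficients")
}

#' Evaluate the noiseless solubility surface
#'
#' @param coeffs A `surface_coefficients` from [calibrate_surface()].
#' @param temperature Kelvin.
#' @param pressure MPa.
#' @return Solubility in (g/L) x 10, positive.
#' @export
true_solubility_surface <- function(coeffs, temperature, pressure) {
  stopifnot(inherits(coeffs, "surface_coefficients"))
  exp(coeffs$a * log(density_proxy(temperature, pressure)) +
        coeffs$b / temperature + coeffs$c)
}

#' Generate a synthetic solubility dataset
#'
#' One record per (compound, temperature, pressure) design cell with
#' solubility = surface value x exp(eps), eps ~ Normal(0, sigma^2) and
#' sigma = log(1 + noise_cv), so generated values are positive and the
#' relative scatter is approximately `noise_cv`. `noise_cv = 0` returns the
#' noiseless surface exactly. Deterministic given the config seed.
#'
#' @param config A [generator_config()].
#' @return A [solubility_dataset()] (103 records for the default design).
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  sigma <- log(1 + config$noise_cv)
  parts <- lapply(config$compounds, function(spec) {
    coeffs <- calibrate_surface(spec)
    cells <- spec$cells
    y0 <- true_solubility_surface(coeffs, cells$temperature, cells$pressure)
    eps <- if (sigma > 0) {
      with_seed(derive_seed(config$seed, "compound", spec$name),
                stats::rnorm(nrow(cells), 0, sigma))
    } else rep(0, nrow(cells))
    data.frame(compound = spec$name,
               temperature = cells$temperature,
               pressure = cells$pressure,
               molecular_weight = spec$molecular_weight,
               melting_point = spec$melting_point,
               solubility = y0 * exp(eps),
               stringsAsFactors = FALSE)
  })
  solubility_dataset(do.call(rbind, parts),
                     provenance = sprintf("synthetic (noise_cv=%g, seed=%d)",
                                          config$noise_cv, config$seed))
}
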