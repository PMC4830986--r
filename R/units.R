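#' Convert a mixing ratio to a molecular number density
#'
#' Converts a mole-fraction mixing ratio (e.g. an NO2 level given in ppmv or
#' ppbv, expressed as a dimensionless fraction) to an absolute number density
#' via the ideal gas law, n = x P / (k_B T).
#'
#' All internal kinetics in this package are done in number-density units
#' (molecules m^-3); ppmv/ppbv appear only at the I/O boundary. Convenience
#' wrappers [ppmv_to_number_density()] and [ppbv_to_number_density()] apply
#' the 1e-6 / 1e-9 scaling.
#'
#' @param x mixing ratio as a dimensionless mole fraction, in `[0, 1]`.
#' @param temperature gas temperature in kelvin.
#' @param pressure total pressure in pascal.
#' @return Number density in molecules per cubic metre.
#' @export
#' @examples
#' mixing_ratio_to_number_density(3e-6)   # 3 ppmv NO2 at 298.15 K, 1 atm
mixing_ratio_to_number_density <- function(x, temperature = .T_DEFAULT,
                                           pressure = .P_DEFAULT) {
  if (!all(is.finite(x)) || any(x < 0))
    stop("mixing ratio `x` must be a finite mole fraction >= 0 ",
         "(ppmv and ppbv values must be scaled by 1e-6 / 1e-9 first)")
  if (any(x > 1))
    stop("mixing ratio `x` exceeds 1: it must be a dimensionless mole ",
         "fraction, not a ppmv/ppbv value")
  if (!all(is.finite(temperature)) || any(temperature <= 0))
    stop("`temperature` must be finite and positive (kelvin)")
  if (!all(is.finite(pressure)) || any(pressure <= 0))
    stop("`pressure` must be finite and positive (pascal)")
  x * pressure / (codata$k_B * temperature)
}

#' @rdname mixing_ratio_to_number_density
#' @param ppmv,ppbv mixing ratio in parts per million / billion by volume.
#' @export
ppmv_to_number_density <- function(ppmv, temperature = .T_DEFAULT,
                                   pressure = .P_DEFAULT) {
  mixing_ratio_to_number_density(ppmv * 1e-6, temperature, pressure)
}

#' @rdname mixing_ratio_to_number_density
#' @export
ppbv_to_number_density <- function(ppbv, temperature = .T_DEFAULT,
                                   pressure = .P_DEFAULT) {
  mixing_ratio_to_number_density(ppbv * 1e-9, temperature, pressure)
}

#' Mean thermal speed of a gas molecule
#'
#' Gas-kinetic molecular speed at temperature `T`. The `"mean"` convention is
#' the Maxwell-Boltzmann mean speed sqrt(8RT/(pi M)) that enters the standard
#' collision-flux expression; `"rms"` is the root-mean-square speed
#' sqrt(3RT/M). The mean convention is the default; both are provided because
#' published uptake coefficients are sometimes better reproduced under one or
#' the other (see the package vignette).
#'
#' @param molar_mass molar mass in kg mol^-1 (NO2: 0.0460055).
#' @param temperature temperature in kelvin.
#' @param convention `"mean"` (default) or `"rms"`.
#' @return Speed in m s^-1.
#' @export
#' @examples
#' mean_thermal_speed(0.0460055, 298.15)          # ~370 m/s
#' mean_thermal_speed(0.0460055, 298.15, "rms")   # ~402 m/s
mean_thermal_speed <- function(molar_mass, temperature = .T_DEFAULT,
                               convention = c("mean", "rms")) {
  convention <- match.arg(convention)
  if (!all(is.finite(molar_mass)) || any(molar_mass <= 0))
    stop("`molar_mass` must be finite and positive (kg mol^-1)")
  if (!all(is.finite(temperature)) || any(temperature <= 0))
    stop("`temperature` must be finite and positive (kelvin)")
  switch(convention,
    mean = sqrt(8 * codata$R * temperature / (pi * molar_mass)),
    rms  = sqrt(3 * codata$R * temperature / molar_mass)
  )
}

#' Gas-phase reaction conditions
#'
#' Bundles temperature, pressure and an NO2 mixing ratio into a validated
#' object carrying the derived number density. Exactly one of `mixing_ratio`,
#' `ppmv` or `ppbv` must be given.
#'
#' @param mixing_ratio dimensionless mole fraction in `[0, 1]`.
#' @param ppmv,ppbv alternative ways to give the mixing ratio.
#' @param temperature kelvin; default 298.15 (reactor conditions).
#' @param pressure pascal; default 101325.
#' @return An object of class `"gas_conditions"`: a list with elements
#'   `temperature`, `pressure`, `mixing_ratio` and `number_density`
#'   (molecules m^-3).
#' @export
#' @examples
#' gas_conditions(ppmv = 3)
#' gas_conditions(ppbv = 50)$number_density
gas_conditions <- function(mixing_ratio = NULL, ppmv = NULL, ppbv = NULL,
                           temperature = .T_DEFAULT, pressure = .P_DEFAULT) {
  given <- c(!is.null(mixing_ratio), !is.null(ppmv), !is.null(ppbv))
  if (sum(given) != 1L)
    stop("give exactly one of `mixing_ratio`, `ppmv`, `ppbv`")
  x <- if (!is.null(mixing_ratio)) mixing_ratio
       else if (!is.null(ppmv)) ppmv * 1e-6
       else ppbv * 1e-9
  nd <- mixing_ratio_to_number_density(x, temperature, pressure)
  structure(
    list(temperature = temperature, pressure = pressure,
         mixing_ratio = x, number_density = nd),
    class = "gas_conditions"
  )
}

#' @export
print.gas_conditions <- function(x, ...) {
  cat(sprintf("Gas conditions: %.5g ppbv (x = %.3g) at %.2f K, %.0f Pa\n",
              x$mixing_ratio * 1e9, x$mixing_ratio, x$temperature, x$pressure))
  cat(sprintf("  number density: %.4g molecules m^-3\n", x$number_density))
  invisible(x)
}

#' Physical properties of a molecular species
#'
#' @param molar_mass molar mass in kg mol^-1.
#' @param cross_section effective molecular cross-section in m^2 (the
#'   surface footprint used for coverage and collision calculations).
#' @return An object of class `"species_properties"`.
#' @export
#' @examples
#' species_properties(0.0460055, 0.8e-18)  # NO2 mass, Py cross-section
species_properties <- function(molar_mass, cross_section) {
  if (!is.finite(molar_mass) || molar_mass <= 0)
    stop("`molar_mass` must be finite and positive (kg mol^-1)")
  if (!is.finite(cross_section) || cross_section <= 0)
    stop("`cross_section` must be finite and positive (m^2)")
  structure(list(molar_mass = molar_mass, cross_section = cross_section),
            class = "species_properties")
}
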