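#' Apparent reaction probability (reactive uptake coefficient)
#'
#' Converts an observed pseudo-first-order rate constant for the loss of
#' surface-bound pyrene into the apparent reaction probability
#' \eqn{\gamma = 4 k_{obs} / (\sigma\, \omega\, [NO_2(g)])}: the fraction of
#' NO2-surface collisions with an adsorbed Py molecule that removes the Py.
#' The denominator is the per-molecule collision frequency
#' \eqn{(\omega/4)\,[NO_2(g)]\,\sigma}, with \eqn{\omega} the thermal speed
#' of NO2 and \eqn{\sigma} the effective Py cross-section.
#'
#' @param k_obs observed rate constant, s^-1 (vectorised).
#' @param gas [gas_conditions()] giving the NO2 number density.
#' @param species [species_properties()] carrying the NO2 molar mass and the
#'   Py cross-section; defaults to NO2 (0.0460055 kg/mol) with
#'   sigma = 0.8 nm^2.
#' @param convention thermal-speed convention passed to
#'   [mean_thermal_speed()]; `"mean"` (default) or `"rms"`.
#' @return Dimensionless gamma. Values above 1 are unphysical for a true
#'   uptake probability and trigger a warning, but are returned (gamma here
#'   is an effective, apparent quantity).
#' @export
#' @examples
#' # ambient extrapolation: k_obs predicted at 50 ppbv NO2
#' reaction_probability(6.7e-5, gas_conditions(ppbv = 50))  # ~7.3e-7
reaction_probability <- function(k_obs, gas,
                                 species = species_properties(.M_NO2, .SIGMA_PY),
                                 convention = c("mean", "rms")) {
  convention <- match.arg(convention)
  if (!all(is.finite(k_obs)) || any(k_obs < 0))
    stop("`k_obs` must be finite and >= 0 (s^-1)")
  if (!inherits(gas, "gas_conditions"))
    stop("`gas` must be a gas_conditions object")
  if (gas$number_density <= 0)
    stop("gamma is undefined at zero NO2 number density")
  omega <- mean_thermal_speed(species$molar_mass, gas$temperature, convention)
  g <- 4 * k_obs / (species$cross_section * omega * gas$number_density)
  if (any(g > 1))
    warning("gamma > 1: more reactive loss than collisions; ",
            "apparent probability is unphysical as a true uptake coefficient")
  g
}

#' Initial fractional surface coverage of pyrene
#'
#' Monolayer-packing estimate \eqn{\theta_{Py,0} = L\, N_A\, \sigma / A_{BET}}
#' for a loading of `L` mol of Py per gram of substrate spread over the BET
#' specific surface area. No surface-roughness or pore-accessibility
#' correction is applied. Kinetics are coverage-independent only in the
#' submonolayer regime, so analyses warn when theta >= 1.
#'
#' @param loading Py loading in mol per gram of substrate
#'   (1 nmol/mg = 1e-6 mol/g).
#' @param sigma effective Py cross-section in m^2 (default 0.8 nm^2).
#' @param bet_area BET specific surface area in m^2 per gram.
#' @return Dimensionless fractional coverage.
#' @export
#' @examples
#' surface_coverage(1e-6, bet_area = 20)  # ~0.024 for CDD-like dust
surface_coverage <- function(loading, sigma = .SIGMA_PY, bet_area) {
  if (!all(is.finite(loading)) || any(loading < 0))
    stop("`loading` must be finite and >= 0 (mol per g)")
  if (!all(is.finite(sigma)) || any(sigma <= 0))
    stop("`sigma` must be finite and positive (m^2)")
  if (!all(is.finite(bet_area)) || any(bet_area <= 0))
    stop("`bet_area` must be finite and positive (m^2 per g); a zero BET ",
         "area leaves the coverage undefined")
  theta <- loading * codata$N_A * sigma / bet_area
  if (any(theta >= 1))
    warning("theta >= 1: multilayer loading; pseudo-first-order surface ",
            "kinetics assume a submonolayer")
  theta
}

#' e-folding lifetime of particle-bound pyrene
#'
#' \eqn{\tau = 1 / k_{obs}}, the time for the surface-bound Py amount to fall
#' to 1/e of its initial value under pseudo-first-order loss.
#'
#' @param k_obs rate constant in s^-1; must be > 0.
#' @return An object of class `"py_lifetime"`: the lifetime in seconds, with
#'   an `hours` attribute and a print method showing both.
#' @export
#' @examples
#' lifetime(6.7e-5)   # ~4.1 h: dust-surface nitration competes with gas-phase OH loss
lifetime <- function(k_obs) {
  if (!is.finite(k_obs) || k_obs <= 0)
    stop("`k_obs` must be finite and > 0 (s^-1) for a finite lifetime")
  tau <- 1 / k_obs
  structure(tau, hours = tau / 3600, class = "py_lifetime")
}

#' @export
print.py_lifetime <- function(x, ...) {
  cat(sprintf("lifetime: %.4g s (%.2f h)\n", unclass(x), attr(x, "hours")))
  invisible(x)
}

#' Per-substrate kinetic summary table
#'
#' Builds the standard per-substrate summary: observed rate constant,
#' apparent reaction probability at the exposure conditions, degradation and
#' 1-NP yield at 2 h, DNP flag, and initial Py coverage.
#'
#' @param substrate character vector of substrate labels.
#' @param k_obs,k_obs_se rate constants and their standard errors, s^-1.
#' @param gas [gas_conditions()] of the exposure (common to all rows).
#' @param py_loading Py loading, mol per g (optional, for theta).
#' @param bet_area BET area, m^2 per g (optional, for theta).
#' @param d_py,y_1np,dnp optional benchmark summaries to carry through.
#' @param convention thermal-speed convention for gamma.
#' @return A data frame of class `"substrate_table"` with columns in SI
#'   units: `substrate`, `k_obs`, `k_obs_se`, `gamma`, `gamma_se`, `d_py`,
#'   `y_1np`, `dnp`, `theta0`.
#' @export
substrate_table <- function(substrate, k_obs, k_obs_se = NA_real_, gas,
                            py_loading = NA_real_, bet_area = NA_real_,
                            d_py = NA_real_, y_1np = NA_real_,
                            dnp = NA_character_,
                            convention = c("mean", "rms")) {
  convention <- match.arg(convention)
  gamma <- reaction_probability(k_obs, gas, convention = convention)
  gamma_se <- ifelse(is.na(k_obs_se), NA_real_,
                     gamma * ifelse(k_obs > 0, k_obs_se / k_obs, 0))
  theta0 <- ifelse(is.na(py_loading) | is.na(bet_area), NA_real_,
                   loading_theta(py_loading, bet_area))
  out <- data.frame(substrate = substrate, k_obs = k_obs,
                    k_obs_se = rep_len(k_obs_se, length(k_obs)),
                    gamma = gamma, gamma_se = gamma_se,
                    d_py = rep_len(d_py, length(k_obs)),
                    y_1np = rep_len(y_1np, length(k_obs)),
                    dnp = rep_len(dnp, length(k_obs)), theta0 = theta0)
  class(out) <- c("substrate_table", "data.frame")
  attr(out, "convention") <- convention
  out
}

# vectorised theta without the multilayer warning (table rows may be NA)
loading_theta <- function(loading, bet_area, sigma = .SIGMA_PY) {
  loading * codata$N_A * sigma / bet_area
}

#' Consistency of a printed kinetics table with collision theory
#'
#' For each row of a per-substrate table of (k_obs, gamma) pairs, recomputes
#' gamma from k_obs under both thermal-speed conventions and reports the
#' relative deviation from the tabulated gamma and which convention
#' reproduces it more closely. Used to audit published tables where the
#' speed convention behind the collision-frequency constant is not stated.
#'
#' @param k_obs observed rate constants, s^-1.
#' @param gamma_printed tabulated gamma values (same length).
#' @param gas [gas_conditions()] of the exposure.
#' @param species [species_properties()] for the collision pair.
#' @return Data frame with per-row `gamma_mean`, `gamma_rms`, relative errors
#'   `rel_err_mean`, `rel_err_rms`, and `best_convention`.
#' @export
gamma_consistency <- function(k_obs, gamma_printed, gas,
                              species = species_properties(.M_NO2, .SIGMA_PY)) {
  gm <- reaction_probability(k_obs, gas, species, "mean")
  gr <- reaction_probability(k_obs, gas, species, "rms")
  em <- gm / gamma_printed - 1
  er <- gr / gamma_printed - 1
  data.frame(
    k_obs = k_obs, gamma_printed = gamma_printed,
    gamma_mean = gm, gamma_rms = gr,
    rel_err_mean = em, rel_err_rms = er,
    best_convention = ifelse(abs(er) <= abs(em), "rms", "mean")
  )
}
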