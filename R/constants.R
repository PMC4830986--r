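#' Physical constants (CODATA 2018)
#'
#' Exact SI values of the constants used throughout the package. Since the
#' 2019 SI redefinition \code{k_B} and \code{N_A} are exact; \code{R} is their
#' product.
#'
#' @format A named list:
#' \describe{
#'   \item{k_B}{Boltzmann constant, 1.380649e-23 J K^-1 (exact)}
#'   \item{R}{molar gas constant, 8.31446261815324 J mol^-1 K^-1 (exact)}
#'   \item{N_A}{Avogadro constant, 6.02214076e23 mol^-1 (exact)}
#' }
#' @export
#' @examples
#' codata$k_B * codata$N_A == codata$R
codata <- list(
  k_B = 1.380649e-23,
  R   = 8.31446261815324,
  N_A = 6.02214076e23
)

# Default reaction conditions: flow reactor at 298 K, 1 atm.
.T_DEFAULT <- 298.15
.P_DEFAULT <- 101325

# NO2 molar mass (kg mol^-1) and effective pyrene cross-section (m^2):
# sigma_Py ~ 0.8 nm^2 is the literature value for a flat-lying Py molecule.
.M_NO2     <- 0.0460055
.SIGMA_PY  <- 0.8e-18
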