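#' @keywords internal
# deterministic child seed per named stream, kept inside 32-bit integer range
.child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

#' Scenario for a synthetic pyrene decay experiment
#'
#' Describes one simulated flow-reactor run with known ground truth. The
#' defaults emulate the reference desert-dust experiment: k_true = 8.6e-4
#' s^-1 (the observed rate on Chinese desert dust at 3 ppmv NO2), no
#' plateau, triplicate measurements with 5% multiplicative noise, and a
#' sampling grid over 0-4 h that always contains the 2 h (7200 s) benchmark
#' point.
#'
#' @param k_true true rate constant, s^-1.
#' @param plateau_true true residual unreactive fraction in `[0, 1)`.
#' @param times sampling times in seconds; 7200 s is appended if missing.
#' @param replicates number of independent replicates per time point.
#' @param noise_cv coefficient of variation of the multiplicative Gaussian
#'   measurement noise (0 = noiseless).
#' @param no2_ppmv NO2 exposure level recorded in the series conditions.
#' @param substrate substrate label.
#' @param products if `TRUE`, generate 1-NP and DNP product tracks from a
#'   two-step consecutive first-order scheme (Py -> 1-NP -> DNP).
#' @param np_branching fraction of reacted Py that forms 1-NP.
#' @param k_dnp rate constant of the 1-NP -> DNP step, s^-1.
#' @param seed integer seed; generation is a pure function of
#'   (scenario, seed).
#' @return An object of class `"decay_scenario"`.
#' @export
decay_scenario <- function(k_true = 8.6e-4, plateau_true = 0,
                           times = c(0, 600, 1800, 3600, 7200, 10800, 14400),
                           replicates = 3, noise_cv = 0.05, no2_ppmv = 3,
                           substrate = "synthetic dust", products = FALSE,
                           np_branching = 0.6, k_dnp = 5e-5, seed = 1L) {
  stopifnot(k_true >= 0, plateau_true >= 0, plateau_true < 1,
            replicates >= 1, noise_cv >= 0)
  if (!7200 %in% times) times <- sort(c(times, 7200))
  structure(
    list(k_true = k_true, plateau_true = plateau_true, times = sort(times),
         replicates = as.integer(replicates), noise_cv = noise_cv,
         no2_ppmv = no2_ppmv, substrate = substrate, products = products,
         np_branching = np_branching, k_dnp = k_dnp, seed = as.integer(seed)),
    class = "decay_scenario"
  )
}

#' Generate a synthetic pyrene decay series
#'
#' Draws a [decay_series()] from a [decay_scenario()]:
#' \eqn{f = [p + (1-p) e^{-kt}](1+\epsilon)} with
#' \eqn{\epsilon \sim N(0, cv^2)}, clipped at 0. Product tracks, when
#' requested, follow the consecutive scheme Py -> 1-NP -> DNP with yield
#' fractions from the closed-form two-step solution scaled by the branching
#' ratio, plus the same multiplicative noise. Output is reproducible and
#' byte-identical for a fixed scenario.
#'
#' @param scenario a [decay_scenario()].
#' @return A [decay_series()].
#' @export
#' @examples
#' s <- generate_decay_series(decay_scenario(noise_cv = 0, seed = 7))
#' fit_decay(s)
generate_decay_series <- function(scenario) {
  stopifnot(inherits(scenario, "decay_scenario"))
  sc <- scenario
  t <- rep(sc$times, each = sc$replicates)
  repl <- rep(seq_len(sc$replicates), times = length(sc$times))
  mu <- sc$plateau_true + (1 - sc$plateau_true) * exp(-sc$k_true * t)

  set.seed(.child_seed(sc$seed, "decay"))
  eps <- if (sc$noise_cv > 0) stats::rnorm(length(t), 0, sc$noise_cv) else 0
  y <- pmax(mu * (1 + eps), 0)

  products <- NULL
  if (sc$products) {
    k1 <- sc$k_true; k2 <- sc$k_dnp
    # reacted fraction feeding products; two-step solution for intermediate
    np <- if (abs(k1 - k2) < 1e-15) {
      sc$np_branching * k1 * t * exp(-k1 * t)
    } else {
      sc$np_branching * k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
    }
    dnp <- sc$np_branching * (1 - exp(-k1 * t)) - np
    set.seed(.child_seed(sc$seed, "products"))
    e2 <- if (sc$noise_cv > 0)
      stats::rnorm(2 * length(t), 0, sc$noise_cv) else 0
    yf <- pmax(c(np, dnp) * (1 + e2), 0)
    products <- data.frame(
      time_s = rep(t, 2),
      species = rep(c("1-NP", "DNP"), each = length(t)),
      yield_fraction = yf, replicate = rep(repl, 2)
    )
  }
  suppressWarnings(decay_series(
    t, y, replicate = repl, substrate = sc$substrate,
    conditions = gas_conditions(ppmv = sc$no2_ppmv), products = products
  ))
}

#' Generate a synthetic k_obs-versus-NO2 rate curve
#'
#' Evaluates a known mechanism truth at the requested NO2 levels and applies
#' multiplicative Gaussian noise; the reported SE column is set to
#' `k_obs * noise_cv` (the generative noise scale), so inverse-variance
#' weighting in [fit_mechanism()] is well defined.
#'
#' @param model `"LH"` or `"N2O4"` functional form of the truth.
#' @param k_max,K true parameters (K in m^3 for LH, m^6 for N2O4).
#' @param no2_ppmv NO2 levels in ppmv.
#' @param noise_cv coefficient of variation of the noise (0 = noiseless).
#' @param seed integer seed.
#' @param substrate label.
#' @param temperature,pressure conversion conditions.
#' @return A [rate_curve()].
#' @export
#' @examples
#' generate_rate_curve("LH", 1e-3, 2e-20, c(1, 3, 6, 12, 24), 0.1, seed = 1)
generate_rate_curve <- function(model = c("LH", "N2O4"), k_max, K,
                                no2_ppmv = c(0.5, 1, 3, 6, 12, 24),
                                noise_cv = 0, seed = 1L,
                                substrate = "synthetic dust",
                                temperature = .T_DEFAULT,
                                pressure = .P_DEFAULT) {
  model <- match.arg(model)
  stopifnot(k_max > 0, K > 0, noise_cv >= 0)
  c_ <- ppmv_to_number_density(no2_ppmv, temperature, pressure)
  k <- .mech_forms[[model]]$f(c_, k_max, K)
  set.seed(.child_seed(as.integer(seed), "rate_curve"))
  if (noise_cv > 0)
    k <- pmax(k * (1 + stats::rnorm(length(k), 0, noise_cv)), 1e-12)
  se <- if (noise_cv > 0) k * noise_cv else NA_real_
  rate_curve(k, c_, k_obs_se = se, substrate = substrate)
}

#' Scenario for a synthetic field campaign
#'
#' Describes a cascade-impactor sampling campaign with a prescribed dust
#' enhancement of the 1-NP/BkF ratio in coarse size fractions. Defaults
#' emulate a month-long urban campaign with a five-stage impactor
#' (>7.0, 3.3-7.0, 2.0-3.3, 1.1-2.0, <=1.1 um), 2-3 day sampling periods
#' (10 periods), a heavy-dust episode in 2 periods, and log-normal
#' concentration scatter.
#'
#' @param n_periods number of sampling periods.
#' @param dust_periods integer indices of the heavy-dust periods.
#' @param low_dust_periods indices labelled `"low"`; remaining periods are
#'   `"none"`.
#' @param size_fractions data frame with columns `lo_um`, `hi_um` (lower and
#'   upper aerodynamic-diameter bounds).
#' @param baseline_bkf median BkF concentration per fraction, pg m^-3.
#' @param baseline_ratio true 1-NP/BkF ratio absent dust chemistry.
#' @param dust_enhancement multiplicative ratio enhancement applied only in
#'   heavy-dust periods to fractions whose lower bound is at or above
#'   `coarse_cutoff_um` (>= 1; 1 = null case).
#' @param coarse_cutoff_um coarse-fraction cutoff in um.
#' @param lognormal_sigma log-scale sd of the concentration noise.
#' @param seed integer seed.
#' @return An object of class `"field_scenario"`.
#' @export
field_scenario <- function(n_periods = 10, dust_periods = c(7, 8),
                           low_dust_periods = c(6, 9),
                           size_fractions = data.frame(
                             lo_um = c(7.0, 3.3, 2.0, 1.1, 0),
                             hi_um = c(30, 7.0, 3.3, 2.0, 1.1)),
                           baseline_bkf = 50, baseline_ratio = 0.05,
                           dust_enhancement = 5, coarse_cutoff_um = 2.0,
                           lognormal_sigma = 0.3, seed = 1L) {
  stopifnot(n_periods >= 1, dust_enhancement >= 1, lognormal_sigma >= 0,
            all(dust_periods %in% seq_len(n_periods)),
            all(size_fractions$lo_um < size_fractions$hi_um))
  structure(
    list(n_periods = as.integer(n_periods),
         dust_periods = as.integer(dust_periods),
         low_dust_periods = as.integer(low_dust_periods),
         size_fractions = size_fractions, baseline_bkf = baseline_bkf,
         baseline_ratio = baseline_ratio,
         dust_enhancement = dust_enhancement,
         coarse_cutoff_um = coarse_cutoff_um,
         lognormal_sigma = lognormal_sigma, seed = as.integer(seed)),
    class = "field_scenario"
  )
}

#' Generate a synthetic size-fractionated field dataset
#'
#' Per period and size fraction draws BkF from a log-normal around the
#' baseline and sets 1-NP = BkF x baseline ratio x (enhancement if the
#' period is a heavy-dust period and the fraction is coarse) x log-normal
#' noise. Deterministic for a fixed scenario.
#'
#' @param scenario a [field_scenario()].
#' @return A data frame of class `"field_samples"` with columns
#'   `period`, `fraction_lo_um`, `fraction_hi_um`, `conc_1np`, `conc_bkf`
#'   (pg m^-3) and `dust_label` (`"heavy"`, `"low"`, `"none"`).
#' @export
#' @examples
#' head(generate_field_dataset(field_scenario(seed = 3)))
generate_field_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "field_scenario"))
  sc <- scenario
  fr <- sc$size_fractions
  grid <- expand.grid(period = seq_len(sc$n_periods),
                      frac = seq_len(nrow(fr)))
  lab <- rep("none", sc$n_periods)
  lab[sc$low_dust_periods] <- "low"
  lab[sc$dust_periods] <- "heavy"

  set.seed(.child_seed(sc$seed, "field"))
  n <- nrow(grid)
  bkf <- sc$baseline_bkf *
    exp(stats::rnorm(n, -sc$lognormal_sigma^2 / 2, sc$lognormal_sigma))
  coarse <- fr$lo_um[grid$frac] >= sc$coarse_cutoff_um
  enh <- ifelse(lab[grid$period] == "heavy" & coarse,
                sc$dust_enhancement, 1)
  ratio_noise <-
    exp(stats::rnorm(n, -sc$lognormal_sigma^2 / 2, sc$lognormal_sigma))
  np <- bkf * sc$baseline_ratio * enh * ratio_noise

  out <- data.frame(
    period = sprintf("P%02d", grid$period),
    fraction_lo_um = fr$lo_um[grid$frac],
    fraction_hi_um = fr$hi_um[grid$frac],
    conc_1np = np, conc_bkf = bkf,
    dust_label = lab[grid$period]
  )
  out <- out[order(grid$period, -fr$lo_um[grid$frac]), ]
  rownames(out) <- NULL
  class(out) <- c("field_samples", "data.frame")
  attr(out, "coarse_cutoff_um") <- sc$coarse_cutoff_um
  out
}
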