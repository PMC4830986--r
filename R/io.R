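#' Read and write pyrene decay measurements as CSV
#'
#' Comma-separated, header row, UTF-8, "." decimal. Decay files carry
#' `substrate,no2_ppmv,time_s,py_fraction,replicate`; product files carry
#' `substrate,time_s,species,yield_fraction,replicate`. A decay file may
#' contain several substrates and NO2 levels; [read_decay_csv()] returns one
#' [decay_series()] per (substrate, NO2 level) combination.
#'
#' @param path file path.
#' @param products_path optional product-yield CSV merged into the matching
#'   series.
#' @return A named list of [decay_series()] objects
#'   (`"<substrate>@<ppmv>ppmv"`).
#' @export
read_decay_csv <- function(path, products_path = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("substrate", "no2_ppmv", "time_s", "py_fraction", "replicate")
  if (!all(need %in% names(d)))
    stop("decay CSV needs columns: ", paste(need, collapse = ", "))
  pr <- NULL
  if (!is.null(products_path)) {
    pr <- utils::read.csv(products_path, stringsAsFactors = FALSE)
    pneed <- c("substrate", "time_s", "species", "yield_fraction", "replicate")
    if (!all(pneed %in% names(pr)))
      stop("product CSV needs columns: ", paste(pneed, collapse = ", "))
  }
  key <- interaction(d$substrate, d$no2_ppmv, drop = TRUE)
  out <- lapply(split(d, key), function(g) {
    prod_g <- if (!is.null(pr)) {
      pg <- pr[pr$substrate == g$substrate[1],
               c("time_s", "species", "yield_fraction", "replicate")]
      if (nrow(pg)) pg else NULL
    } else NULL
    suppressWarnings(decay_series(
      g$time_s, g$py_fraction, g$replicate, substrate = g$substrate[1],
      conditions = gas_conditions(ppmv = g$no2_ppmv[1]), products = prod_g
    ))
  })
  names(out) <- vapply(out, function(s)
    sprintf("%s@%gppmv", s$substrate, s$conditions$mixing_ratio * 1e6), "")
  out
}

#' @rdname read_decay_csv
#' @param series a [decay_series()] or list of them.
#' @export
write_decay_csv <- function(series, path, products_path = NULL) {
  if (inherits(series, "decay_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(substrate = s$substrate,
               no2_ppmv = if (is.null(s$conditions)) NA_real_
                          else s$conditions$mixing_ratio * 1e6,
               s$data)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  if (!is.null(products_path)) {
    prows <- do.call(rbind, lapply(series, function(s) {
      if (is.null(s$products)) return(NULL)
      data.frame(substrate = s$substrate, s$products)
    }))
    if (!is.null(prows))
      utils::write.csv(prows[c("substrate", "time_s", "species",
                               "yield_fraction", "replicate")],
                       products_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read and write rate curves as CSV
#'
#' Columns: `substrate,no2_ppmv,k_obs_s,k_obs_se`. One [rate_curve()] per
#' substrate is returned.
#'
#' @param path file path.
#' @return Named list of [rate_curve()] objects.
#' @export
read_rate_curve_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("substrate", "no2_ppmv", "k_obs_s")
  if (!all(need %in% names(d)))
    stop("rate-curve CSV needs columns: ", paste(need, collapse = ", "))
  if (is.null(d$k_obs_se)) d$k_obs_se <- NA_real_
  lapply(split(d, d$substrate), function(g)
    rate_curve(g$k_obs_s, no2_ppmv = g$no2_ppmv, k_obs_se = g$k_obs_se,
               substrate = g$substrate[1]))
}

#' @rdname read_rate_curve_csv
#' @param curves a [rate_curve()] or list of them.
#' @export
write_rate_curve_csv <- function(curves, path) {
  if (inherits(curves, "rate_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(substrate = attr(cv, "substrate"),
               no2_ppmv = cv$no2_number_density /
                 ppmv_to_number_density(1),
               k_obs_s = cv$k_obs, k_obs_se = cv$k_obs_se)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write field impactor tables as CSV
#'
#' Columns: `period_start,period_end,fraction_lo_um,fraction_hi_um,
#' conc_1np,conc_bkf,dust_label`. Concentrations in pg m^-3. In-memory
#' tables carry a single `period` label; the writer duplicates it into the
#' start/end columns when no explicit dates are present, and the reader
#' collapses identical start/end back to one label.
#'
#' @param path file path.
#' @return A data frame of class `"field_samples"`.
#' @export
read_field_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("period_start", "period_end", "fraction_lo_um", "fraction_hi_um",
            "conc_1np", "conc_bkf", "dust_label")
  if (!all(need %in% names(d)))
    stop("field CSV needs columns: ", paste(need, collapse = ", "))
  d$period <- ifelse(d$period_start == d$period_end, d$period_start,
                     paste(d$period_start, d$period_end, sep = "/"))
  out <- d[c("period", "fraction_lo_um", "fraction_hi_um",
             "conc_1np", "conc_bkf", "dust_label")]
  class(out) <- c("field_samples", "data.frame")
  out
}

#' @rdname read_field_csv
#' @param samples a `field_samples` data frame.
#' @export
write_field_csv <- function(samples, path) {
  p <- strsplit(as.character(samples$period), "/", fixed = TRUE)
  out <- data.frame(
    period_start = vapply(p, `[`, "", 1),
    period_end = vapply(p, function(x) x[length(x)], ""),
    samples[c("fraction_lo_um", "fraction_hi_um", "conc_1np", "conc_bkf",
              "dust_label")]
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reference per-substrate kinetics table
#'
#' Loads the bundled published per-substrate summary for the reaction of
#' surface-bound Py with 3 ppmv NO2 at 298 K: observed rate constants,
#' apparent reaction probabilities, 2 h degradation percentages and 1-NP
#' yields, DNP flags, and initial Py coverages for 19 mineral and reference
#' substrates. The file stores the printed scaling (k_obs x 1e5, gamma x
#' 1e8, theta x 1e2); this reader converts to SI.
#'
#' @return Data frame with columns `substrate`, `k_obs`, `k_obs_se` (s^-1),
#'   `gamma`, `gamma_se`, `d_py`, `y_1np` (percent), `dnp` (`"+"`/`"-"`),
#'   `theta0`.
#' @export
#' @examples
#' head(reference_substrate_table())
reference_substrate_table <- function() {
  path <- system.file("extdata", "table1_substrates.csv",
                      package = "dustnitro", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(
    substrate = d$substrate,
    k_obs = d$k_obs_1e5 * 1e-5, k_obs_se = d$k_obs_se_1e5 * 1e-5,
    gamma = d$gamma_1e8 * 1e-8, gamma_se = d$gamma_se_1e8 * 1e-8,
    d_py = d$d_py_pct, y_1np = d$y_1np_pct, dnp = d$dnp,
    theta0 = d$theta0_1e2 * 1e-2
  )
}
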