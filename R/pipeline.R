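# polynomial rolling hash (mod 2^31 - 1) over the deparsed config: a stable,
# dependency-free provenance fingerprint
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.provenance <- function(config, seed = NULL) {
  list(package = "dustnitro",
       version = as.character(utils::packageVersion("dustnitro")),
       config_hash = .config_hash(config), seed = seed)
}

#' Run configuration for the analysis pipeline
#'
#' Assembles (and validates defaults for) the options shared by
#' [run_kinetics()], [run_field()] and [run_synthesize()]. A configuration
#' can also be loaded from a JSON file.
#'
#' @param decay_csv path to a decay-measurement CSV ([read_decay_csv()]).
#' @param products_csv optional product-yield CSV.
#' @param rate_curve_csv optional k_obs-vs-NO2 CSV ([read_rate_curve_csv()]);
#'   when absent, rate curves are assembled from the per-NO2-level decay
#'   fits.
#' @param field_csv path to a field impactor CSV ([read_field_csv()]).
#' @param temperature,pressure gas conditions (K, Pa).
#' @param convention thermal-speed convention for gamma.
#' @param reference_ppbv ambient NO2 mixing ratio for the extrapolation
#'   (ppbv; default 50, a typical urban level).
#' @param discrimination_ppbv low-concentration reference for mechanism
#'   discrimination (ppbv).
#' @param coarse_cutoff_um coarse-fraction cutoff for the field analysis.
#' @param seed integer seed for any synthesis steps.
#' @param out_dir output directory (created if needed); `NULL` disables
#'   file output.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(decay_csv = NULL, products_csv = NULL,
                       rate_curve_csv = NULL, field_csv = NULL,
                       temperature = .T_DEFAULT, pressure = .P_DEFAULT,
                       convention = c("mean", "rms"), reference_ppbv = 50,
                       discrimination_ppbv = 100, coarse_cutoff_um = 2.0,
                       seed = 1L, out_dir = NULL) {
  convention <- match.arg(convention)
  structure(
    list(decay_csv = decay_csv, products_csv = products_csv,
         rate_curve_csv = rate_curve_csv, field_csv = field_csv,
         temperature = temperature, pressure = pressure,
         convention = convention, reference_ppbv = reference_ppbv,
         discrimination_ppbv = discrimination_ppbv,
         coarse_cutoff_um = coarse_cutoff_um, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path JSON file with any subset of the `run_config` fields.
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' Kinetics pipeline: decay fits, collision theory, mechanism, extrapolation
#'
#' End-to-end composition of the kinetic stages. Ingests decay CSVs per
#' substrate and NO2 level, fits each series with automatic simple/plateau
#' selection, assembles the per-substrate summary (k_obs, gamma, 2 h
#' degradation and 1-NP yield, DNP flag), builds k_obs-vs-NO2 curves
#' (from `rate_curve_csv` when given, else from the per-level decay fits),
#' runs mechanism discrimination where at least 4 NO2 levels exist, and
#' extrapolates the preferred-mechanism fit to the ambient reference level
#' (k_obs with delta-method SE, gamma, lifetime).
#'
#' @param config a [run_config()] with at least `decay_csv` set.
#' @return A list of class `"kinetics_run"`: `summary` (per-substrate data
#'   frame), `fits` (decay fits per series), `mechanism` (per-substrate
#'   [compare_mechanisms()] results), `extrapolation` (per-substrate data
#'   frame with `k_obs`, `k_obs_se`, `gamma`, `lifetime_s`, `lifetime_h`),
#'   `provenance`. When `out_dir` is set, writes `substrate_summary.csv`,
#'   `mechanism_<substrate>.json`, `extrapolation.csv` and
#'   `provenance.json`.
#' @export
run_kinetics <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$decay_csv)) stop("config$decay_csv is required")
  series <- read_decay_csv(config$decay_csv, config$products_csv)

  fits <- lapply(series, fit_decay)
  meta <- do.call(rbind, lapply(names(series), function(nm) {
    s <- series[[nm]]
    f <- fits[[nm]]
    data.frame(
      key = nm, substrate = s$substrate,
      no2_ppmv = s$conditions$mixing_ratio * 1e6,
      k_obs = f$k_obs, k_obs_se = f$k_obs_se, model = f$model,
      plateau = f$plateau,
      d_py = tryCatch(degradation_percent(s), error = function(e) NA_real_),
      y_1np = tryCatch(product_yield(s, "1-NP"),
                       error = function(e) NA_real_),
      dnp = if (is.null(s$products)) NA_character_ else dnp_formed(s)
    )
  }))

  # per-substrate summary at the highest common exposure level
  summ <- do.call(rbind, lapply(split(meta, meta$substrate), function(g) {
    g <- g[order(-g$no2_ppmv), ][1, ]
    gas <- gas_conditions(ppmv = g$no2_ppmv, temperature = config$temperature,
                          pressure = config$pressure)
    gamma <- reaction_probability(g$k_obs, gas,
                                  convention = config$convention)
    data.frame(g[c("substrate", "no2_ppmv", "k_obs", "k_obs_se", "model",
                   "plateau", "d_py", "y_1np", "dnp")],
               gamma = gamma,
               gamma_se = ifelse(g$k_obs > 0,
                                 gamma * g$k_obs_se / g$k_obs, 0))
  }))
  rownames(summ) <- NULL

  # rate curves: provided file wins, else assembled from decay fits
  curves <- if (!is.null(config$rate_curve_csv)) {
    read_rate_curve_csv(config$rate_curve_csv)
  } else {
    lapply(split(meta, meta$substrate), function(g) {
      if (length(unique(g$no2_ppmv)) < 3L) return(NULL)
      rate_curve(g$k_obs, no2_ppmv = g$no2_ppmv, k_obs_se = g$k_obs_se,
                 substrate = g$substrate[1],
                 temperature = config$temperature,
                 pressure = config$pressure)
    })
  }
  curves <- Filter(Negate(is.null), curves)

  mech <- lapply(curves, function(cv) {
    if (length(unique(cv$no2_number_density)) < 4L) return(NULL)
    compare_mechanisms(cv, ref_ppbv = config$discrimination_ppbv,
                       temperature = config$temperature,
                       pressure = config$pressure)
  })
  mech <- Filter(Negate(is.null), mech)

  gas_ref <- gas_conditions(ppbv = config$reference_ppbv,
                            temperature = config$temperature,
                            pressure = config$pressure)
  extrap <- do.call(rbind, lapply(names(mech), function(nm) {
    cmp <- mech[[nm]]
    f <- cmp$fits[[cmp$preferred]]
    if (inherits(f, "error")) return(NULL)
    p <- predict(f, gas_ref$number_density)
    tau <- lifetime(p$k_obs)
    data.frame(substrate = nm, model = cmp$preferred,
               no2_ppbv = config$reference_ppbv,
               k_obs = p$k_obs, k_obs_se = p$se,
               gamma = reaction_probability(p$k_obs, gas_ref,
                                            convention = config$convention),
               lifetime_s = as.numeric(tau), lifetime_h = attr(tau, "hours"))
  }))

  out <- structure(
    list(summary = summ, fits = fits, series_table = meta,
         mechanism = mech, extrapolation = extrap,
         provenance = .provenance(config, config$seed)),
    class = "kinetics_run"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summ, file.path(config$out_dir,
                                     "substrate_summary.csv"),
                     row.names = FALSE)
    for (nm in names(mech))
      mech_report_json(mech[[nm]],
                       file.path(config$out_dir,
                                 sprintf("mechanism_%s.json",
                                         gsub("[^A-Za-z0-9]+", "_", nm))))
    if (!is.null(extrap))
      utils::write.csv(extrap, file.path(config$out_dir,
                                         "extrapolation.csv"),
                       row.names = FALSE)
    writeLines(jsonlite::toJSON(out$provenance, auto_unbox = TRUE,
                                pretty = TRUE),
               file.path(config$out_dir, "provenance.json"))
  }
  out
}

#' @export
print.kinetics_run <- function(x, ...) {
  cat("Kinetics run:", nrow(x$summary), "substrate(s)\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$extrapolation) && nrow(x$extrapolation)) {
    cat("\nAmbient extrapolation:\n")
    print(x$extrapolation, row.names = FALSE)
  }
  invisible(x)
}

#' Field pipeline: 1-NP/BkF dust-effect analysis
#'
#' Reads a field impactor CSV and produces the [dust_effect_report()];
#' writes `dust_report.json` and `provenance.json` when `out_dir` is set.
#'
#' @param config a [run_config()] with `field_csv` set.
#' @return The [dust_effect_report()], with a `provenance` attribute.
#' @export
run_field <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$field_csv)) stop("config$field_csv is required")
  samples <- read_field_csv(config$field_csv)
  rep_ <- dust_effect_report(samples,
                             coarse_cutoff_um = config$coarse_cutoff_um)
  attr(rep_, "provenance") <- .provenance(config, config$seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    dust_report_json(rep_, file.path(config$out_dir, "dust_report.json"))
    writeLines(jsonlite::toJSON(attr(rep_, "provenance"), auto_unbox = TRUE,
                                pretty = TRUE),
               file.path(config$out_dir, "provenance.json"))
  }
  rep_
}

#' Synthesize a complete set of pipeline input fixtures
#'
#' Writes, for a named list of scenarios, the CSV files the readers consume:
#' decay series (plus products), rate curves, and field tables. All files
#' are deterministic in the scenario seeds.
#'
#' @param config a [run_config()] with `out_dir` set.
#' @param decay_scenarios list of [decay_scenario()] objects (may be empty).
#' @param rate_truths list of lists with fields `model`, `k_max`, `K`,
#'   `no2_ppmv`, `noise_cv`, `substrate` for [generate_rate_curve()].
#' @param field_scenarios list of [field_scenario()] objects.
#' @return Character vector of the files written (empty scenarios, no
#'   files).
#' @export
run_synthesize <- function(config, decay_scenarios = list(),
                           rate_truths = list(), field_scenarios = list()) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  if (length(decay_scenarios)) {
    series <- lapply(decay_scenarios, generate_decay_series)
    dp <- file.path(config$out_dir, "decay.csv")
    pp <- file.path(config$out_dir, "products.csv")
    has_products <- any(!vapply(lapply(series, `[[`, "products"), is.null,
                                logical(1)))
    write_decay_csv(series, dp, if (has_products) pp)
    written <- c(written, dp, if (has_products) pp)
  }
  if (length(rate_truths)) {
    curves <- lapply(rate_truths, function(tr) {
      tr$seed <- if (is.null(tr$seed)) config$seed else tr$seed
      do.call(generate_rate_curve, tr)
    })
    rp <- file.path(config$out_dir, "rate_curves.csv")
    write_rate_curve_csv(curves, rp)
    written <- c(written, rp)
  }
  if (length(field_scenarios)) {
    fields <- do.call(rbind, lapply(field_scenarios,
                                    generate_field_dataset))
    fp <- file.path(config$out_dir, "field.csv")
    write_field_csv(fields, fp)
    written <- c(written, fp)
  }
  invisible(written)
}
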