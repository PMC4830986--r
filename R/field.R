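#' 1-NP / BkF concentration ratio
#'
#' Ratio of 1-nitropyrene to benzo[k]fluoranthene, the source-normalised
#' indicator of secondary 1-NP formation: BkF is essentially unreactive and
#' non-volatile, so if the (shared, combustion-dominated) sources do not
#' change, the ratio only moves when 1-NP is produced on the particles.
#' A zero or missing BkF concentration yields `NA` (never infinity); callers
#' exclude and count such samples.
#'
#' @param conc_1np,conc_bkf concentrations in the same units (vectorised),
#'   or a data frame with these columns as the first argument.
#' @return Dimensionless ratio(s), `NA` where BkF is 0 or missing.
#' @export
#' @examples
#' ratio_1np_bkf(2, 4)          # 0.5
#' ratio_1np_bkf(2, 0)          # NA, not Inf
ratio_1np_bkf <- function(conc_1np, conc_bkf = NULL) {
  if (is.data.frame(conc_1np)) {
    df <- conc_1np
    conc_bkf <- df$conc_bkf
    conc_1np <- df$conc_1np
  }
  if (any(conc_1np < 0, na.rm = TRUE) || any(conc_bkf < 0, na.rm = TRUE))
    stop("concentrations must be >= 0")
  ifelse(is.na(conc_bkf) | conc_bkf <= 0, NA_real_, conc_1np / conc_bkf)
}

#' Classify sampling periods by dust load
#'
#' Threshold rule standing in for external storm reports: a period is
#' `"heavy"` when its mean dust concentration is at or above
#' `heavy_threshold`, `"low"` when below that but at or above
#' `low_threshold`, else `"none"`.
#'
#' @param dust mean aeolian-dust (or PM10 surrogate) concentration per
#'   period, ug m^-3.
#' @param heavy_threshold,low_threshold classification thresholds, ug m^-3.
#' @return Character vector of labels, same length as `dust` (empty input
#'   gives an empty vector).
#' @export
classify_periods <- function(dust, heavy_threshold = 500,
                             low_threshold = 100) {
  if (low_threshold > heavy_threshold)
    stop("`low_threshold` must not exceed `heavy_threshold`")
  if (length(dust) == 0L) return(character(0))
  ifelse(dust >= heavy_threshold, "heavy",
         ifelse(dust >= low_threshold, "low", "none"))
}

#' Mann-Whitney U test with exact enumeration
#'
#' Rank-sum test for a location difference between two independent samples.
#' U is computed from rank sums using midranks for ties. The p-value is
#' exact — by enumeration of all `choose(n_a + n_b, n_a)` equally likely
#' assignments of the pooled ranks — whenever `n_a + n_b <= exact_limit` and
#' the pooled values contain no ties; otherwise a normal approximation with
#' tie correction and continuity correction is used. The two-sided p-value
#' is twice the smaller one-sided value, capped at 1.
#'
#' @param a,b numeric samples (each nonempty).
#' @param alternative `"two.sided"` (default), `"greater"` (a tends larger),
#'   or `"less"`.
#' @param exact_limit largest pooled size for which enumeration is used.
#' @return A list of class `"mwu_test"`: `U` (statistic of sample `a`),
#'   `p_value`, `method` (`"exact"` or `"normal_approx"`), `alternative`,
#'   `n_a`, `n_b`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4), "less")   # U = 0, exact p = 1/6
mann_whitney_u <- function(a, b,
                           alternative = c("two.sided", "greater", "less"),
                           exact_limit = 12L) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a == 0L || n_b == 0L) stop("both samples must be nonempty")
  pooled <- c(a, b)
  r <- rank(pooled)                       # midranks for ties
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  N <- n_a + n_b

  if (length(unique(pooled)) == 1L) {
    return(structure(list(U = U, p_value = 1, method = "degenerate",
                          alternative = alternative, n_a = n_a, n_b = n_b),
                     class = "mwu_test"))
  }

  if (!ties && N <= exact_limit) {
    # exact null distribution of U by enumeration of rank assignments to a
    idx <- utils::combn(N, n_a)
    Us <- colSums(matrix(r[idx], nrow = n_a)) - n_a * (n_a + 1) / 2
    p_less <- mean(Us <= U)
    p_greater <- mean(Us >= U)
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma <- sqrt(n_a * n_b / 12 * ((N + 1) - tie_corr))
    if (sigma == 0) {
      p_less <- p_greater <- 1
    } else {
      p_less <- stats::pnorm((U - mu + 0.5) / sigma)
      p_greater <- stats::pnorm((U - mu - 0.5) / sigma,
                                lower.tail = FALSE)
    }
    method <- "normal_approx"
  }
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two.sided = min(2 * min(p_less, p_greater), 1))
  structure(list(U = U, p_value = p, method = method,
                 alternative = alternative, n_a = n_a, n_b = n_b),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s, %s): U = %g, p = %.4g  (n = %d, %d)\n",
              x$method, x$alternative, x$U, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Dust-storm effect on size-fractionated 1-NP/BkF ratios
#'
#' Summarises 1-NP/BkF ratios by size fraction and dust label and tests
#' whether ratios during heavy-dust periods differ from those during
#' non-/low-dust periods with the exact Mann-Whitney U test — over all
#' fractions and restricted to the coarse fractions (lower diameter bound at
#' or above `coarse_cutoff_um`), where wind-blown mineral dust concentrates.
#'
#' @param samples a data frame with columns `fraction_lo_um`,
#'   `fraction_hi_um`, `conc_1np`, `conc_bkf`, `dust_label` (e.g. from
#'   [generate_field_dataset()] or [read_field_csv()]).
#' @param coarse_cutoff_um coarse-fraction cutoff, um (default 2.0).
#' @param alternative sidedness of the tests (two-sided default).
#' @return An object of class `"dust_report"`: list with `by_fraction`
#'   (median ratio per fraction and label), `test_overall` and
#'   `test_coarse` ([mann_whitney_u()] results), `n_excluded` (samples
#'   dropped for zero/missing BkF) and `coarse_cutoff_um`.
#' @export
dust_effect_report <- function(samples, coarse_cutoff_um = 2.0,
                               alternative = "two.sided") {
  need <- c("fraction_lo_um", "conc_1np", "conc_bkf", "dust_label")
  if (!all(need %in% names(samples)))
    stop("`samples` needs columns: ", paste(need, collapse = ", "))
  ratio <- ratio_1np_bkf(samples$conc_1np, samples$conc_bkf)
  keep <- !is.na(ratio)
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    message(n_excluded, " sample(s) excluded for zero/missing BkF")
  s <- samples[keep, ]
  ratio <- ratio[keep]
  heavy <- s$dust_label == "heavy"
  if (!any(heavy) || all(heavy))
    stop("need samples in both the heavy and the non-/low-dust group")
  coarse <- s$fraction_lo_um >= coarse_cutoff_um

  frac_lab <- sprintf("%g-%g um", s$fraction_lo_um, s$fraction_hi_um)
  by_fraction <- stats::aggregate(
    ratio, by = list(fraction = frac_lab, dust_label = s$dust_label),
    FUN = stats::median)
  names(by_fraction)[3] <- "median_ratio"

  test_overall <- mann_whitney_u(ratio[heavy], ratio[!heavy], alternative)
  test_coarse <- if (any(heavy & coarse) && any(!heavy & coarse))
    mann_whitney_u(ratio[heavy & coarse], ratio[!heavy & coarse], alternative)
  else NULL

  structure(
    list(by_fraction = by_fraction, test_overall = test_overall,
         test_coarse = test_coarse, n_excluded = n_excluded,
         coarse_cutoff_um = coarse_cutoff_um,
         n_heavy = sum(heavy), n_other = sum(!heavy)),
    class = "dust_report"
  )
}

#' @export
print.dust_report <- function(x, ...) {
  cat("1-NP/BkF dust-effect report\n")
  cat(sprintf("  %d heavy-dust vs %d non-/low-dust samples (%d excluded)\n",
              x$n_heavy, x$n_other, x$n_excluded))
  cat("  median ratios by size fraction and dust label:\n")
  print(x$by_fraction, row.names = FALSE)
  cat("  all fractions:    "); print(x$test_overall)
  if (!is.null(x$test_coarse)) {
    cat(sprintf("  coarse (>= %g um): ", x$coarse_cutoff_um))
    print(x$test_coarse)
  }
  invisible(x)
}

#' Serialise a dust-effect report to JSON
#'
#' @param x a [dust_effect_report()] result.
#' @param path optional output file.
#' @return JSON string (invisibly if written to `path`).
#' @export
dust_report_json <- function(x, path = NULL) {
  tj <- function(t) if (is.null(t)) NULL else
    list(U = t$U, p_value = t$p_value, method = t$method,
         alternative = t$alternative, n = c(t$n_a, t$n_b))
  obj <- list(by_fraction = x$by_fraction,
              test_overall = tj(x$test_overall),
              test_coarse = tj(x$test_coarse),
              n_excluded = x$n_excluded,
              coarse_cutoff_um = x$coarse_cutoff_um)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
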