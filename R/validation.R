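#' Validation acceptance criteria
#'
#' Thresholds against which each validation parameter is judged. Defaults are
#' the conventional ICH Q2 assay criteria: |r| > 0.998, r2 > 0.995, mean
#' recovery within 98-102% (inclusive), %RSD < 2.0, robustness |di| < 2, plus
#' flags requiring the intercept CI to contain 0 and the slope CI to contain 1.
#'
#' @param r_min Minimum |r|.
#' @param r2_min Minimum r2.
#' @param recovery_low,recovery_high Inclusive mean-recovery bounds, percent.
#' @param rsd_max Maximum %RSD.
#' @param abs_diff_max Maximum robustness |di|, percent.
#' @param require_ci_beta0_contains_zero Require CI(beta0) to contain 0.
#' @param require_ci_beta1_contains_one Require CI(beta1) to contain 1.
#' @return A list of class `validation_criteria`.
#' @export
validation_criteria <- function(r_min = 0.998, r2_min = 0.995,
                                recovery_low = 98, recovery_high = 102,
                                rsd_max = 2.0, abs_diff_max = 2.0,
                                require_ci_beta0_contains_zero = TRUE,
                                require_ci_beta1_contains_one = TRUE) {
  if (recovery_low >= recovery_high) stop("recovery bounds must be ordered")
  if (r_min <= 0 || r2_min <= 0 || rsd_max <= 0 || abs_diff_max <= 0) {
    stop("thresholds must be positive")
  }
  structure(list(r_min = r_min, r2_min = r2_min,
                 recovery_low = recovery_low, recovery_high = recovery_high,
                 rsd_max = rsd_max, abs_diff_max = abs_diff_max,
                 require_ci_beta0_contains_zero = require_ci_beta0_contains_zero,
                 require_ci_beta1_contains_one = require_ci_beta1_contains_one),
            class = "validation_criteria")
}

#' Calibration table
#'
#' Long-format calibration data: one row per (level, replicate) measurement.
#' `kind = "system"` means pure-standard calibration (response is a peak
#' area); `kind = "method"` means analyte-fortified placebos (response is a
#' peak area to be converted to a found concentration, or a found
#' concentration directly).
#'
#' @param level_ug_ml Nominal concentration, ug/ml (> 0).
#' @param replicate Replicate index.
#' @param response Measured response (area units or found concentration).
#' @param kind `"system"` or `"method"`.
#' @return A `data.frame` with class `calibration_table`.
#' @export
calibration_table <- function(level_ug_ml, replicate, response,
                              kind = c("system", "method")) {
  kind <- match.arg(kind)
  df <- data.frame(level_ug_ml = as.numeric(level_ug_ml),
                   replicate = as.integer(replicate),
                   response = as.numeric(response))
  if (any(df$level_ug_ml <= 0)) stop("concentrations must be positive")
  if (length(unique(df$level_ug_ml)) < 3L) stop("need at least 3 distinct levels")
  counts <- table(df$level_ug_ml)
  attr(df, "balanced") <- length(unique(counts)) == 1L
  attr(df, "kind") <- kind
  class(df) <- c("calibration_table", "data.frame")
  df
}

#' Read a calibration CSV
#'
#' Schema: columns `level_ug_ml, replicate, area, kind` (header required; the
#' `area` column carries the response).
#' @param path File path.
#' @return A [calibration_table].
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("level_ug_ml", "replicate", "area", "kind")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("calibration CSV missing columns: ", paste(miss, collapse = ", "))
  kind <- unique(df$kind)
  if (length(kind) != 1L) stop("calibration CSV mixes kinds")
  calibration_table(df$level_ug_ml, df$replicate, df$area, kind = kind)
}

ci_contains <- function(ci, value, tol = 1e-8) {
  # pad by a small numerical tolerance so that degenerate zero-width
  # intervals from exact fits compare sanely
  if (anyNA(ci)) return(FALSE)
  pad <- tol * max(1, abs(ci))
  ci[1] - pad <= value && value <= ci[2] + pad
}

#' System linearity assessment
#'
#' OLS of response on concentration for a pure-standard calibration. Reports
#' r, r2, the %RSD of the response factors (response/concentration), the
#' confidence interval of the intercept, and pass/fail flags against the
#' supplied criteria.
#'
#' @param table A [calibration_table] of kind `"system"`.
#' @param criteria A [validation_criteria].
#' @param confidence_level Passed to [ols_fit].
#' @return A list (report section) with the fit, computed statistics and flags.
#' @export
system_linearity <- function(table, criteria = validation_criteria(),
                             confidence_level = 0.95) {
  stopifnot(inherits(table, "calibration_table"))
  if (attr(table, "kind") != "system") stop("table kind must be 'system'")
  fit <- ols_fit(xy_data(table$level_ug_ml, table$response),
                 confidence_level = confidence_level)
  rf <- table$response / table$level_ug_ml
  rsd_rf <- rsd_percent(rf)
  flags <- list(
    r = abs(fit$r) >= criteria$r_min,
    r2 = fit$r2 >= criteria$r2_min,
    rsd = rsd_rf <= criteria$rsd_max,
    ci_beta0_contains_zero = if (criteria$require_ci_beta0_contains_zero)
      ci_contains(fit$ci_beta0, 0) else NA
  )
  list(parameter = "system_linearity", fit = fit,
       r = fit$r, r2 = fit$r2, rsd_response_factors = rsd_rf,
       ci_beta0 = fit$ci_beta0, flags = flags,
       pass = all(unlist(flags[!is.na(flags)])))
}

#' Method linearity assessment
#'
#' Regression of found on added concentration for analyte-fortified placebos.
#' When a system-calibration fit is supplied, found concentrations are
#' obtained by inverse prediction `(response - beta0) / beta1`; otherwise the
#' table's responses are taken as found concentrations directly.
#'
#' @param table A [calibration_table] of kind `"method"`.
#' @param nominal Working-level concentration, ug/ml (> 0); levels are also
#'   reported as percent of this nominal.
#' @param criteria A [validation_criteria].
#' @param system_fit Optional `linear_fit` from [system_linearity] for inverse
#'   prediction of found concentrations.
#' @param confidence_level Passed to [ols_fit].
#' @return A list (report section): per-level recoveries, mean recovery, %RSD,
#'   fit of found vs. added, CI flags for slope ~ 1 and intercept ~ 0.
#' @export
method_linearity <- function(table, nominal, criteria = validation_criteria(),
                             system_fit = NULL, confidence_level = 0.95) {
  stopifnot(inherits(table, "calibration_table"))
  if (attr(table, "kind") != "method") stop("table kind must be 'method'")
  if (!is.numeric(nominal) || nominal <= 0) stop("nominal must be positive")
  added <- table$level_ug_ml
  found <- if (!is.null(system_fit)) {
    stopifnot(inherits(system_fit, "linear_fit"))
    (table$response - system_fit$beta0) / system_fit$beta1
  } else {
    table$response
  }
  recoveries <- 100 * found / added
  fit <- ols_fit(xy_data(added, found), confidence_level = confidence_level)
  mean_rec <- mean(recoveries)
  sd_rec <- stats::sd(recoveries)
  rsd <- rsd_percent(recoveries)
  flags <- list(
    r = abs(fit$r) >= criteria$r_min,
    r2 = fit$r2 >= criteria$r2_min,
    recovery = mean_rec >= criteria$recovery_low && mean_rec <= criteria$recovery_high,
    rsd = rsd <= criteria$rsd_max,
    ci_beta1_contains_one = if (criteria$require_ci_beta1_contains_one)
      ci_contains(fit$ci_beta1, 1) else NA,
    ci_beta0_contains_zero = if (criteria$require_ci_beta0_contains_zero)
      ci_contains(fit$ci_beta0, 0) else NA
  )
  list(parameter = "method_linearity", fit = fit,
       level_percent = 100 * added / nominal,
       added = added, found = found, recoveries = recoveries,
       mean_recovery = mean_rec, sd_recovery = sd_rec, rsd = rsd,
       r = fit$r, r2 = fit$r2,
       ci_beta0 = fit$ci_beta0, ci_beta1 = fit$ci_beta1,
       flags = flags, pass = all(unlist(flags[!is.na(flags)])))
}

#' Accuracy and precision assessment
#'
#' Mean recovery +/- sd, %RSD, and per-observation residuals from 100%.
#' Passes when the mean recovery lies within the criteria bounds (inclusive)
#' and the %RSD is below its threshold. Whether every per-observation
#' residual |recovery - 100| stays below the criteria's `abs_diff_max` is
#' reported as an informational flag but does not gate the verdict.
#'
#' @param recoveries Percent recoveries, length >= 2 (>= 3 for a meaningful
#'   precision estimate).
#' @param criteria A [validation_criteria].
#' @return A list (report section).
#' @export
accuracy_precision <- function(recoveries, criteria = validation_criteria()) {
  if (!is.numeric(recoveries) || length(recoveries) < 2L) {
    stop("recoveries must be a numeric vector of length >= 2")
  }
  mean_rec <- mean(recoveries)
  sd_rec <- stats::sd(recoveries)
  rsd <- rsd_percent(recoveries)
  residuals_pct <- recoveries - 100
  flags <- list(
    recovery = mean_rec >= criteria$recovery_low && mean_rec <= criteria$recovery_high,
    rsd = rsd <= criteria$rsd_max,
    # informational: individual-recovery spread, not part of the pass gate
    residuals = all(abs(residuals_pct) < criteria$abs_diff_max)
  )
  list(parameter = "accuracy_precision",
       mean_recovery = mean_rec, sd_recovery = sd_rec, rsd = rsd,
       residuals_pct = residuals_pct, n = length(recoveries),
       flags = flags, pass = flags$recovery && flags$rsd)
}

#' Detection and quantification limits from calibration regression
#'
#' `LOD = 3.3 * S_beta0 / beta1` and `LOQ = 10 * S_beta0 / beta1`, where
#' `S_beta0` is the dispersion of the calibration intercept and `beta1` the
#' calibration slope. The ratio LOQ/LOD is 10/3.3 by construction.
#'
#' @param fit A `linear_fit` from a calibration regression with positive slope.
#' @return A list with elements `lod` and `loq` (concentration units of the
#'   calibration x axis).
#' @export
lod_loq <- function(fit) {
  stopifnot(inherits(fit, "linear_fit"))
  if (is.na(fit$se_beta0)) stop("fit carries no intercept dispersion (n = 2?)")
  if (fit$beta1 <= 0) stop("calibration slope must be positive")
  list(lod = 3.3 * fit$se_beta0 / fit$beta1,
       loq = 10 * fit$se_beta0 / fit$beta1)
}

#' Robustness difference |di|
#'
#' Absolute difference of mean recoveries between the nominal analytical
#' condition and a deliberately perturbed one.
#'
#' @param mean_normal Mean recovery (percent) under nominal conditions.
#' @param mean_modified Mean recovery (percent) under the modified condition.
#' @return |mean_normal - mean_modified|.
#' @export
robustness_diff <- function(mean_normal, mean_modified) {
  if (!is.numeric(mean_normal) || !is.numeric(mean_modified)) {
    stop("means must be numeric")
  }
  abs(mean_normal - mean_modified)
}

#' Specificity decision rule
#'
#' Passes when no blank, placebo or degradation-product peak falls within
#' `tolerance` minutes of the analyte retention time.
#'
#' @param peaks A [peak_table] of candidate interfering peaks (blanks,
#'   placebos, degradant peaks of stressed samples). Do not include the
#'   analyte peak itself.
#' @param analyte_tr Analyte retention time, minutes.
#' @param tolerance Interference window half-width, minutes (> 0).
#' @return A list with `pass` and the `interfering` subset of `peaks`.
#' @export
specificity_check <- function(peaks, analyte_tr, tolerance = 0.2) {
  if (tolerance <= 0) stop("tolerance must be positive")
  if (nrow(peaks) == 0L) {
    return(list(pass = TRUE, interfering = peaks))
  }
  stopifnot(inherits(peaks, "peak_table"))
  hit <- abs(peaks$t_r_min - analyte_tr) <= tolerance
  list(pass = !any(hit), interfering = peaks[hit, , drop = FALSE])
}
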