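#' Study design for the synthetic-data generator
#'
#' Defaults mirror the emulated assay study: a 6-level standard calibration
#' from 0.525 to 16.8 ug/ml (serial 1:2 dilutions of a 21 ug/ml stock taken at
#' 80%), fortified placebos at 80-120% of a 3.5 ug/ml working level, time
#' courses at 0/24/72/120 h and 4/25/40/60 C, triplicate measurements, and a
#' multiplicative assay noise of 1.5% RSD (the study's reported precision is
#' ~1-1.5%).
#'
#' @param calibration_levels Standard concentrations, ug/ml.
#' @param method_percent Fortification levels as percent of `nominal`.
#' @param nominal Working-level concentration, ug/ml.
#' @param times_h Degradation sampling times, hours.
#' @param temperatures_c Stress temperatures, Celsius.
#' @param replicates Replicates per point.
#' @param noise_rsd Multiplicative gaussian noise, percent RSD.
#' @param seed Integer seed; every generator in this package is fully
#'   deterministic given the design seed.
#' @return A list of class `study_design`.
#' @export
study_design <- function(calibration_levels = c(0.525, 1.05, 2.1, 4.2, 8.4, 16.8),
                         method_percent = c(80, 90, 100, 110, 120),
                         nominal = 3.5,
                         times_h = c(0, 24, 72, 120),
                         temperatures_c = c(4, 25, 40, 60),
                         replicates = 3L,
                         noise_rsd = 1.5,
                         seed = 1L) {
  if (any(calibration_levels <= 0) || nominal <= 0) stop("levels must be positive")
  if (replicates < 1L) stop("replicates must be >= 1")
  if (noise_rsd < 0) stop("noise_rsd must be nonnegative")
  structure(list(calibration_levels = sort(calibration_levels),
                 method_percent = sort(method_percent),
                 nominal = nominal,
                 times_h = sort(times_h),
                 temperatures_c = sort(temperatures_c),
                 replicates = as.integer(replicates),
                 noise_rsd = noise_rsd,
                 seed = as.integer(seed)),
            class = "study_design")
}

mult_noise <- function(n, rsd) {
  if (rsd == 0) rep(1, n) else 1 + stats::rnorm(n, sd = rsd / 100)
}

#' Generate a system calibration table with known truth
#'
#' Responses follow `area = slope * conc + intercept` with multiplicative
#' gaussian noise at the design's RSD.
#'
#' @param design A [study_design].
#' @param slope,intercept True calibration line (area units per ug/ml).
#' @return A list with `table` (a [calibration_table], kind `"system"`) and
#'   `truth` (`slope`, `intercept`, `noise_rsd`, `seed`).
#' @export
gen_calibration <- function(design = study_design(), slope = 50000, intercept = 0) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  conc <- rep(design$calibration_levels, each = design$replicates)
  repl <- rep(seq_len(design$replicates), times = length(design$calibration_levels))
  mu <- slope * conc + intercept
  area <- mu * mult_noise(length(mu), design$noise_rsd)
  list(table = calibration_table(conc, repl, area, kind = "system"),
       truth = list(slope = slope, intercept = intercept,
                    noise_rsd = design$noise_rsd, seed = design$seed))
}

#' Generate a fortified-placebo (method linearity) table
#'
#' Found concentrations equal `added * true_recovery/100` with multiplicative
#' noise; responses are found concentrations directly (use
#' `as_area = TRUE` with a slope to emit areas instead).
#'
#' @param design A [study_design].
#' @param true_recovery_pct True mean recovery, percent.
#' @param as_area Emit areas through a calibration line rather than found
#'   concentrations.
#' @param slope,intercept Calibration line used when `as_area = TRUE`.
#' @return A list with `table` (kind `"method"`) and `truth`.
#' @export
gen_method_table <- function(design = study_design(), true_recovery_pct = 100,
                             as_area = FALSE, slope = 50000, intercept = 0) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed + 1L)
  added <- rep(design$nominal * design$method_percent / 100,
               each = design$replicates)
  repl <- rep(seq_len(design$replicates), times = length(design$method_percent))
  found <- added * (true_recovery_pct / 100) * mult_noise(length(added), design$noise_rsd)
  resp <- if (as_area) slope * found + intercept else found
  list(table = calibration_table(added, repl, resp, kind = "method"),
       truth = list(true_recovery_pct = true_recovery_pct,
                    noise_rsd = design$noise_rsd, seed = design$seed,
                    as_area = as_area, slope = slope, intercept = intercept))
}

#' Default Arrhenius ground truth per stress condition
#'
#' (A, E) pairs chosen so the implied rates k(T) = exp(A - 11605 E / T_K)
#' reproduce the order of magnitude of a typical forced-degradation study of
#' a light- and base-sensitive stilbene: acid hydrolysis slowest, basic
#' hydrolysis fastest, oxidation intermediate, plain thermal stress mild.
#' Photolysis conditions are single-temperature (25 C) with fixed rates, so
#' they get no Arrhenius step.
#'
#' @return A list with `arrhenius` (named list of `c(A, E)` per condition)
#'   and `photolysis_rates` (named 1/h rates at 25 C).
#' @export
default_degradation_truth <- function() {
  list(
    arrhenius = list(
      acid        = c(A = 6.1,  E = 0.36),
      base        = c(A = 14.0, E = 0.46),
      oxidation   = c(A = 16.4, E = 0.56),
      temperature = c(A = 10.0, E = 0.45)
    ),
    photolysis_rates = c(darkness = 0.00015, ambient = 0.00116, uv = 0.01411)
  )
}

arrhenius_rate <- function(A, E, temp_c) {
  exp(A - E * B_INV_KELVIN_EV / celsius_to_kelvin(temp_c))
}

#' Generate a forced-degradation study with known truth
#'
#' For each Arrhenius condition and design temperature, replicate recoveries
#' follow `100 * exp(-k(T) * t)` with multiplicative noise, truncated at 0
#' (a fully degraded sample cannot report negative recovery); photolysis
#' conditions are generated at 25 C from their fixed rates.
#'
#' @param design A [study_design].
#' @param truth Ground truth as from [default_degradation_truth()].
#' @param sample_id Sample label stamped on all rows.
#' @return A list with `data` (long `data.frame` in the degradation-CSV
#'   schema: `sample_id, condition, temperature_c, time_h, replicate,
#'   recovery_pct`) and `truth` (input truth plus the implied `k` per
#'   condition/temperature).
#' @export
gen_degradation_study <- function(design = study_design(),
                                  truth = default_degradation_truth(),
                                  sample_id = "STD") {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed + 2L)
  rows <- list(); k_truth <- list()
  for (cond in names(truth$arrhenius)) {
    par <- truth$arrhenius[[cond]]
    for (temp in design$temperatures_c) {
      k <- arrhenius_rate(par[["A"]], par[["E"]], temp)
      k_truth[[paste(cond, temp, sep = "@")]] <- k
      for (tt in design$times_h) {
        mu <- 100 * exp(-k * tt)
        rec <- pmax(mu * mult_noise(design$replicates, design$noise_rsd), 0)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, condition = cond, temperature_c = temp,
          time_h = tt, replicate = seq_len(design$replicates),
          recovery_pct = rec, stringsAsFactors = FALSE)
      }
    }
  }
  for (cond in names(truth$photolysis_rates)) {
    k <- truth$photolysis_rates[[cond]]
    k_truth[[paste(cond, 25, sep = "@")]] <- k
    for (tt in design$times_h) {
      mu <- 100 * exp(-k * tt)
      rec <- pmax(mu * mult_noise(design$replicates, design$noise_rsd), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, condition = cond, temperature_c = 25,
        time_h = tt, replicate = seq_len(design$replicates),
        recovery_pct = rec, stringsAsFactors = FALSE)
    }
  }
  list(data = do.call(rbind, rows),
       truth = c(truth, list(k = unlist(k_truth), seed = design$seed,
                             noise_rsd = design$noise_rsd)))
}

# Degradant retention schedule (min): analyte at 2.6, photoisomer at 3.9,
# putative ketone at 3.2, five unidentified early/late eluters.
ANALYTE_TR <- 2.6
DEGRADANT_TR <- c(0.7, 1.0, 1.4, 1.8, 3.2, 3.9, 5.0)

gaussian_peak <- function(time_min, center_min, area, sd_min) {
  area / (sd_min * sqrt(2 * pi)) * exp(-(time_min - center_min)^2 / (2 * sd_min^2))
}

#' Generate a synthetic chromatogram
#'
#' A six-minute trace: the analyte peak at 2.6 min with area proportional to
#' the remaining fraction, and seven degradant peaks (0.7, 1.0, 1.4, 1.8,
#' 3.2, 3.9, 5.0 min) sharing the degraded fraction's area uniformly. Peak
#' shapes are Gaussian with a 21 s baseline width (sigma = 5.25 s) for the
#' analyte.
#'
#' @param degraded_fraction Fraction of analyte degraded, in `[0, 1]`.
#' @param total_area Area of the undegraded analyte peak.
#' @param dt_min Grid spacing, minutes.
#' @param noise_sd Additive baseline gaussian noise (signal units); seeded by
#'   `seed`.
#' @param seed Integer seed for the baseline noise.
#' @return A [chrom_trace] over 0-6 min with attributes `analyte_area` and
#'   `degradant_area` (the per-peak truth).
#' @export
gen_chromatogram <- function(degraded_fraction, total_area = 2715729,
                             dt_min = 0.002, noise_sd = 0, seed = 1L) {
  if (degraded_fraction < 0 || degraded_fraction > 1) {
    stop("degraded_fraction must be in [0, 1]")
  }
  time_min <- seq(0, 6, by = dt_min)
  # areas are in (signal units) x seconds to match integrate_peaks
  analyte_area <- total_area * (1 - degraded_fraction)
  deg_area <- total_area * degraded_fraction / length(DEGRADANT_TR)
  sd_s <- 21 / 4 # baseline width ~ 4 sigma
  signal <- gaussian_peak(time_min * 60, ANALYTE_TR * 60, analyte_area, sd_s)
  for (tr_d in DEGRADANT_TR) {
    signal <- signal + gaussian_peak(time_min * 60, tr_d * 60, deg_area, sd_s)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    signal <- signal + stats::rnorm(length(signal), sd = noise_sd)
  }
  out <- chrom_trace(time_min, signal)
  attr(out, "analyte_area") <- analyte_area
  attr(out, "degradant_area") <- deg_area
  out
}

#' Write a synthetic study to disk
#'
#' Emits the CSV schemas the analysis functions read, plus a ground-truth
#' JSON, under `outdir`: `calibration.csv`, `method.csv`, `degradation.csv`,
#' `truth.json`.
#'
#' @param design A [study_design].
#' @param outdir Output directory (created if needed).
#' @param true_recovery_pct Passed to [gen_method_table].
#' @return Invisibly, the named vector of file paths.
#' @export
write_synthetic_study <- function(design = study_design(), outdir,
                                  true_recovery_pct = 100) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cal <- gen_calibration(design)
  met <- gen_method_table(design, true_recovery_pct = true_recovery_pct)
  deg <- gen_degradation_study(design)

  paths <- c(calibration = file.path(outdir, "calibration.csv"),
             method = file.path(outdir, "method.csv"),
             degradation = file.path(outdir, "degradation.csv"),
             truth = file.path(outdir, "truth.json"))
  cal_df <- data.frame(level_ug_ml = cal$table$level_ug_ml,
                       replicate = cal$table$replicate,
                       area = cal$table$response, kind = "system")
  met_df <- data.frame(level_ug_ml = met$table$level_ug_ml,
                       replicate = met$table$replicate,
                       area = met$table$response, kind = "method")
  utils::write.csv(cal_df, paths[["calibration"]], row.names = FALSE)
  utils::write.csv(met_df, paths[["method"]], row.names = FALSE)
  utils::write.csv(deg$data, paths[["degradation"]], row.names = FALSE)
  truth <- list(design = unclass(design), calibration = cal$truth,
                method = met$truth, degradation = deg$truth)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
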