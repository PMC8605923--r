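# Boltzmann's constant in eV/K is ~1/11605; the Arrhenius fits below use
# ln k = A - E * 11605 / T with E in eV and T in Kelvin.
B_INV_KELVIN_EV <- 11605

celsius_to_kelvin <- function(temp_c) {
  if (any(temp_c < -273.15)) stop("temperature below absolute zero")
  temp_c + 273.15
}

#' Degradation time course at one condition and temperature
#'
#' @param condition Stress condition label (e.g. `"acid"`, `"base"`,
#'   `"oxidation"`, `"temperature"`, `"uv"`).
#' @param temperature_c Temperature in degrees Celsius.
#' @param times_h Sampling times in hours, nondecreasing, starting at 0.
#' @param recovery_pct Percent of initial analyte remaining at each time
#'   (replicate mean).
#' @param recovery_sd Optional replicate standard deviations.
#' @param n_replicates Replicates behind each mean.
#' @param sample_id Sample label (e.g. `"STD"`, `"F1"`, `"F2"`).
#' @return An object of class `degradation_series`.
#' @export
degradation_series <- function(condition, temperature_c, times_h, recovery_pct,
                               recovery_sd = NULL, n_replicates = NA_integer_,
                               sample_id = "STD") {
  if (length(times_h) != length(recovery_pct)) stop("times and recoveries differ in length")
  if (length(times_h) < 2L) stop("need at least 2 time points")
  if (is.unsorted(times_h)) stop("times must be nondecreasing")
  if (times_h[1L] != 0) stop("time course must start at 0 h")
  if (any(recovery_pct < 0)) stop("recoveries must be nonnegative")
  structure(list(condition = as.character(condition),
                 temperature_c = as.numeric(temperature_c),
                 times_h = as.numeric(times_h),
                 recovery_pct = as.numeric(recovery_pct),
                 recovery_sd = recovery_sd,
                 n_replicates = n_replicates,
                 sample_id = as.character(sample_id)),
            class = "degradation_series")
}

#' First-order degradation fit
#'
#' Fits log(recovery) against time by least squares and returns the
#' unadjusted rate constant `k0 = -slope`. Natural logarithms are the default;
#' with `log_base = "10"` the rate is on the decadic-log basis (k rescales by
#' ln 10, and t90 computed consistently is unchanged). Zero or negative
#' recoveries cannot enter a log fit and are excluded and listed.
#'
#' @param series A [degradation_series].
#' @param log_base `"e"` (default) or `"10"`.
#' @param anchor_t0 If `TRUE`, force the fitted line through 100% at t = 0
#'   (regression through the origin of log(recovery/100) on time). Default
#'   `FALSE`: free intercept.
#' @return An object of class `first_order_fit`: `k0` (1/h), `intercept`
#'   (log-recovery at t = 0), `r2`, `n_points_used`, `excluded_points`
#'   (indices), `log_base`, `anchor_t0`.
#' @export
fit_first_order <- function(series, log_base = c("e", "10"), anchor_t0 = FALSE) {
  stopifnot(inherits(series, "degradation_series"))
  log_base <- match.arg(log_base)
  base <- if (log_base == "e") exp(1) else 10
  keep <- which(series$recovery_pct > 0)
  excluded <- setdiff(seq_along(series$recovery_pct), keep)
  if (length(keep) < 2L) {
    stop("fewer than 2 positive-recovery points: series truncated beyond use")
  }
  t <- series$times_h[keep]
  if (length(unique(t)) < 2L) stop("all usable times identical")
  y <- log(series$recovery_pct[keep], base = base)

  if (anchor_t0) {
    y0 <- log(100, base = base)
    yc <- y - y0
    slope <- sum(t * yc) / sum(t * t)
    fitted <- y0 + slope * t
    intercept <- y0
  } else {
    sxx <- sum((t - mean(t))^2)
    slope <- sum((t - mean(t)) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * mean(t)
    fitted <- intercept + slope * t
  }
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) as.numeric(sse < 1e-12) else max(0, 1 - sse / sst)

  structure(list(k0 = -slope, intercept = intercept, r2 = r2,
                 n_points_used = length(keep), excluded_points = excluded,
                 log_base = log_base, anchor_t0 = anchor_t0,
                 temperature_c = series$temperature_c,
                 condition = series$condition, sample_id = series$sample_id),
            class = "first_order_fit")
}

#' Arrhenius fit of rate constants across temperatures
#'
#' Accelerated-stability model: `ln k = A - E * 11605 / T`, i.e. log-rate
#' linear in inverse absolute temperature, with E an activation-energy-like
#' parameter in eV and B = 1/11605 eV/K (Boltzmann's constant) fixed.
#'
#' @param rates Named numeric vector: names are temperatures in degrees
#'   Celsius, values are positive rate constants (1/h). At least 2 distinct
#'   temperatures.
#' @return An object of class `arrhenius_model`: `a_param` (intercept A),
#'   `e_param` (E, eV), `b_const` (1/11605), `fitted_temperatures_k`, `r2`.
#' @examples
#' m <- fit_arrhenius(c(`40` = 0.0148, `60` = 0.0513))
#' m$e_param
#' @export
fit_arrhenius <- function(rates) {
  if (is.null(names(rates))) stop("rates must be named by temperature in Celsius")
  temps_c <- as.numeric(names(rates))
  if (anyNA(temps_c)) stop("rate names must be numeric temperatures")
  if (length(unique(temps_c)) < 2L) stop("need at least 2 distinct temperatures")
  if (any(rates <= 0)) stop("rates must be positive")
  temps_k <- celsius_to_kelvin(temps_c)
  x <- 1 / temps_k
  y <- log(rates)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else max(0, 1 - sum((y - fitted)^2) / sst)
  structure(list(a_param = intercept,
                 e_param = -slope / B_INV_KELVIN_EV,
                 b_const = 1 / B_INV_KELVIN_EV,
                 fitted_temperatures_k = temps_k, r2 = r2),
            class = "arrhenius_model")
}

#' Adjusted rate constant at a target temperature
#'
#' Evaluates the Arrhenius model at a target temperature:
#' `kA = exp(A - E * 11605 / T_K)`. When the target lies outside the span of
#' fitted temperatures the result carries `extrapolated = TRUE` as an
#' attribute.
#'
#' @param model An [fit_arrhenius] model.
#' @param target_temperature_c Target temperature, degrees Celsius.
#' @return Adjusted rate constant kA (1/h) with attribute `extrapolated`.
#' @export
adjusted_rate <- function(model, target_temperature_c) {
  stopifnot(inherits(model, "arrhenius_model"))
  t_k <- celsius_to_kelvin(target_temperature_c)
  ka <- exp(model$a_param - model$e_param * B_INV_KELVIN_EV / t_k)
  span <- range(model$fitted_temperatures_k)
  attr(ka, "extrapolated") <- t_k < span[1] || t_k > span[2]
  ka
}

#' Shelf-life t90
#'
#' Time for the analyte to fall to 90% of its initial concentration under
#' first-order decay: `t90 = log(C0 / (0.9 C0)) / kA = log(10/9) / kA`, in the
#' same log basis as the rate constant. Independent of C0, which is retained
#' only for traceability.
#'
#' @param ka Degradation rate constant, 1/h (> 0), on the `log_base` basis.
#' @param c0 Initial concentration (cancels; default 100).
#' @param log_base `"e"` (default) or `"10"`, matching the basis of `ka`.
#' @return t90 in hours.
#' @examples
#' t90(0.04275) # 2.46 h
#' @export
t90 <- function(ka, c0 = 100, log_base = c("e", "10")) {
  log_base <- match.arg(log_base)
  if (any(ka <= 0)) stop("ka must be positive: no finite shelf life otherwise")
  if (any(c0 <= 0)) stop("c0 must be positive")
  base <- if (log_base == "e") exp(1) else 10
  log(c0 / (0.9 * c0), base = base) / ka
}

#' Stability summary table
#'
#' The engine behind a forced-degradation summary: per (sample, condition)
#' group, each series is fitted first-order; when the group spans two or more
#' temperatures the rates are Arrhenius-fitted and the adjusted constant kA is
#' the model evaluated at each series temperature, otherwise kA = k0
#' (no adjustment possible). kA is reported in 1e-3/h to match the
#' conventional presentation scale.
#'
#' @param series_list List of [degradation_series].
#' @param log_base,anchor_t0 Passed to [fit_first_order].
#' @param report_time_h Time whose recovery is reported per row (default 120);
#'   if a series ends (or is truncated to zero) earlier, the last usable
#'   time's recovery is reported and the row is footnoted.
#' @return A `data.frame` with class `stability_table`: columns `sample_id`,
#'   `condition`, `temperature_c`, `k0_per_h`, `ka_per_h`, `ka_e3` (kA in
#'   1e-3/h), `t90_h`, `r2`, `recovery_reported`, `recovery_time_h`,
#'   `truncated`, `n_points_used`, `arrhenius_r2`.
#' @export
stability_table <- function(series_list, log_base = c("e", "10"),
                            anchor_t0 = FALSE, report_time_h = 120) {
  log_base <- match.arg(log_base)
  stopifnot(length(series_list) > 0)
  keys <- vapply(series_list, function(s) paste(s$sample_id, s$condition, sep = "\r"),
                 character(1))
  rows <- list()
  for (key in unique(keys)) {
    group <- series_list[keys == key]
    fits <- list(); skipped <- logical(length(group))
    for (i in seq_along(group)) {
      f <- tryCatch(fit_first_order(group[[i]], log_base = log_base,
                                    anchor_t0 = anchor_t0),
                    error = function(e) e)
      if (inherits(f, "error")) {
        warning(sprintf("skipping %s / %s at %g C: %s",
                        group[[i]]$sample_id, group[[i]]$condition,
                        group[[i]]$temperature_c, conditionMessage(f)))
        skipped[i] <- TRUE
      }
      fits[[i]] <- f
    }
    ok <- which(!skipped)
    if (!length(ok)) next
    temps <- vapply(group[ok], `[[`, numeric(1), "temperature_c")
    k0s <- vapply(fits[ok], `[[`, numeric(1), "k0")
    # Arrhenius adjustment needs >= 2 distinct temperatures and positive rates
    arr <- NULL
    if (length(unique(temps)) >= 2L && all(k0s > 0)) {
      arr <- fit_arrhenius(stats::setNames(k0s, temps))
    }
    for (i in ok) {
      s <- group[[i]]; f <- fits[[i]]
      ka <- if (!is.null(arr)) as.numeric(adjusted_rate(arr, s$temperature_c)) else f$k0
      usable <- s$times_h[s$recovery_pct > 0]
      last_t <- if (length(usable)) max(usable) else NA_real_
      trunc <- is.na(last_t) || last_t < report_time_h ||
        max(s$times_h) < report_time_h
      rep_t <- min(report_time_h, max(s$times_h))
      # report recovery at the requested time; fall back to last measured point
      idx <- which(s$times_h == rep_t)
      if (!length(idx)) idx <- length(s$times_h)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s$sample_id, condition = s$condition,
        temperature_c = s$temperature_c,
        k0_per_h = f$k0, ka_per_h = ka, ka_e3 = 1000 * ka,
        t90_h = if (ka > 0) t90(ka, log_base = log_base) else NA_real_,
        r2 = f$r2,
        recovery_reported = s$recovery_pct[idx[1L]],
        recovery_time_h = s$times_h[idx[1L]],
        truncated = trunc, n_points_used = f$n_points_used,
        arrhenius_r2 = if (!is.null(arr)) arr$r2 else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no usable series")
  out <- do.call(rbind, rows)
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Read a degradation CSV into series
#'
#' Schema: columns `sample_id, condition, temperature_c, time_h, replicate,
#' recovery_pct`. Replicates are averaged per time point.
#'
#' @param path File path.
#' @return A list of [degradation_series], one per
#'   (sample_id, condition, temperature_c).
#' @export
read_degradation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "temperature_c", "time_h",
            "replicate", "recovery_pct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("degradation CSV missing columns: ", paste(miss, collapse = ", "))
  key <- interaction(df$sample_id, df$condition, df$temperature_c, drop = TRUE)
  lapply(split(df, key), function(g) {
    agg <- stats::aggregate(recovery_pct ~ time_h, data = g, FUN = mean)
    sds <- stats::aggregate(recovery_pct ~ time_h, data = g, FUN = stats::sd)
    agg <- agg[order(agg$time_h), ]
    degradation_series(condition = g$condition[1L],
                       temperature_c = g$temperature_c[1L],
                       times_h = agg$time_h,
                       recovery_pct = agg$recovery_pct,
                       recovery_sd = sds$recovery_pct[order(sds$time_h)],
                       n_replicates = max(g$replicate),
                       sample_id = g$sample_id[1L])
  })
}
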