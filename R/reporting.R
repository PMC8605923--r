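pkg_version <- function() as.character(utils::packageVersion("stabval"))

strip_fits <- function(x) {
  # linear_fit objects carry closures-free plain lists already; keep JSON lean
  if (inherits(x, "linear_fit")) return(unclass(x))
  if (is.list(x)) return(lapply(x, strip_fits))
  x
}

#' Run the validation battery and write a report
#'
#' Reads a system-calibration CSV and a fortified-placebo CSV, runs system
#' linearity, method linearity, accuracy/precision and LOD/LOQ, evaluates
#' every criterion, and writes a JSON report plus a human-readable text table.
#'
#' @param config A list: `calibration` (path), `method` (path), `nominal`
#'   (ug/ml, default 3.5), `criteria` (optional path to a JSON file of
#'   [validation_criteria] fields), `confidence_level` (default 0.95),
#'   `outdir` (default `"."`), `inverse_prediction` (default TRUE: found
#'   concentrations via the system fit when the method responses are areas).
#' @return Invisibly, a list with `report` (the full report), `status`
#'   (0 if all required criteria pass, 1 otherwise) and the output `paths`.
#' @export
run_validation_report <- function(config) {
  need <- c("calibration", "method")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing fields: ", paste(miss, collapse = ", "))
  nominal <- config$nominal %||% 3.5
  conf <- config$confidence_level %||% 0.95
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  criteria <- if (!is.null(config$criteria)) {
    fields <- jsonlite::read_json(config$criteria, simplifyVector = TRUE)
    do.call(validation_criteria, fields)
  } else {
    warning("no criteria file supplied: using default ICH Q2 thresholds")
    validation_criteria()
  }

  cal <- read_calibration(config$calibration)
  met <- read_calibration(config$method)
  sys <- system_linearity(cal, criteria, confidence_level = conf)
  inv <- isTRUE(config$inverse_prediction %||% FALSE)
  mth <- method_linearity(met, nominal = nominal, criteria = criteria,
                          system_fit = if (inv) sys$fit else NULL,
                          confidence_level = conf)
  acc <- accuracy_precision(mth$recoveries, criteria)
  lim <- lod_loq(sys$fit)

  report <- list(
    meta = list(package = "stabval", version = pkg_version(),
                date = format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                config = config[setdiff(names(config), "outdir")]),
    criteria = unclass(criteria),
    system_linearity = strip_fits(sys),
    method_linearity = strip_fits(mth),
    accuracy_precision = acc,
    limits = lim,
    pass = sys$pass && mth$pass && acc$pass
  )
  paths <- c(json = file.path(outdir, "validation_report.json"),
             text = file.path(outdir, "validation_report.txt"))
  write_report(report, paths[["json"]])
  writeLines(format_validation_report(report), paths[["text"]])
  invisible(list(report = report, status = as.integer(!report$pass),
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the stability analysis and write a report
#'
#' Reads a degradation CSV, builds the per-condition stability table
#' (first-order fits, Arrhenius adjustment, t90), and writes it as CSV, JSON
#' and a formatted text table.
#'
#' @param config A list: `degradation` (path), `log_base` (`"e"` or `"10"`),
#'   `anchor_t0` (logical), `outdir` (default `"."`).
#' @return Invisibly, a list with `table` (the [stability_table]), `status`
#'   (always 0 unless no series is usable) and output `paths`.
#' @export
run_stability_report <- function(config) {
  if (is.null(config$degradation)) stop("config missing field: degradation")
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  series <- read_degradation(config$degradation)
  tab <- stability_table(series,
                         log_base = config$log_base %||% "e",
                         anchor_t0 = isTRUE(config$anchor_t0))
  paths <- c(csv = file.path(outdir, "stability_table.csv"),
             json = file.path(outdir, "stability_table.json"),
             text = file.path(outdir, "stability_table.txt"))
  utils::write.csv(as.data.frame(tab), paths[["csv"]], row.names = FALSE)
  report <- list(meta = list(package = "stabval", version = pkg_version(),
                             config = config[setdiff(names(config), "outdir")]),
                 table = as.data.frame(tab))
  write_report(report, paths[["json"]])
  writeLines(format_stability_table(tab), paths[["text"]])
  invisible(list(table = tab, status = 0L, paths = paths))
}

#' Write / read a JSON report
#'
#' Reports round-trip: numeric content is serialized at full precision.
#' @param report A report list.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

fmt_flag <- function(flag) {
  if (is.na(flag)) "-" else if (flag) "pass" else "FAIL"
}

#' Format a validation report as text
#' @param report A report list from [run_validation_report].
#' @return Character vector of lines.
#' @export
format_validation_report <- function(report) {
  s <- report$system_linearity; m <- report$method_linearity
  a <- report$accuracy_precision; l <- report$limits
  c(
    "Validation summary",
    "==================",
    sprintf("%-22s r=%.3f [%s]  r2=%.3f [%s]  %%RSD=%.2f [%s]  CI(b0) contains 0 [%s]",
            "System linearity", s$r, fmt_flag(s$flags$r), s$r2, fmt_flag(s$flags$r2),
            s$rsd_response_factors, fmt_flag(s$flags$rsd),
            fmt_flag(s$flags$ci_beta0_contains_zero)),
    sprintf("%-22s r=%.3f [%s]  r2=%.3f [%s]  recovery=%.2f +/- %.2f [%s]  %%RSD=%.2f [%s]",
            "Method linearity", m$r, fmt_flag(m$flags$r), m$r2, fmt_flag(m$flags$r2),
            m$mean_recovery, m$sd_recovery, fmt_flag(m$flags$recovery),
            m$rsd, fmt_flag(m$flags$rsd)),
    sprintf("%-22s CI(b1) contains 1 [%s]  CI(b0) contains 0 [%s]",
            "", fmt_flag(m$flags$ci_beta1_contains_one),
            fmt_flag(m$flags$ci_beta0_contains_zero)),
    sprintf("%-22s recovery=%.2f +/- %.2f [%s]  %%RSD=%.2f [%s]  residuals<max [%s]",
            "Accuracy/precision", a$mean_recovery, a$sd_recovery,
            fmt_flag(a$flags$recovery), a$rsd, fmt_flag(a$flags$rsd),
            fmt_flag(a$flags$residuals)),
    sprintf("%-22s LOD=%.3f ug/ml  LOQ=%.3f ug/ml", "Limits", l$lod, l$loq),
    sprintf("Overall: %s", if (isTRUE(report$pass)) "PASS" else "FAIL")
  )
}

#' Format a stability table as text
#'
#' kA rendered in 1e-3/h with 2 decimals, t90 and recovery with 2 decimals;
#' truncated series are footnoted.
#' @param tab A [stability_table].
#' @return Character vector of lines.
#' @export
format_stability_table <- function(tab) {
  header <- sprintf("%-8s %-12s %6s %14s %10s %6s %18s",
                    "sample", "condition", "T(C)", "KA(x1e-3/h)", "t90(h)",
                    "r2", "%recovery")
  lines <- vapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    note <- if (isTRUE(r$truncated)) sprintf(" (at %g h)", r$recovery_time_h) else ""
    sprintf("%-8s %-12s %6g %14.2f %10.2f %6.2f %12.2f%s",
            r$sample_id, r$condition, r$temperature_c, r$ka_e3,
            r$t90_h, r$r2, r$recovery_reported, note)
  }, character(1))
  c(header, strrep("-", nchar(header)), lines)
}
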