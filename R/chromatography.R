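#' Peak table constructor
#'
#' One row per integrated chromatographic peak. Retention times are in
#' minutes, baseline widths in seconds (the mixed-unit convention of HPLC
#' reports); figure-of-merit functions convert internally.
#'
#' @param label Peak label, e.g. `"t-RSV"`, `"c-RSV"`, `"deg1"`.
#' @param t_r_min Retention time, minutes (> 0).
#' @param width_s Baseline peak width, seconds (>= 0).
#' @param area Integrated response, area units (>= 0).
#' @param sample_id Sample identifier.
#' @param role One of `"standard"`, `"sample"`, `"placebo"`, `"blank"`.
#' @return A `data.frame` with class `peak_table`.
#' @export
peak_table <- function(label, t_r_min, width_s, area,
                       sample_id = "S1", role = "sample") {
  roles <- c("standard", "sample", "placebo", "blank")
  df <- data.frame(sample_id = as.character(sample_id),
                   role = as.character(role),
                   label = as.character(label),
                   t_r_min = as.numeric(t_r_min),
                   width_s = as.numeric(width_s),
                   area = as.numeric(area),
                   stringsAsFactors = FALSE)
  if (any(!df$role %in% roles)) {
    stop("role must be one of: ", paste(roles, collapse = ", "))
  }
  if (any(df$t_r_min <= 0)) stop("retention times must be positive")
  if (any(df$width_s < 0) || any(df$area < 0)) {
    stop("widths and areas must be nonnegative")
  }
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Percent recovery from peak areas
#'
#' The assay's central quantity: how much analyte response remains in a sample
#' relative to an undegraded standard. Default orientation is
#' `100 * area_sample / area_std`, so recovery falls as the sample degrades;
#' the inverted orientation (standard over sample) is exposed for completeness.
#'
#' @param area_sample Peak area of the sample.
#' @param area_std Peak area of the reference standard (> 0).
#' @param orientation `"sample_over_standard"` (default) or
#'   `"standard_over_sample"`.
#' @return Percent recovery (vectorized over areas).
#' @examples
#' recovery_percent(1357864, 2715729) # ~50
#' @export
recovery_percent <- function(area_sample, area_std,
                             orientation = c("sample_over_standard",
                                             "standard_over_sample")) {
  orientation <- match.arg(orientation)
  if (any(area_std <= 0)) stop("standard area must be positive")
  if (any(area_sample < 0)) stop("sample area must be nonnegative")
  if (orientation == "sample_over_standard") {
    100 * area_sample / area_std
  } else {
    if (any(area_sample == 0)) stop("sample area must be positive for this orientation")
    100 * area_std / area_sample
  }
}

#' Capacity (retention) factor k'
#'
#' `k' = (t_R - t_0) / t_0`, retention relative to the column void time.
#'
#' @param t_r Retention time of the peak, minutes.
#' @param t_0 Void (dead) time, minutes (> 0). Instrument-specific and must be
#'   supplied by the user.
#' @return Dimensionless capacity factor.
#' @export
capacity_factor <- function(t_r, t_0) {
  if (any(t_0 <= 0)) stop("void time t_0 must be positive")
  if (any(t_r < t_0)) stop("t_r earlier than void time: not a retained peak")
  (t_r - t_0) / t_0
}

#' Resolution between two peaks
#'
#' Baseline-width resolution `Rs = 2 * |t_R2 - t_R1| / (w1 + w2)` with
#' retention times in minutes and widths in seconds (converted internally to a
#' common unit). Symmetric in the two peaks.
#'
#' @param t_r1,t_r2 Retention times, minutes.
#' @param w1,w2 Baseline widths, seconds.
#' @param width_kind `"baseline"` (default) or `"half_height"`; with
#'   half-height widths the standard factor 1.18 replaces 2.
#' @return Dimensionless resolution, nonnegative.
#' @examples
#' resolution(2.6, 26.8, 3.9, 26.8) # 2.91
#' @export
resolution <- function(t_r1, w1, t_r2, w2,
                       width_kind = c("baseline", "half_height")) {
  width_kind <- match.arg(width_kind)
  if (w1 + w2 <= 0) stop("combined width must be positive")
  factor <- if (width_kind == "baseline") 2 else 1.18
  dt_s <- abs(t_r2 - t_r1) * 60
  factor * dt_s / (w1 + w2)
}

#' Synthetic chromatogram trace
#'
#' @param time_min Strictly increasing time grid, minutes.
#' @param signal Detector response at each time point.
#' @return An object of class `chrom_trace`.
#' @export
chrom_trace <- function(time_min, signal) {
  if (length(time_min) != length(signal)) stop("time and signal lengths differ")
  if (length(time_min) < 2L) stop("trace needs at least 2 points")
  if (any(diff(time_min) <= 0)) stop("time must be strictly increasing")
  structure(list(time_min = as.numeric(time_min), signal = as.numeric(signal)),
            class = "chrom_trace")
}

#' Integrate peaks from a trace
#'
#' For each window the baseline is the straight line between the signal at the
#' window endpoints; the area is the trapezoidal integral of the
#' baseline-subtracted signal (converted to area units per second), and the
#' retention time is the location of the signal maximum inside the window.
#'
#' @param tr A [chrom_trace].
#' @param windows List of `c(start, end)` pairs in minutes, non-overlapping,
#'   within the trace span.
#' @param labels Optional character vector of peak labels.
#' @param sample_id,role Passed through to the resulting [peak_table].
#' @return A [peak_table] with one row per window. Width is reported as 4
#'   sigma of the moment-based peak spread (a baseline-width estimate for
#'   near-Gaussian peaks).
#' @export
integrate_peaks <- function(tr, windows, labels = NULL,
                            sample_id = "S1", role = "sample") {
  if (!inherits(tr, "chrom_trace")) stop("tr must be a chrom_trace")
  if (!length(windows)) stop("no integration windows given")
  span <- range(tr$time_min)
  win <- lapply(windows, function(w) {
    if (length(w) != 2L || w[1] >= w[2]) stop("each window must be c(start, end) with start < end")
    if (w[1] < span[1] || w[2] > span[2]) stop("window outside trace span")
    w
  })
  ord <- order(vapply(win, `[`, numeric(1), 1L))
  starts <- vapply(win, `[`, numeric(1), 1L)[ord]
  ends <- vapply(win, `[`, numeric(1), 2L)[ord]
  if (any(starts[-1] < ends[-length(ends)])) stop("windows overlap")

  if (is.null(labels)) labels <- sprintf("peak%d", seq_along(win))
  rows <- lapply(seq_along(win), function(i) {
    w <- win[[i]]
    idx <- which(tr$time_min >= w[1] & tr$time_min <= w[2])
    if (length(idx) < 2L) stop("empty integration window")
    t <- tr$time_min[idx]
    s <- tr$signal[idx]
    base <- s[1L] + (s[length(s)] - s[1L]) * (t - t[1L]) / (t[length(t)] - t[1L])
    y <- s - base
    t_s <- t * 60
    area <- sum(diff(t_s) * (y[-1L] + y[-length(y)]) / 2)
    t_r <- t[which.max(s)]
    # moment-based spread; baseline width of a Gaussian is ~4 sigma
    yp <- pmax(y, 0)
    if (sum(yp) > 0) {
      mu <- sum(t_s * yp) / sum(yp)
      sd_s <- sqrt(max(sum((t_s - mu)^2 * yp) / sum(yp), 0))
    } else sd_s <- 0
    data.frame(label = labels[i], t_r_min = t_r, width_s = 4 * sd_s,
               area = max(area, 0), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  peak_table(out$label, out$t_r_min, out$width_s, out$area,
             sample_id = sample_id, role = role)
}

#' Read / write peak-table CSV
#'
#' CSV schema: columns `sample_id, role, label, t_r_min, width_s, area`,
#' header required, UTF-8, `.` decimal separator.
#'
#' @param path File path.
#' @return `read_peak_table` returns a [peak_table].
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "role", "label", "t_r_min", "width_s", "area")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("peak-table CSV missing columns: ", paste(miss, collapse = ", "))
  peak_table(df$label, df$t_r_min, df$width_s, df$area,
             sample_id = df$sample_id, role = df$role)
}

#' @rdname read_peak_table
#' @param peaks A [peak_table] to write.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE)
  invisible(path)
}
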