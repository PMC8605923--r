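#' Paired x/y data for regression
#'
#' Light container used by every regression in the package: calibration
#' (response vs. concentration), first-order kinetics (log-recovery vs. time)
#' and Arrhenius fits (log-rate vs. inverse Kelvin temperature).
#'
#' @param x Numeric predictor vector (units context-dependent).
#' @param y Numeric response vector, same length as `x`.
#' @return An object of class `xy_data` with elements `x`, `y`, `n`.
#' @examples
#' xy_data(1:5, c(2.1, 3.9, 6.2, 8.0, 9.8))
#' @export
xy_data <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop("x and y must be numeric")
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 points")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in input")
  }
  if (stats::var(x) == 0) stop("x has zero variance: slope is unidentifiable")
  structure(list(x = as.numeric(x), y = as.numeric(y), n = length(x)),
            class = "xy_data")
}

#' Ordinary least-squares fit with inference
#'
#' Fits `y = beta0 + beta1 * x` by least squares and returns the estimates
#' together with the inferential quantities the validation and kinetics
#' modules consume: standard errors, two-sided Student-t confidence intervals
#' (n - 2 degrees of freedom), the signed Pearson correlation coefficient and
#' the coefficient of determination.
#'
#' With `n = 2` the line interpolates the points and no inference is possible;
#' the standard errors and intervals are returned as `NA` and the fit is
#' flagged with `inference = FALSE`.
#'
#' @param data An [xy_data] object (or anything coercible via `xy_data(x, y)`).
#' @param confidence_level Two-sided confidence level, default `0.95`.
#' @param intercept_se How to fill the `se_beta0` slot: `"regression"` (the
#'   standard error of the intercept estimate, the default) or `"residual_sd"`
#'   (the residual standard deviation). Both are admissible readings of the
#'   "standard deviation of the y-intercept" used by detection-limit formulas.
#' @return An object of class `linear_fit`: a list with `beta0`, `beta1`,
#'   `se_beta0`, `se_beta1`, `r`, `r2`, `ci_beta0`, `ci_beta1`, `n`,
#'   `residuals`, `sigma` (residual sd), `confidence_level`, `inference`.
#' @examples
#' fit <- ols_fit(xy_data(c(1, 2, 3), c(3, 5, 7)))
#' fit$beta1 # 2
#' @export
ols_fit <- function(data, confidence_level = 0.95,
                    intercept_se = c("regression", "residual_sd")) {
  if (!inherits(data, "xy_data")) stop("data must be an xy_data object")
  intercept_se <- match.arg(intercept_se)
  if (confidence_level <= 0 || confidence_level >= 1) {
    stop("confidence_level must be in (0, 1)")
  }
  n <- data$n
  fit <- stats::lm(y ~ x, data = list(x = data$x, y = data$y))
  est <- stats::coef(fit)
  beta0 <- unname(est[1L]); beta1 <- unname(est[2L])
  res <- unname(stats::residuals(fit))
  # correlation is undefined for a flat response; report NA rather than warn
  r <- if (stats::sd(data$y) == 0) NA_real_ else stats::cor(data$x, data$y)

  if (n >= 3L) {
    # exact fits trip summary.lm's "essentially perfect fit" warning;
    # zero residual variance is legitimate here (noiseless synthetic data)
    sm <- suppressWarnings(summary(fit))
    se <- sm$coefficients[, "Std. Error"]
    sigma <- sm$sigma
    se_beta0 <- if (intercept_se == "regression") unname(se[1L]) else sigma
    se_beta1 <- unname(se[2L])
    tq <- stats::qt(1 - (1 - confidence_level) / 2, df = n - 2L)
    # CIs always use the regression SEs, whatever fills se_beta0
    ci_beta0 <- beta0 + c(-1, 1) * tq * unname(se[1L])
    ci_beta1 <- beta1 + c(-1, 1) * tq * se_beta1
    inference <- TRUE
  } else {
    sigma <- NA_real_
    se_beta0 <- se_beta1 <- NA_real_
    ci_beta0 <- ci_beta1 <- c(NA_real_, NA_real_)
    inference <- FALSE
  }

  structure(list(
    beta0 = beta0, beta1 = beta1,
    se_beta0 = se_beta0, se_beta1 = se_beta1,
    r = r, r2 = r^2,
    ci_beta0 = ci_beta0, ci_beta1 = ci_beta1,
    n = n, residuals = res, sigma = sigma,
    confidence_level = confidence_level, inference = inference
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit (n = %d)\n", x$n))
  cat(sprintf("  beta0 = %.6g (SE %.4g), beta1 = %.6g (SE %.4g)\n",
              x$beta0, x$se_beta0, x$beta1, x$se_beta1))
  cat(sprintf("  r = %.6f, r2 = %.6f\n", x$r, x$r2))
  if (x$inference) {
    cat(sprintf("  %g%% CI beta0: [%.6g, %.6g]  beta1: [%.6g, %.6g]\n",
                100 * x$confidence_level,
                x$ci_beta0[1], x$ci_beta0[2], x$ci_beta1[1], x$ci_beta1[2]))
  }
  invisible(x)
}

#' Relative standard deviation in percent
#'
#' `100 * sd(values) / mean(values)`, the %RSD used throughout assay
#' validation reporting.
#'
#' @param values Numeric vector, length >= 2, with nonzero mean.
#' @return The %RSD as a single number.
#' @examples
#' rsd_percent(c(9, 10, 11)) # 10
#' @export
rsd_percent <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    stop("values must be a numeric vector of length >= 2")
  }
  if (anyNA(values)) stop("values contain NA")
  m <- mean(values)
  if (m == 0) stop("mean is zero: RSD undefined")
  100 * stats::sd(values) / m
}
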