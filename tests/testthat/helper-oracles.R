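# Independent oracles: deliberately primitive implementations that never
# share code with the package internals they check.

# Direct 2x2 normal-equations solve for simple linear regression.
oracle_ols <- function(x, y) {
  n <- length(x)
  xtx <- matrix(c(n, sum(x), sum(x), sum(x^2)), 2, 2)
  xty <- c(sum(y), sum(x * y))
  beta <- solve(xtx, xty)
  list(beta0 = beta[1], beta1 = beta[2])
}

# Two-pass sample variance, then %RSD.
oracle_rsd <- function(v) {
  m <- sum(v) / length(v)
  s2 <- sum((v - m)^2) / (length(v) - 1)
  100 * sqrt(s2) / m
}

# Pearson correlation from the textbook sum formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Brute-force SSE grid search for the Arrhenius parameters (A, E) of
# ln k = A - E * 11605 / T_K.
oracle_arrhenius_grid <- function(temps_c, rates, a_range, e_range, n_grid = 400) {
  t_k <- temps_c + 273.15
  a_grid <- seq(a_range[1], a_range[2], length.out = n_grid)
  e_grid <- seq(e_range[1], e_range[2], length.out = n_grid)
  best <- c(NA, NA); best_sse <- Inf
  for (a in a_grid) {
    # vectorize over E for speed
    pred <- outer(e_grid, 1 / t_k, function(e, it) a - e * 11605 * it)
    sse <- rowSums((sweep(pred, 2, log(rates)))^2)
    i <- which.min(sse)
    if (sse[i] < best_sse) {
      best_sse <- sse[i]
      best <- c(a, e_grid[i])
    }
  }
  list(a_param = best[1], e_param = best[2], sse = best_sse)
}

# Fine-grid trapezoid quadrature of a Gaussian peak above zero baseline.
oracle_gauss_area <- function(center_s, area, sd_s, from_s, to_s, n = 200001) {
  t <- seq(from_s, to_s, length.out = n)
  y <- area / (sd_s * sqrt(2 * pi)) * exp(-(t - center_s)^2 / (2 * sd_s^2))
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}

make_series <- function(k, times = c(0, 24, 72, 120), temp = 25,
                        condition = "temperature", noise = NULL,
                        sample_id = "STD") {
  rec <- 100 * exp(-k * times)
  if (!is.null(noise)) rec <- rec * noise
  degradation_series(condition, temp, times, rec, sample_id = sample_id)
}
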