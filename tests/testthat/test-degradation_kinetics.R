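test_that("fit_first_order recovers a noiseless exponential exactly", {
  fit <- fit_first_order(make_series(0.01))
  expect_equal(fit$k0, 0.01, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, log(100), tolerance = 1e-12)

  flat <- fit_first_order(make_series(0))
  expect_equal(flat$k0, 0)
  expect_equal(flat$r2, 1) # zero residuals on constant series
})

test_that("zero recoveries are excluded and over-truncated series error", {
  s <- degradation_series("base", 60, c(0, 24, 72, 120),
                          c(100, 5, 0, 0))
  fit <- fit_first_order(s)
  expect_equal(fit$excluded_points, c(3L, 4L))
  expect_equal(fit$n_points_used, 2L)

  dead <- degradation_series("base", 60, c(0, 24, 72), c(100, 0, 0))
  expect_error(fit_first_order(dead), "fewer than 2")
})

test_that("anchored fit forces 100% at t = 0", {
  s <- degradation_series("acid", 40, c(0, 24, 72, 120),
                          c(97, 80, 60, 45))
  fit <- fit_first_order(s, anchor_t0 = TRUE)
  expect_equal(fit$intercept, log(100))
  free <- fit_first_order(s)
  expect_false(isTRUE(all.equal(fit$k0, free$k0)))
})

test_that("first-order parameter recovery over seeded replications", {
  # true k0 = 0.005/h, 1% multiplicative noise, 500 replications: the mean
  # estimate must land within 2 Monte-Carlo standard errors of the truth
  set.seed(515)
  ks <- replicate(500, {
    noise <- 1 + rnorm(4, sd = 0.01)
    fit_first_order(make_series(0.005, noise = noise))$k0
  })
  mc_se <- sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - 0.005), 2 * mc_se + 1e-6)
})

test_that("fit_arrhenius solves two-point systems exactly", {
  t_k <- c(313.15, 333.15)
  k <- exp(30 - 0.8 * 11605 / t_k)
  m <- fit_arrhenius(setNames(k, c(40, 60)))
  expect_equal(m$e_param, 0.8, tolerance = 1e-9)
  expect_equal(m$a_param, 30, tolerance = 1e-6)
  expect_equal(m$r2, 1)
  expect_equal(m$b_const, 1 / 11605)

  flat <- fit_arrhenius(setNames(c(0.01, 0.01), c(40, 60)))
  expect_equal(flat$e_param, 0, tolerance = 1e-12)
  expect_error(fit_arrhenius(setNames(0.01, 40)), "2 distinct temperatures")
  expect_error(fit_arrhenius(setNames(c(-1, 1), c(40, 60))), "positive")
})

test_that("fit_arrhenius matches a brute-force grid-search oracle", {
  set.seed(616)
  temps <- c(25, 40, 60)
  true_a <- 12; true_e <- 0.5
  k <- exp(true_a - true_e * 11605 / (temps + 273.15)) * rlnorm(3, sdlog = 0.05)
  m <- fit_arrhenius(setNames(k, temps))
  orc <- oracle_arrhenius_grid(temps, k, a_range = m$a_param + c(-2, 2),
                               e_range = m$e_param + c(-0.1, 0.1), n_grid = 401)
  # agreement to within the oracle's grid resolution (0.01 in A, 5e-4 in E)
  expect_lt(abs(m$a_param - orc$a_param), 0.011)
  expect_lt(abs(m$e_param - orc$e_param), 5.5e-4)
})

test_that("adjusted_rate interpolates, extrapolates and degenerates correctly", {
  k <- exp(14 - 0.46 * 11605 / (c(40, 60) + 273.15))
  m <- fit_arrhenius(setNames(k, c(40, 60)))
  at40 <- adjusted_rate(m, 40)
  expect_equal(as.numeric(at40), k[1], tolerance = 1e-9)
  expect_false(attr(at40, "extrapolated"))
  at25 <- adjusted_rate(m, 25)
  expect_true(attr(at25, "extrapolated"))

  m0 <- fit_arrhenius(setNames(c(0.02, 0.02), c(40, 60)))
  expect_equal(as.numeric(adjusted_rate(m0, -40)), exp(m0$a_param), tolerance = 1e-9)
  expect_error(adjusted_rate(m, -300), "absolute zero")
})

test_that("adjusted_rate increases with temperature when E > 0", {
  k <- exp(10 - 0.45 * 11605 / (c(4, 60) + 273.15))
  m <- fit_arrhenius(setNames(k, c(4, 60)))
  temps <- seq(-20, 80, by = 5)
  rates <- vapply(temps, function(tc) as.numeric(adjusted_rate(m, tc)), numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("t90 matches hand and published-style values", {
  expect_equal(t90(0.04275), 2.46, tolerance = 5e-3)
  expect_equal(t90(log(10 / 9)), 1.0, tolerance = 1e-12)
  expect_equal(t90(0.4795), 0.22, tolerance = 5e-3)
  expect_error(t90(0), "positive")
  expect_error(t90(0.1, c0 = -1), "positive")
})

test_that("t90 is independent of c0 and exactly ln(10/9)/ka", {
  set.seed(717)
  for (i in 1:50) {
    ka <- runif(1, 1e-4, 1)
    expect_equal(t90(ka) * ka, log(10 / 9), tolerance = 1e-12)
    expect_equal(t90(ka, c0 = runif(1, 0.1, 500)), t90(ka), tolerance = 1e-12)
  }
})

test_that("log-base choice leaves t90 invariant", {
  set.seed(818)
  for (i in 1:25) {
    k <- runif(1, 1e-4, 0.05)
    noise <- 1 + rnorm(4, sd = 0.01)
    s <- make_series(k, noise = noise)
    f_e <- fit_first_order(s, log_base = "e")
    f_10 <- fit_first_order(s, log_base = "10")
    expect_equal(f_10$k0, f_e$k0 / log(10), tolerance = 1e-12)
    expect_equal(t90(f_10$k0, log_base = "10"), t90(f_e$k0, log_base = "e"),
                 tolerance = 1e-9)
  }
})

test_that("E parameter recovery stays within 15% median relative error", {
  # synthetic 3-temperature studies, true E in [0.3, 1.2] eV, 2% RSD noise
  set.seed(919)
  n_rep <- 200
  rel_err <- numeric(n_rep)
  temps <- c(25, 40, 60)
  for (i in seq_len(n_rep)) {
    true_e <- runif(1, 0.3, 1.2)
    # anchor A so that k(60 C) ~ 0.02/h: decays measurably within 120 h
    true_a <- log(0.02) + true_e * 11605 / 333.15
    ks <- numeric(length(temps))
    usable <- TRUE
    for (j in seq_along(temps)) {
      k <- exp(true_a - true_e * 11605 / (temps[j] + 273.15))
      noise <- 1 + rnorm(4, sd = 0.02)
      fit <- tryCatch(fit_first_order(make_series(k, temp = temps[j], noise = noise)),
                      error = function(e) NULL)
      if (is.null(fit) || fit$k0 <= 0) { usable <- FALSE; break }
      ks[j] <- fit$k0
    }
    rel_err[i] <- if (usable) {
      m <- fit_arrhenius(setNames(ks, temps))
      abs(m$e_param - true_e) / true_e
    } else NA_real_
  }
  expect_lt(median(rel_err, na.rm = TRUE), 0.15)
})

test_that("stability_table computes closed-form rows and the t90 identity", {
  s <- make_series(0.01, temp = 40)
  tab <- stability_table(list(s))
  expect_equal(tab$ka_e3, 10, tolerance = 1e-9)
  expect_equal(tab$t90_h, log(10 / 9) / 0.01, tolerance = 1e-9)
  expect_equal(tab$r2, 1, tolerance = 1e-12)
  expect_true(is.na(tab$arrhenius_r2)) # single temperature: no adjustment

  # synthetic 4-temperature study: every row satisfies t90 * ka = ln(10/9)
  des <- study_design(seed = 99, noise_rsd = 1)
  study <- gen_degradation_study(des)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(study$data, path, row.names = FALSE)
  tab4 <- stability_table(read_degradation(path))
  expect_gt(nrow(tab4), 10)
  expect_equal(tab4$t90_h * tab4$ka_per_h, rep(log(10 / 9), nrow(tab4)),
               tolerance = 1e-12)
})

test_that("stability_table footnotes truncated series", {
  s_trunc <- degradation_series("base", 60, c(0, 24, 72, 120),
                                c(100, 4, 0, 0), sample_id = "F2")
  tab <- stability_table(list(s_trunc))
  expect_true(tab$truncated)
  expect_equal(tab$n_points_used, 2L)

  dead <- degradation_series("base", 60, c(0, 24, 72, 120), c(100, 0, 0, 0))
  expect_warning(
    tab2 <- stability_table(list(dead, make_series(0.01))),
    "skipping")
  expect_equal(nrow(tab2), 1L)
})

test_that("degradation CSV reader averages replicates per time point", {
  df <- data.frame(sample_id = "STD", condition = "acid", temperature_c = 40,
                   time_h = rep(c(0, 24), each = 2), replicate = rep(1:2, 2),
                   recovery_pct = c(99, 101, 79, 81))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  series <- read_degradation(path)
  expect_length(series, 1L)
  expect_equal(series[[1]]$recovery_pct, c(100, 80))
})
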