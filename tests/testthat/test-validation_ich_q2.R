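cal_table <- function(levels, f, reps = 3) {
  conc <- rep(levels, each = reps)
  calibration_table(conc, rep(seq_len(reps), length(levels)), f(conc),
                    kind = "system")
}

test_that("system linearity passes on proportional data, fails on forced intercept", {
  levels <- c(0.525, 1.05, 2.1, 4.2, 8.4, 16.8)
  prop <- cal_table(levels, function(x) 50000 * x)
  res <- system_linearity(prop)
  expect_equal(res$r, 1)
  expect_true(res$flags$ci_beta0_contains_zero)
  expect_true(res$pass)

  set.seed(5)
  shifted <- cal_table(levels, function(x) (50000 * x + 10000) * (1 + rnorm(length(x), sd = 1e-4)))
  res2 <- system_linearity(shifted)
  expect_false(res2$flags$ci_beta0_contains_zero)
  expect_false(res2$pass)
})

test_that("system linearity r matches an independent Pearson oracle", {
  set.seed(6)
  levels <- c(0.525, 1.05, 2.1, 4.2, 8.4, 16.8)
  tab <- cal_table(levels, function(x) 50000 * x * (1 + rnorm(length(x), sd = 0.01)))
  res <- system_linearity(tab)
  expect_equal(res$r, oracle_pearson(tab$level_ug_ml, tab$response),
               tolerance = 1e-9)
  expect_equal(res$r2, res$r^2, tolerance = 1e-12)
})

test_that("method linearity on identity data gives perfect recovery", {
  added <- rep(3.5 * c(80, 90, 100, 110, 120) / 100, each = 3)
  tab <- calibration_table(added, rep(1:3, 5), added, kind = "method")
  res <- method_linearity(tab, nominal = 3.5)
  expect_equal(res$mean_recovery, 100)
  expect_equal(res$fit$beta1, 1)
  expect_equal(res$fit$beta0, 0, tolerance = 1e-12)
  expect_true(res$pass)
})

test_that("recovery bounds are inclusive at the 102 boundary", {
  added <- rep(3.5 * c(80, 90, 100, 110, 120) / 100, each = 3)
  tab <- calibration_table(added, rep(1:3, 5), 1.02 * added, kind = "method")
  res <- method_linearity(tab, nominal = 3.5)
  expect_equal(res$mean_recovery, 102)
  expect_true(res$flags$recovery)
})

test_that("method linearity recovers a simulated true recovery", {
  # true recovery 100.1%, RSD 1.2%: the estimate must sit within the
  # generator's standard error band (se = rsd / sqrt(n))
  des <- study_design(noise_rsd = 1.2, seed = 77)
  gen <- gen_method_table(des, true_recovery_pct = 100.1)
  res <- method_linearity(gen$table, nominal = 3.5)
  se <- 1.2 / sqrt(nrow(gen$table))
  expect_lt(abs(res$mean_recovery - 100.1), 3 * se)
  expect_lt(res$rsd, 2.5)
})

test_that("inverse prediction through the system fit recovers concentrations", {
  des <- study_design(noise_rsd = 0, seed = 1)
  sys <- system_linearity(gen_calibration(des, slope = 48000, intercept = 500)$table)
  gen <- gen_method_table(des, true_recovery_pct = 100, as_area = TRUE,
                          slope = 48000, intercept = 500)
  res <- method_linearity(gen$table, nominal = 3.5, system_fit = sys$fit)
  expect_equal(res$mean_recovery, 100, tolerance = 1e-9)
})

test_that("accuracy_precision computes oracle statistics and verdicts", {
  perfect <- accuracy_precision(c(100, 100, 100))
  expect_equal(perfect$mean_recovery, 100)
  expect_equal(perfect$rsd, 0)
  expect_true(perfect$pass)

  spread <- accuracy_precision(c(95, 105))
  expect_equal(spread$mean_recovery, 100)
  expect_false(spread$flags$rsd)      # RSD 7.07 > 2
  expect_false(spread$flags$residuals) # |residual| 5 > 2
  expect_false(spread$pass)

  set.seed(8)
  v <- rnorm(15, mean = 100.2, sd = 1.5)
  res <- accuracy_precision(v)
  expect_equal(res$mean_recovery, sum(v) / 15, tolerance = 1e-12)
  expect_equal(res$rsd, oracle_rsd(v), tolerance = 1e-12)
  expect_error(accuracy_precision(numeric(0)), "length >= 2")
})

test_that("lod_loq follows the 3.3/10 intercept-dispersion rule", {
  fit <- structure(list(beta0 = 0, beta1 = 1, se_beta0 = 0.3, n = 18),
                   class = "linear_fit")
  lim <- lod_loq(fit)
  expect_equal(lim$lod, 0.99)
  expect_equal(lim$loq, 3.0)

  fit$se_beta0 <- 0
  lim0 <- lod_loq(fit)
  expect_equal(lim0$lod, 0)
  expect_equal(lim0$loq, 0)

  fit$se_beta0 <- 0.3; fit$beta1 <- -1
  expect_error(lod_loq(fit), "slope must be positive")
})

test_that("loq/lod ratio is exactly 10/3.3 for any fit", {
  set.seed(9)
  for (i in 1:50) {
    x <- runif(12, 0.5, 17)
    y <- runif(1, 1e3, 1e5) * x * (1 + rnorm(12, sd = 0.02))
    lim <- lod_loq(ols_fit(xy_data(x, y)))
    expect_equal(lim$loq / lim$lod, 10 / 3.3, tolerance = 1e-12)
  }
})

test_that("robustness_diff reproduces reported |di| rows", {
  expect_equal(robustness_diff(100.00, 100.00), 0.00) # pH perturbation row
  expect_equal(robustness_diff(100.00, 100.01), 0.01) # instrument-change row
  expect_equal(robustness_diff(99.89, 99.89), 0)
})

test_that("specificity decision rule flags only interfering peaks", {
  none <- specificity_check(peak_table("x", 1, 1, 1)[0, ], 2.6)
  expect_true(none$pass)

  placebo <- peak_table("ghost", 2.6, 20, 100, role = "placebo")
  hit <- specificity_check(placebo, 2.6, tolerance = 0.2)
  expect_false(hit$pass)
  expect_equal(nrow(hit$interfering), 1L)

  # stressed-sample degradants: seven peaks, none within 0.2 min of 2.6
  degradants <- peak_table(paste0("deg", 1:7),
                           c(0.7, 1.0, 1.4, 1.8, 3.2, 3.9, 5.0),
                           rep(20, 7), rep(1e4, 7), role = "sample")
  ok <- specificity_check(degradants, 2.6, tolerance = 0.2)
  expect_true(ok$pass)
  expect_error(specificity_check(degradants, 2.6, tolerance = 0), "positive")
})

test_that("pass flags are monotone in their thresholds", {
  set.seed(10)
  des <- study_design(noise_rsd = 1, seed = 10)
  tab <- gen_method_table(des, true_recovery_pct = 100.5)$table
  r_thresholds <- c(0.9, 0.99, 0.999, 0.99999)
  passes <- vapply(r_thresholds, function(rt) {
    method_linearity(tab, 3.5, validation_criteria(r_min = rt))$flags$r
  }, logical(1))
  # tightening the threshold can only flip pass -> fail, never the reverse
  expect_equal(passes, as.logical(cummin(passes)))
})

test_that("calibration tables validate their invariants", {
  expect_error(calibration_table(c(1, 2), 1:2, c(5, 6)), "3 distinct levels")
  expect_error(calibration_table(c(-1, 2, 3), 1:3, c(5, 6, 7)), "positive")
  tab <- calibration_table(c(1, 2, 3), c(1, 1, 1), c(5, 10, 15))
  expect_true(attr(tab, "balanced"))
})
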