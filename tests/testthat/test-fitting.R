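test_that("normalization divides by the control mean", {
  pl <- gradient_plate(c(0, 0, 50, 100), c(2, 2, 1, 0.5))
  norm <- normalize_to_control(pl)
  expect_equal(norm$response_norm, c(1, 1, 0.5, 0.25))
  pl0 <- gradient_plate(c(0, 50), c(0, 1))
  expect_error(normalize_to_control(pl0), "positive")
  expect_error(gradient_plate(c(10, 50), c(1, 1)), "control")
  expect_warning(gradient_plate(c(0, 10, 50), c(1, 1, 1)), "two-fold")
})

test_that("noise-free self-recovery reproduces both presets to 1e-6", {
  f_comm <- fit_plate(comm, noise = noise_model(sd = 0, seed = 1))
  expect_equal(f_comm$log_ic50, -1.914, tolerance = 1e-6)
  expect_equal(f_comm$hill_slope, -1.813, tolerance = 1e-6)
  expect_true(f_comm$log_ic50_ci[1] <= f_comm$log_ic50)
  expect_true(f_comm$log_ic50_ci[2] >= f_comm$log_ic50)
  f_bmsr <- fit_plate(bmsr, noise = noise_model(sd = 0, seed = 1))
  expect_equal(f_bmsr$log_ic50, -2.099, tolerance = 1e-6)
  expect_equal(f_bmsr$hill_slope, -1.108, tolerance = 1e-6)
})

test_that("self-recovery holds across random strains (property)", {
  set.seed(11)
  for (i in 1:12) {
    s <- random_strain()   # IC50 in [1, 200] mM, slope in [-4, -0.5]
    f <- fit_plate(s, noise = noise_model(sd = 0, seed = i))
    expect_equal(f$log_ic50, s$log_ic50, tolerance = 1e-4)
    expect_equal(f$hill_slope, s$hill_slope, tolerance = 1e-4)
  }
})

test_that("fit respects the documented mM-to-molar convention", {
  # feeding concentrations in M instead of mM must shift logIC50 by
  # exactly log10(1000)
  pl <- normalize_to_control(
    gen_plate_gradient(comm, noise = noise_model(sd = 0, seed = 1)))
  f_mM <- fit_dose_response(pl$concentration_mM, pl$response_norm)
  f_M <- fit_dose_response(pl$concentration_mM / 1000, pl$response_norm)
  expect_equal(f_M$log_ic50 - f_mM$log_ic50, -3, tolerance = 1e-6)
  expect_equal(f_M$hill_slope, f_mM$hill_slope, tolerance = 1e-6)
})

test_that("fit preconditions: enough concentrations, sane responses", {
  expect_error(fit_dose_response(c(0, 10, 20, 40), c(1, 0.8, 0.5, 0.2)),
               "at least 4")
  expect_error(fit_dose_response(c(10, 20, 40, 80), c(2, 0.8, 0.5, 0.2)),
               "within")
})

test_that("noisy recovery envelope: median logIC50 error under 0.05 at noise sd 0.05", {
  errs <- vapply(1:100, function(s) {
    f <- fit_plate(comm, noise = noise_model(sd = 0.05, seed = s),
                   replicates = 3)
    abs(f$log_ic50 - comm$log_ic50)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("growth-rate extraction recovers exponential and logistic rates", {
  tt <- seq(0, 40, by = 2)
  pure <- growth_curve_set(tt, rep(0, length(tt)), 0.01 * exp(0.13 * tt))
  r <- estimate_growth_rate(pure)
  expect_equal(r$rate_per_h, 0.13, tolerance = 1e-9)
  expect_false(r$flagged)
  # logistic curves from the generator: early-phase window slope
  gc <- gen_growth_curves(bmsr, 0, duration = 72,
                          noise = noise_model(sd = 0, seed = 1))
  r2 <- estimate_growth_rate(gc)
  expect_equal(r2$rate_per_h, 0.2, tolerance = 0.05)
  # flat curve: flagged, near-zero rate
  expect_warning(
    rf <- estimate_growth_rate(
      growth_curve_set(tt, rep(0, length(tt)), rep(0.5, length(tt)))),
    "exponential window")
  expect_true(rf$flagged)
  expect_equal(rf$rate_per_h, 0, tolerance = 1e-8)
})

test_that("growth-rate dose-response recovers the strain constants", {
  grad <- c(500 / 2^(0:8), 0)
  # exact rates: perfect recovery
  rates <- data.frame(perchlorate_mM = grad,
                      rate_per_h = effective_growth_rate(grad, comm))
  f <- dose_response_from_growth_rates(rates)
  expect_equal(f$log_ic50, comm$log_ic50, tolerance = 1e-8)
  expect_equal(f$hill_slope, comm$hill_slope, tolerance = 1e-8)
  expect_identical(f$source, "growth_rate")
  # duplicate control rows: mean is used
  rates2 <- rbind(rates, data.frame(perchlorate_mM = 0, rate_per_h = 0.13))
  f2 <- dose_response_from_growth_rates(rates2)
  expect_equal(f2$log_ic50, comm$log_ic50, tolerance = 1e-8)
  expect_error(dose_response_from_growth_rates(
    data.frame(perchlorate_mM = grad[1:5],
               rate_per_h = rep(0.1, 5))), "control")
  # full pipeline from noise-free synthetic curves (window-slope bias only)
  gc0 <- gen_growth_curves(comm, grad, duration = 72,
                           noise = noise_model(sd = 0, seed = 1))
  fp <- dose_response_from_growth_rates(estimate_growth_rate(gc0))
  expect_equal(fp$log_ic50, comm$log_ic50, tolerance = 0.01)
  # and with mild multiplicative noise
  gcn <- gen_growth_curves(comm, grad, duration = 72,
                           noise = noise_model(sd = 0.02, seed = 7),
                           replicates = 3)
  fn <- dose_response_from_growth_rates(
    suppressWarnings(estimate_growth_rate(gcn)))
  expect_lt(abs(fn$log_ic50 - comm$log_ic50), 0.1)
})

test_that("sulfide calibration regression: self-recovery, R2 identity, errors", {
  srm <- c(0.5, 1, 2, 5, 10, 20, 40)
  s_exact <- sulfide_from_srm(srm, ref_calib)
  cal <- fit_sulfide_calibration(srm, s_exact)
  expect_equal(cal$slope, 0.6786, tolerance = 1e-9)
  expect_equal(cal$intercept, -0.7375, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_identical(attr(cal, "data_used"), "points")
  # internal consistency: R2 = 1 - SSE/SST in log space
  set.seed(3)
  s_noisy <- s_exact * exp(stats::rnorm(length(srm), 0, 0.3))
  cal_n <- fit_sulfide_calibration(srm, s_noisy)
  pred <- cal_n$slope * log10(srm) + cal_n$intercept
  sse <- sum((log10(s_noisy) - pred)^2)
  sst <- sum((log10(s_noisy) - mean(log10(s_noisy)))^2)
  expect_equal(cal_n$r_squared, 1 - sse / sst, tolerance = 1e-12)
  # means mode aggregates duplicated srm values
  cal_m <- fit_sulfide_calibration(c(srm, srm), c(s_exact * 1.1, s_exact / 1.1),
                                   data_used = "means")
  expect_identical(attr(cal_m, "data_used"), "means")
  expect_equal(attr(cal_m, "n"), length(srm))
  expect_error(fit_sulfide_calibration(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_sulfide_calibration(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("noisy calibration recovers the slope at realistic scatter", {
  # log-space noise sized so typical R2 sits near the published 0.79
  srm <- 10^seq(-0.3, 1.6, length.out = 30)
  truth <- sulfide_from_srm(srm, ref_calib)
  res <- t(vapply(1:100, function(s) {
    set.seed(s)
    obs <- truth * exp(stats::rnorm(length(srm), 0, 0.44))
    cal <- fit_sulfide_calibration(srm, obs)
    c(err = abs(cal$slope - 0.6786), r2 = cal$r_squared)
  }, numeric(2)))
  expect_lt(stats::median(res[, "err"]), 0.1)
  expect_equal(stats::median(res[, "r2"]), 0.79, tolerance = 0.15)
})

test_that("IC50 fold change is pure log arithmetic", {
  f1 <- fit_plate(comm, noise = noise_model(sd = 0, seed = 1))
  expect_equal(ic50_fold_change(f1, f1), 1)
  shifted <- strain_params("adapted", comm$mu_max, comm$log_ic50 + 0.2,
                           comm$hill_slope)
  f2 <- fit_plate(shifted, noise = noise_model(sd = 0, seed = 1))
  expect_equal(ic50_fold_change(f2, f1), 10^0.2, tolerance = 1e-6)
  expect_equal(10^0.3, 2, tolerance = 1e-2)
})
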