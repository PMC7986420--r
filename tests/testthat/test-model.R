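test_that("polynomial fitting recovers exact and noisy truths", {
  # exact degree-4 data from 7 points: interpolation identity, degree 4 kept
  en <- seq(60, 250, length.out = 7)
  u <- (en - mean(range(en))) / (diff(range(en)) / 2)
  truth4 <- 2 + 0.5 * u - 0.3 * u^2 + 0.1 * u^3 + 0.05 * u^4
  fit <- fit_parameter_polynomial(en, truth4)
  expect_equal(fit$degree, 4)
  expect_equal(predict(fit, en), truth4, tolerance = 1e-9)
  # constant data: degree 4 with vanishing non-constant coefficients
  fitc <- fit_parameter_polynomial(en, rep(3.2, 7))
  expect_equal(fitc$degree, 4)
  expect_equal(fitc$coefficients[-1], rep(0, 4), tolerance = 1e-9)
  expect_equal(fitc$coefficients[1], 3.2, tolerance = 1e-12)
  # degree-6 truth at 20 points with tiny noise: degree 6 selected
  en20 <- seq(60, 250, length.out = 20)
  u20 <- (en20 - mean(range(en20))) / (diff(range(en20)) / 2)
  truth6 <- 5 - u20 + 0.8 * u20^2 - 0.6 * u20^3 + 0.5 * u20^4 -
    0.8 * u20^5 + 0.9 * u20^6
  set.seed(5)
  noise <- rnorm(20, 0, 1e-3)
  fit6 <- fit_parameter_polynomial(en20, truth6 + noise)
  expect_equal(fit6$degree, 6)
  expect_lt(max(abs(fit6$residuals)), 3e-3)
  expect_error(fit_parameter_polynomial(en[1:4], 1:4), "at least 5")
})

test_that("beam model build validates inputs and interpolates smooth truths", {
  truth <- make_machine_truth("synchrotron-20", seed = 1)
  tp <- truth_parameters(truth)
  tuned <- data.frame(energy_nominal = tp$energy_nominal, energy = tp$energy_true,
                      sigma_e = tp$sigma_e,
                      sigma_x = tp$sigma_x, theta_x = tp$theta_x,
                      epsilon_x = tp$epsilon_x, sign_x = tp$sign_x,
                      sigma_y = tp$sigma_y, theta_y = tp$theta_y,
                      epsilon_y = tp$epsilon_y, sign_y = tp$sign_y)
  model <- build_beam_model(tuned)
  # smooth truth curves are reproduced at untuned intermediate energies
  mid <- (tp$energy_nominal[-1] + tp$energy_nominal[-20]) / 2
  pars <- beam_model_parameters(model, mid)
  tp_mid <- truth_parameters(truth, mid)
  for (p in c("sigma_x", "theta_x", "epsilon_x", "sigma_y", "sigma_e")) {
    expect_lt(max(abs(pars[[p]] / tp_mid[[p]] - 1)), 0.005)
  }
  # model evaluation at tuned energies stays within the fit residual
  pars_t <- beam_model_parameters(model, tp$energy_nominal)
  expect_lt(max(abs(pars_t$sigma_x / tp$sigma_x - 1)), 0.02)
  expect_error(build_beam_model(tuned[1:4, ]), ">= 5")
})

test_that("beam model JSON round trip reproduces evaluations exactly", {
  fx <- pipeline_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_beam_model(fx$model, path)
  back <- read_beam_model(path)
  probe <- seq(fx$model$energy_range[1], fx$model$energy_range[2],
               length.out = 100)
  expect_identical(beam_model_parameters(back, probe),
                   beam_model_parameters(fx$model, probe))
  # byte-stable serialization
  path2 <- withr::local_tempfile(fileext = ".json")
  write_beam_model(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("dose scaling factor is the mean measured/simulated ratio", {
  expect_equal(dose_scaling_factor(c(1, 2, 3), c(1, 2, 3)), 1.0)
  # simulation uniformly 3.5% above measurement
  meas <- c(2.00, 2.10, 1.95, 2.05)
  expect_equal(dose_scaling_factor(meas, meas * 1.035), 1 / 1.035,
               tolerance = 1e-12)
  expect_equal(dose_scaling_factor(2 * meas, meas * 1.035),
               2 / 1.035, tolerance = 1e-12)   # scale equivariance
  # applying the factor zeroes the mean relative difference by construction
  set.seed(8)
  sim <- meas * runif(4, 0.9, 1.1)
  f <- dose_scaling_factor(meas, sim)
  expect_equal(mean(meas / (f * sim)), 1, tolerance = 1e-12)
  expect_equal(dose_scaling_factor(c(2, 4), c(1, 4), "ratio_of_means"), 1.2)
  expect_error(dose_scaling_factor(c(1, -1), c(1, 1)), "positive")
  expect_error(dose_scaling_factor(1:3, 1:2), "equal")
})

test_that("model evaluation is self-consistent and well-aggregated", {
  fx <- pipeline_fixture()
  # zero-noise measurements generated from the model itself evaluate to ~0
  truth <- fx$truth
  model <- fx$model
  eval_e <- fx$report$eval_energies
  ms0 <- fx$ms
  for (e in eval_e) {
    mp <- beamtune:::model_planes_at(model, e)
    idc <- simulate_idc(mp$spectrum)
    ms0$idc[[as.character(e)]] <- idc
  }
  # patch spots of the eval energies to the model forward values
  for (e in eval_e) {
    sel <- ms0$spots$energy == e
    mp <- beamtune:::model_planes_at(model, e)
    ms0$spots$fwhm_x_mm[sel] <- spot_fwhm_at(mp$x, ms0$geometry, mp$spectrum,
                                             ms0$spots$position_mm[sel])
    ms0$spots$fwhm_y_mm[sel] <- spot_fwhm_at(mp$y, ms0$geometry, mp$spectrum,
                                             ms0$spots$position_mm[sel])
  }
  rep0 <- evaluate_model(model, ms0, n_eval = 5)
  idx <- rep0$summary$metric %in% c("R80", "BPW80", "BPW50")
  expect_lt(max(abs(rep0$summary$avg_abs_mm[idx])), 1e-6)
  # FWHM differs only by the half-max grid-extraction bias
  expect_lt(rep0$summary$mean_absolute_rel_pct[rep0$summary$metric == "FWHM"],
            0.1)
  # aggregation invariant: min <= avg <= max per metric
  s <- fx$report$summary
  expect_true(all(s$min_abs_mm <= s$avg_abs_mm + 1e-12))
  expect_true(all(s$avg_abs_mm <= s$max_abs_mm + 1e-12))
})
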