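test_that("weighting functions are the stated least-squares arithmetic", {
  expect_equal(energy_objective(1, 100.0, function(e) 99.5), 0.25)
  expect_equal(energy_objective(1, 100.0, function(e) 100.0), 0)
  expect_equal(spread_objective(1, 4.0, function(s) 3.6), 0.16)
  expect_equal(spread_objective(1, 4.0, function(s) 4.0), 0)
  rec2 <- data.frame(position_mm = c(0, 100), fwhm_mm = c(10, 12))
  expect_equal(optics_objective(c(1, 1, 1), rec2, function(p) c(9, 13)), 2)
  expect_equal(optics_objective(c(1, 1, 1), rec2, function(p) c(10, 12)), 0)
  # a matched extra position adds a zero summand
  rec3 <- rbind(rec2, data.frame(position_mm = 200, fwhm_mm = 14))
  expect_equal(optics_objective(c(1, 1, 1), rec3, function(p) c(9, 13, 14)), 2)
  expect_error(optics_objective(c(1, 1, 1), rec2[1, , drop = FALSE],
                                function(p) 10), "at least 2")
})

test_that("regularization term and regularized objective arithmetic", {
  expect_equal(regularization_term(c(3, 2, 10), c(3, 2, 10)), 0)
  expect_equal(regularization_term(c(3.1, 2.2, 9), c(3, 2, 10)), 1.05)
  expect_equal(regularization_term(c(3, 2, 10), c(3.1, 2.2, 9)), 1.05)  # symmetric
  rec <- data.frame(position_mm = c(0, 100), fwhm_mm = c(10, 12))
  fwd <- function(p) c(9, 13)  # data term 2.0
  expect_equal(
    regularized_optics_objective(c(3.1, 2.2, 9), rec, c(3, 2, 10), 0.1, fwd),
    2.105)
  expect_equal(
    regularized_optics_objective(c(3.1, 2.2, 9), rec, c(3, 2, 10), 0, fwd), 2)
  expect_equal(
    regularized_optics_objective(c(3.1, 2.2, 9), rec, NULL, 0.1, fwd), 2)
})

test_that("Nelder-Mead minimizes standard test functions deterministically", {
  cfg <- tuning_config()
  r1 <- nelder_mead(function(x) (x[1] - 3)^2, 0, cfg)
  expect_equal(r1$par, 3, tolerance = 1e-3)
  r3 <- nelder_mead(function(x) sum((x - c(1, 2, 3))^2), c(0, 0, 0), cfg)
  expect_equal(r3$par, c(1, 2, 3), tolerance = 1e-3)
  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  cfg_r <- tuning_config(stop_param_change = 1e-8, stop_objective = 1e-12,
                         max_iterations = 2000)
  rr <- nelder_mead(rosen, c(-1.2, 1), cfg_r)
  expect_equal(rr$par, c(1, 1), tolerance = 1e-3)
  # independent cross-check of the minimum with the stats optimizer
  ref <- optim(c(-1.2, 1), rosen, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(rr$value, ref$value, tolerance = 1e-6)
  expect_error(nelder_mead(function(x) NaN, 1, cfg), "finite")
  # determinism
  r3b <- nelder_mead(function(x) sum((x - c(1, 2, 3))^2), c(0, 0, 0), cfg)
  expect_identical(r3$par, r3b$par)
  expect_identical(r3$iterations, r3b$iterations)
})

test_that("energy and spread tuning recover a synthetic spectrum", {
  idc <- simulate_idc(energy_spectrum(150, 1.0))
  fit_e <- tune_energy(idc)
  expect_lt(abs(fit_e$achieved_r80 - fit_e$measured_r80), 0.05)
  fit_s <- tune_spread(idc, fit_e$energy)
  expect_lt(abs(fit_s$achieved_bpw80 - fit_s$measured_bpw80), 0.05)
  # starting at the truth converges immediately via the objective stop
  direct <- nelder_mead(function(x) {
    energy_objective(x[1], r80(idc), function(e) {
      r80(simulate_idc(energy_spectrum(e, 1.0)))
    })
  }, 150, tuning_config())
  expect_lt(direct$value, 1e-5)
  expect_lte(direct$iterations, 1)
  # degenerate curve: no distal falloff propagates an extraction error
  mono <- data.frame(depth = 0:60, dose = seq(1, 2, length.out = 61))
  expect_error(tune_energy(mono), "falloff")
})

test_that("energy tuning result is insensitive to the fixed spread guess", {
  idc <- simulate_idc(energy_spectrum(150, 0.8))
  fits <- lapply(c(0.4, 0.8, 1.4), function(s) tune_energy(idc, sigma_e = s))
  for (f in fits) expect_lt(abs(f$achieved_r80 - f$measured_r80), 0.05)
})

test_that("spread tuning handles the zero-spread boundary", {
  idc <- simulate_idc(energy_spectrum(150, 0))  # straggling-only peak
  fit <- tune_spread(idc, 150)
  expect_lt(fit$sigma_e, 0.08)
  expect_lt(abs(fit$achieved_bpw80 - fit$measured_bpw80), 0.05)
})

test_that("optics tuning recovers synthetic truth and respects feasibility", {
  g <- beamline_geometry(-1300, list(list(length_mm = 1600, medium = "air")))
  sp <- energy_spectrum(150, 1.0)
  pos <- c(-200, -100, 0, 100, 200)
  for (sgn in c(-1, 1)) {
    pl <- optics_plane(6.5, 4.2, 0.55 * pi * 6.5 * 4.2, sgn)
    rec <- data.frame(position_mm = pos,
                      fwhm_mm = spot_fwhm_at(pl, g, sp, pos))
    fit <- tune_optics(rec, g, sp)
    expect_equal(fit$plane$sign, sgn)
    fsim <- spot_fwhm_at(fit$plane, g, sp, pos)
    expect_lt(max(abs(fsim / rec$fwhm_mm - 1)), 1e-3)
    expect_lte(fit$plane$epsilon,
               pi * fit$plane$sigma * fit$plane$theta * (1 + 1e-9))
  }
})

test_that("optics sequence regularizes against the preceding energy", {
  truth <- make_machine_truth("synchrotron-5", seed = 3)
  ms <- generate_measurements(truth, noise_config(rng_seed = 3))
  fits <- lapply(seq_along(ms$energies), function(j) {
    tune_spectrum(ms$idc[[as.character(ms$energies[j])]])
  })
  spectra <- lapply(fits, function(f) energy_spectrum(f$energy, f$sigma_e))
  cfg <- tuning_config(lambda = 0.1)
  seq_reg <- tune_optics_sequence(ms, "x", spectra, cfg)
  # single-energy measurement set: identical to an unregularized single fit
  ms1 <- measurement_set(ms$particle, ms$energies[1], ms$geometry,
                         ms$idc[1], ms$spots[ms$spots$energy == ms$energies[1], ])
  one <- tune_optics_sequence(ms1, "x", spectra[1], cfg)[[1]]
  rec1 <- ms$spots[ms$spots$energy == ms$energies[1],
                   c("position_mm", "fwhm_x_mm")]
  names(rec1) <- c("position_mm", "fwhm_mm")
  alone <- tune_optics(rec1, ms$geometry, spectra[[1]], cfg)
  expect_equal(one$plane, alone$plane)
  expect_equal(seq_reg[[1]]$plane, alone$plane)
  # regularization never degrades the data term by more than lambda * R
  for (j in 2:length(seq_reg)) {
    prev <- seq_reg[[j - 1]]$plane
    cur <- seq_reg[[j]]$plane
    slack <- seq_reg[[j]]$regularized_objective - seq_reg[[j]]$objective
    expect_gte(slack, -1e-9)  # reg part is non-negative
    expect_lte(seq_reg[[j]]$objective, seq_reg[[j]]$regularized_objective)
  }
})

test_that("objective evaluations are pure (deterministic forward engine)", {
  g <- beamline_geometry(-500, list(list(length_mm = 800, medium = "air")))
  sp <- energy_spectrum(120, 0.6)
  rec <- data.frame(position_mm = c(-100, 0, 100), fwhm_mm = c(8, 8.5, 9.2))
  fwd <- function(p) spot_fwhm_at(optics_plane(p[1], p[2], p[3], 1), g, sp,
                                  rec$position_mm)
  v1 <- optics_objective(c(3, 2, 10), rec, fwd)
  v2 <- optics_objective(c(3, 2, 10), rec, fwd)
  expect_identical(v1, v2)
})
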