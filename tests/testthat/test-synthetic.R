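test_that("machine presets match their stated layouts", {
  t20 <- make_machine_truth("synchrotron-20", seed = 1)
  expect_length(t20$energies, 20)
  expect_equal(range(t20$energies), c(62, 253))
  expect_equal(t20$positions_mm, c(-200, -100, 0, 100, 200))
  t27 <- make_machine_truth("cyclotron-27", seed = 1)
  expect_length(t27$energies, 27)
  expect_equal(range(t27$energies), c(100, 226.7))
  t5 <- make_machine_truth("synchrotron-5", seed = 1)
  expect_length(t5$energies, 5)
  expect_error(make_machine_truth("linac-3"), "unknown preset")
  # identical seeds give identical truths
  expect_identical(make_machine_truth("synchrotron-20", seed = 4),
                   make_machine_truth("synchrotron-20", seed = 4))
  # truth curves are feasible everywhere
  tp <- truth_parameters(t20)
  expect_true(all(tp$epsilon_x <= pi * tp$sigma_x * tp$theta_x))
  expect_true(all(tp$epsilon_y <= pi * tp$sigma_y * tp$theta_y))
  # infeasible custom curves are rejected
  bad <- list(curves = utils::modifyList(beamtune:::default_truth_curves(),
                                         list(frac_x = c(1.5, 0, 0))))
  expect_error(make_machine_truth("synchrotron-5", custom = bad), "infeasible")
})

test_that("generated measurements are deterministic in the noise seed", {
  truth <- make_machine_truth("synchrotron-5", seed = 1)
  a <- generate_measurements(truth, noise_config(rng_seed = 10))
  b <- generate_measurements(truth, noise_config(rng_seed = 10))
  c <- generate_measurements(truth, noise_config(rng_seed = 11))
  expect_identical(a$spots, b$spots)
  expect_identical(a$idc, b$idc)
  expect_false(identical(a$spots$fwhm_x_mm, c$spots$fwhm_x_mm))
})

test_that("zero-noise measurements equal the forward model exactly", {
  truth <- make_machine_truth("synchrotron-5", seed = 1)
  ms <- generate_measurements(truth, noise_config(0, 0, rng_seed = 1))
  tp <- truth_parameters(truth)
  j <- 3
  p <- tp[j, ]
  sp <- energy_spectrum(p$energy_true, p$sigma_e)
  expect_identical(ms$idc[[as.character(truth$energies[j])]]$dose,
                   simulate_idc(sp, truth$particle)$dose)
  sel <- ms$spots$energy == truth$energies[j]
  expect_identical(
    ms$spots$fwhm_x_mm[sel],
    spot_fwhm_at(optics_plane(p$sigma_x, p$theta_x, p$epsilon_x, p$sign_x),
                 truth$geometry, sp, truth$positions_mm, truth$particle))
})

test_that("generated R80 increases strictly with nominal energy", {
  truth <- make_machine_truth("synchrotron-20", seed = 2)
  ms <- generate_measurements(truth, noise_config(rng_seed = 2))
  r80s <- vapply(as.character(ms$energies), function(e) r80(ms$idc[[e]]),
                 numeric(1))
  expect_true(all(diff(r80s) > 0))
})

test_that("measurement sets survive a disk round trip", {
  truth <- make_machine_truth("synchrotron-5", seed = 6)
  dir <- withr::local_tempdir()
  ms <- generate_measurements(truth, noise_config(rng_seed = 6), dir = dir)
  back <- read_measurement_set(dir)
  expect_equal(back$energies, ms$energies)
  expect_equal(back$spots$fwhm_x_mm, ms$spots$fwhm_x_mm)
  for (e in as.character(ms$energies)) {
    expect_equal(back$idc[[e]]$dose, ms$idc[[e]]$dose)
    expect_equal(back$idc[[e]]$depth_mm, ms$idc[[e]]$depth_mm)
  }
  expect_equal(back$geometry$source_z_mm, ms$geometry$source_z_mm)
})
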