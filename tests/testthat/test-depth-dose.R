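test_that("Bragg-Kleeman range-energy relation and inverse", {
  r100 <- range_from_energy(100)
  expect_equal(r100, 10 * 0.0022 * 100^1.77)
  expect_equal(r100, 76.3, tolerance = 0.05)   # ~CSDA water range scale
  expect_gt(range_from_energy(150), r100)
  expect_lt(range_from_energy(0.5), 0.05)
  expect_error(range_from_energy(-1), "positive")
  expect_equal(energy_from_range(r100), 100, tolerance = 1e-9)
  # bisection oracle for the inverse
  f <- function(e) range_from_energy(e) - 76.3
  e_bisect <- uniroot(f, c(50, 150), tol = 1e-10)$root
  expect_equal(energy_from_range(76.3), e_bisect, tolerance = 1e-6)
  expect_gt(energy_from_range(0.1), 0)
  expect_error(energy_from_range(0), "positive")
  # round trip to sub-micrometer
  for (e in c(62, 100, 180, 253)) {
    expect_equal(range_from_energy(energy_from_range(range_from_energy(e))),
                 range_from_energy(e), tolerance = 1e-6)
  }
})

test_that("range sigma combines straggling and energy spread", {
  expect_equal(total_range_sigma(energy_spectrum(100, 0)),
               10 * 0.012 * 7.628211^0.935, tolerance = 1e-4)
  s0 <- total_range_sigma(energy_spectrum(150, 0))
  s1 <- total_range_sigma(energy_spectrum(150, 0.5))
  s2 <- total_range_sigma(energy_spectrum(150, 1.0))
  expect_true(s0 < s1 && s1 < s2)
  nostrag <- particle_spec("p", 1, 1, 0.0022, 1.77, straggling_c = 0,
                           mass_mev = 938.27208816)
  expect_equal(total_range_sigma(energy_spectrum(150, 0), nostrag), 0)
})

test_that("energy spectrum validates its invariants", {
  expect_error(energy_spectrum(-5), "positive")
  expect_error(energy_spectrum(100, 15), "0.1")
  expect_silent(energy_spectrum(100, 0))
})

test_that("simulated IDC has the prescribed peak structure", {
  sp <- energy_spectrum(150, 0.5)
  idc <- simulate_idc(sp)
  r_mm <- range_from_energy(150)
  s_r <- total_range_sigma(sp)
  met <- idc_metrics(idc)
  expect_gte(met$peak_depth, r_mm - 2 * s_r)
  expect_lte(met$peak_depth, r_mm)
  expect_gt(met$r80, met$peak_depth)
  expect_lt(met$r80, r_mm + 2 * s_r)
  # Gaussian tail bound beyond the falloff
  tail_dose <- idc$dose[idc$depth_mm >= r_mm + 5 * s_r]
  expect_true(all(tail_dose < 1e-3))
  # deterministic: identical inputs give bit-identical curves
  expect_identical(idc$dose, simulate_idc(sp)$dose)
  expect_error(simulate_idc(sp, grid = seq(0, 100, by = 0.1)), "grid too short")
})

test_that("R80 grows with energy and BPW80 with energy spread", {
  energies <- seq(70, 250, length.out = 20)
  r80s <- vapply(energies, function(e) r80(simulate_idc(energy_spectrum(e, 0.8))),
                 numeric(1))
  expect_true(all(diff(r80s) > 0))
  spreads <- seq(0, 1.5, by = 0.25)
  bpws <- vapply(spreads, function(s) {
    bragg_peak_width(simulate_idc(energy_spectrum(150, s)), 0.8)
  }, numeric(1))
  expect_true(all(diff(bpws) > 0))
})

test_that("Gaussian convolution preserves the integral of interior curves", {
  h <- 0.1
  x <- seq(0, 60, by = h)
  y <- exp(-(x - 30)^2 / 4)  # support well inside the grid
  out <- gaussian_convolve(y, 1.5, h)
  expect_equal(sum(out), sum(y), tolerance = 1e-9)
  expect_equal(gaussian_convolve(y, 0, h), y)  # sub-bin sigma: identity
})

test_that("simulated R80 is continuous in energy at the grid scale", {
  # regression guard: the singular-bin sampling must not make R80 jump as
  # the range sweeps across depth-grid points
  es <- seq(62.55, 62.67, by = 0.004)
  r <- vapply(es, function(e) r80(simulate_idc(energy_spectrum(e, 0.9))),
              numeric(1))
  expect_lt(max(abs(diff(r))), 0.02)
  expect_true(all(diff(r) > 0))
})
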