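test_that("waist emittance formula and feasibility checks", {
  expect_equal(emittance_at_waist(1, 1), pi)
  expect_equal(emittance_at_waist(0, 5), 0)
  expect_equal(emittance_at_waist(2, 3), 6 * pi)
  expect_error(emittance_at_waist(-1, 1), "non-negative")
  # waist <=> zero correlation; epsilon = 0 is the fully correlated limit
  expect_equal(moments_from_optics(optics_plane(2, 1, 2 * pi))$cov_xxp, 0)
  expect_equal(moments_from_optics(optics_plane(2, 1, 0, sign = 1))$cov_xxp, 2)
  expect_error(optics_plane(1, 1, 4 * pi), "infeasible")
})

test_that("free drift follows the closed form and preserves emittance", {
  m <- moments_from_optics(optics_plane(2, 1, 2 * pi))  # waist
  expect_equal(sqrt(drift_moments(m, 1000)$var_x), sqrt(5))
  expect_equal(drift_moments(m, 0), m)
  # fully anticorrelated converging beam focuses to zero width
  conv <- moments_from_optics(optics_plane(2, 1, 0, sign = -1))
  expect_equal(drift_moments(conv, 2000)$var_x, 0, tolerance = 1e-12)
  # determinant conservation over random drifts
  set.seed(7)
  for (i in 1:20) {
    sg <- runif(1, 0.5, 8); th <- runif(1, 0.5, 6)
    pl <- optics_plane(sg, th, runif(1, 0, 1) * pi * sg * th,
                       sample(c(-1, 1), 1))
    m0 <- moments_from_optics(pl)
    d0 <- m0$var_x * m0$var_xp - m0$cov_xxp^2
    m1 <- drift_moments(m0, runif(1, -3000, 3000))
    d1 <- m1$var_x * m1$var_xp - m1$cov_xxp^2
    # relative to the moment magnitudes: the determinant itself suffers
    # catastrophic cancellation as epsilon -> 0
    expect_lt(abs(d1 - d0), 1e-12 * (m1$var_x * m1$var_xp + m1$cov_xxp^2))
    expect_equal(pi * sqrt(d0), pl$epsilon, tolerance = 1e-9)
  }
})

test_that("converging beam has a unique waist at -cov/var_xp and sign mirrors it", {
  pl <- optics_plane(5, 3, 0.5 * pi * 5 * 3, sign = -1)
  m <- moments_from_optics(pl)
  z_star <- -m$cov_xxp / m$var_xp * 1e3  # mm downstream of source
  zs <- seq(0, 3000, by = 10)
  sig <- vapply(zs, function(z) sqrt(drift_moments(m, z)$var_x), numeric(1))
  expect_equal(zs[which.min(sig)], z_star, tolerance = 10)
  expect_equal(length(which(diff(sign(diff(sig))) != 0)), 1)  # single minimum
  # mirror symmetry about the waist when the sign flips
  mp <- moments_from_optics(optics_plane(5, 3, 0.5 * pi * 5 * 3, sign = 1))
  sig_m <- vapply(zs, function(z) sqrt(drift_moments(mp, -z)$var_x), numeric(1))
  expect_equal(sig, sig_m, tolerance = 1e-12)
})

test_that("air scattering increments match the quadrature oracle", {
  sp <- energy_spectrum(100)
  seg_vac <- list(length_mm = 1000, medium = "vacuum")
  inc0 <- air_scattering_increments(sp, seg_vac)
  expect_equal(c(inc0$var_x, inc0$cov_xxp, inc0$var_xp), c(0, 0, 0))
  seg <- list(length_mm = 1000, medium = "air")
  inc <- air_scattering_increments(sp, seg)
  tt <- oracle_scattering_power(100, 1000)
  orc <- oracle_fe_increments(tt, 1000)
  expect_equal(inc$var_x, orc$var_x, tolerance = 1e-6)
  expect_equal(inc$cov_xxp, orc$cov, tolerance = 1e-6)
  expect_equal(inc$var_xp, orc$var_xp, tolerance = 1e-6)
  # scattering decreases with energy
  inc200 <- air_scattering_increments(energy_spectrum(200), seg)
  expect_lt(inc200$var_x, inc$var_x)
  expect_lt(inc200$var_xp, inc$var_xp)
  expect_error(air_scattering_increments(energy_spectrum(100),
                                         list(length_mm = -5, medium = "air")))
})

test_that("spot sigma reduces to the drift form in vacuum and grows in air", {
  sp <- energy_spectrum(150)
  gv <- beamline_geometry(-1300, list(list(length_mm = 1600, medium = "vacuum")))
  ga <- beamline_geometry(-1300, list(list(length_mm = 1600, medium = "air")))
  pl <- optics_plane(2, 1, 2 * pi)  # waist at source
  expect_equal(spot_sigma_at(pl, gv, sp, -300), sqrt(5))
  zs <- c(-200, -100, 0, 100, 200)
  sv <- spot_sigma_at(pl, gv, sp, zs)
  sa <- spot_sigma_at(pl, ga, sp, zs)
  expect_true(all(sa > sv))
  expect_error(spot_sigma_at(pl, ga, sp, -1400), "upstream")
  expect_error(spot_sigma_at(pl, ga, sp, 500), "beyond")
})

test_that("lateral transport agrees with the particle-sampling oracle", {
  sp <- energy_spectrum(62)
  g <- beamline_geometry(-1300, list(list(length_mm = 1600, medium = "air")))
  pl <- optics_plane(3, 2, 0.5 * pi * 3 * 2, sign = 1)
  set.seed(11)
  mc <- oracle_mc_spot_sigma(3, 2, 0.5 * pi * 3 * 2, 1, -1300, 300, 62,
                             c(-200, 0, 200), n_particles = 2e6)
  an <- spot_sigma_at(pl, g, sp, c(-200, 0, 200))
  expect_equal(an, mc, tolerance = 0.01)
})

test_that("geometry validation rejects malformed descriptions", {
  expect_error(beamline_geometry(-100, list()), "at least one segment")
  expect_error(beamline_geometry(-100, list(list(length_mm = 0, medium = "air"))))
  expect_error(beamline_geometry(-100, list(list(length_mm = 10, medium = "steel"))),
               "unknown medium")
})
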