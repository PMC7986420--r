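# Independent oracles used by the unit and acceptance suites. These
# re-derive expected values by brute force (dense resampling, numerical
# quadrature, particle sampling) without touching the closed-form paths
# they check.

# Metric oracle: resample a curve onto a dense grid with linear
# interpolation and locate threshold crossings by scanning.
oracle_crossing <- function(x, y, level, side = c("distal", "proximal"),
                            n_dense = 1e5) {
  side <- match.arg(side)
  xs <- seq(min(x), max(x), length.out = n_dense)
  ys <- approx(x, y, xs)$y
  above <- ys >= level
  if (side == "distal") {
    idx <- which(above)
    i <- max(idx)
    if (i == length(xs)) return(xs[i])
    # refine linearly inside the last bracketing dense step
    x1 <- xs[i]; x2 <- xs[i + 1]; y1 <- ys[i]; y2 <- ys[i + 1]
    x1 + (level - y1) / (y2 - y1) * (x2 - x1)
  } else {
    idx <- which(above)
    i <- min(idx)
    if (i == 1) return(xs[1])
    x1 <- xs[i - 1]; x2 <- xs[i]; y1 <- ys[i - 1]; y2 <- ys[i]
    x1 + (level - y1) / (y2 - y1) * (x2 - x1)
  }
}

oracle_r80 <- function(x, y, level = 0.8) {
  oracle_crossing(x, y, level * max(y), "distal")
}

oracle_bpw <- function(x, y, level) {
  thr <- level * max(y)
  oracle_crossing(x, y, thr, "distal") - oracle_crossing(x, y, thr, "proximal")
}

oracle_fwhm <- function(x, y) oracle_bpw(x, y, 0.5)

# Random unimodal test curve: asymmetric peak with smooth flanks sampled
# on an irregular-amplitude grid.
random_unimodal_curve <- function() {
  n <- sample(40:120, 1)
  x <- seq(0, runif(1, 5, 50), length.out = n)
  peak <- runif(1, 0.3, 0.7) * max(x)
  # flank widths bounded by the edge distances so both flanks decay well
  # below any extraction threshold inside the grid
  wl <- runif(1, 0.1, 0.33) * peak
  wr <- runif(1, 0.1, 0.33) * (max(x) - peak)
  y <- ifelse(x <= peak, exp(-(x - peak)^2 / (2 * wl^2)),
              exp(-(x - peak)^2 / (2 * wr^2)))
  y <- y * runif(1, 0.5, 20) + runif(1, 0, 0.02)
  list(x = x, y = y)
}

# Fermi-Eyges oracle: trapezoid quadrature of the moment integrands over a
# segment with uniform scattering power.
oracle_fe_increments <- function(t_const, length_mm, n_steps = 1000) {
  s <- seq(0, length_mm, length.out = n_steps + 1)
  w <- rep(1, n_steps + 1); w[c(1, n_steps + 1)] <- 0.5
  h <- length_mm / n_steps
  lever <- length_mm - s
  list(var_x = sum(w * t_const * lever^2) * h,
       cov = sum(w * t_const * lever) * h * 1e3,
       var_xp = sum(w * t_const) * h * 1e6)
}

# Highland scattering power, written out independently of the package.
oracle_scattering_power <- function(energy_mev, length_mm, x0_mm = 304200) {
  m <- 938.27208816
  w <- m + energy_mev
  pv <- (w^2 - m^2) / w
  th <- 14.1 / pv * sqrt(length_mm / x0_mm) *
    (1 + log10(length_mm / x0_mm) / 9)
  th^2 / length_mm
}

# Particle-sampling transport oracle: draw a Gaussian phase space at the
# source and transport each particle through the air path in thin slabs,
# applying a Highland scattering kick per slab (drift ds/2, kick, drift
# ds/2), then report the sample sigma at each requested plane.
oracle_mc_spot_sigma <- function(sigma, theta, epsilon, sign, source_z,
                                 path_end_z, energy, z_positions,
                                 n_particles = 2e6, slab_mm = 150) {
  cov <- sign * sqrt(max(sigma^2 * theta^2 - (epsilon / pi)^2, 0))
  cmat <- matrix(c(sigma^2, cov, cov, theta^2), 2)
  l <- chol(cmat)
  zmat <- matrix(rnorm(2 * n_particles), ncol = 2) %*% l
  x <- zmat[, 1]          # mm
  xp <- zmat[, 2] * 1e-3  # rad
  seg_len <- path_end_z - source_z
  t_const <- oracle_scattering_power(energy, seg_len)
  out <- numeric(length(z_positions))
  for (k in seq_along(z_positions)) {
    zt <- z_positions[k]
    xx <- x; xxp <- xp
    pos <- source_z
    while (pos < zt - 1e-9) {
      ds <- min(slab_mm, zt - pos)
      xx <- xx + xxp * ds / 2
      xxp <- xxp + rnorm(n_particles, 0, sqrt(t_const * ds))
      xx <- xx + xxp * ds / 2
      pos <- pos + ds
    }
    out[k] <- sd(xx)
  }
  out
}

# Shared fixture: one tuned pipeline run on the default synthetic machine,
# computed once per test session (used by the acceptance criteria 1-3).
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- make_machine_truth("synchrotron-20", seed = 1)
      ms <- generate_measurements(truth, noise_config(rng_seed = 1))
      tr <- tune_machine(ms)
      model <- build_beam_model(tr)
      report <- evaluate_model(model, ms, n_eval = 5)
      cache <<- list(truth = truth, ms = ms, tuning = tr, model = model,
                     report = report)
    }
    cache
  }
})
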