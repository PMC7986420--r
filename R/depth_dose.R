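#' Gaussian beam energy spectrum
#'
#' The beam energy distribution is modeled as a Gaussian with mean energy
#' and energy spread. The spread must stay below 10% of the mean for the
#' forward model to be meaningful.
#'
#' @param mean_energy Mean kinetic energy \[MeV for protons, MeV/u for
#'   ions\], > 0.
#' @param sigma_energy Gaussian energy spread \[MeV\], >= 0 and
#'   < 0.1 * mean_energy.
#' @return An object of class `energy_spectrum`.
#' @export
energy_spectrum <- function(mean_energy, sigma_energy = 0) {
  if (!is.finite(mean_energy) || mean_energy <= 0) {
    stop("energy_spectrum: mean_energy must be positive", call. = FALSE)
  }
  if (!is.finite(sigma_energy) || sigma_energy < 0 || sigma_energy >= 0.1 * mean_energy) {
    stop("energy_spectrum: sigma_energy must satisfy 0 <= sigma_E < 0.1 * E", call. = FALSE)
  }
  structure(list(mean_energy = mean_energy, sigma_energy = sigma_energy),
            class = "energy_spectrum")
}

#' Bragg-Kleeman range-energy conversion
#'
#' `range_from_energy()` evaluates the continuous-slowing-down range in
#' water, `R_mm = 10 * alpha * E^p`; `energy_from_range()` is its analytic
#' inverse. The energy directly defines the beam range, which is what the
#' energy-tuning stage exploits.
#'
#' @param energy Kinetic energy \[MeV or MeV/u\], > 0. Vectorized.
#' @param particle A [particle_spec()].
#' @return Range in water \[mm\].
#' @export
#' @examples
#' range_from_energy(100)  # ~76.3 mm for protons
range_from_energy <- function(energy, particle = proton_spec()) {
  if (any(!is.finite(energy)) || any(energy <= 0)) {
    stop("range_from_energy: energy must be positive", call. = FALSE)
  }
  10 * particle$alpha * energy^particle$p
}

#' @rdname range_from_energy
#' @param range_mm Range in water \[mm\], > 0. Vectorized.
#' @export
energy_from_range <- function(range_mm, particle = proton_spec()) {
  if (any(!is.finite(range_mm)) || any(range_mm <= 0)) {
    stop("energy_from_range: range must be positive", call. = FALSE)
  }
  (range_mm / (10 * particle$alpha))^(1 / particle$p)
}

# Analytic derivative dR/dE [mm/MeV] of the Bragg-Kleeman rule.
range_energy_derivative <- function(energy, particle = proton_spec()) {
  10 * particle$alpha * particle$p * energy^(particle$p - 1)
}

#' Total sigma of the range distribution
#'
#' Combines range straggling in water with the contribution of the beam
#' energy spread: `sigma_R = sqrt(sigma_strag^2 + (sigma_E dR/dE)^2)`, with
#' `sigma_strag_cm = c * R_cm^m`. The Bragg peak width grows with both
#' terms, which is what ties BPW80 to the energy spread.
#'
#' @param spectrum An [energy_spectrum()].
#' @param particle A [particle_spec()].
#' @return Range sigma \[mm\].
#' @export
total_range_sigma <- function(spectrum, particle = proton_spec()) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  r_cm <- particle$alpha * spectrum$mean_energy^particle$p
  strag_mm <- 10 * particle$straggling_c * r_cm^particle$straggling_m
  spread_mm <- spectrum$sigma_energy *
    range_energy_derivative(spectrum$mean_energy, particle)
  sqrt(strag_mm^2 + spread_mm^2)
}

#' Sampled depth-dose curve container
#'
#' A laterally integrated depth-dose curve on a strictly increasing uniform
#' depth grid (default bin 0.1 mm).
#'
#' @param depth_mm Depths \[mm\], uniform strictly increasing grid with at
#'   least 50 samples.
#' @param dose Dose values \[arb\], >= 0.
#' @return An object of class `depth_dose_curve` (also a data.frame).
#' @export
depth_dose_curve <- function(depth_mm, dose) {
  if (length(depth_mm) < 50) {
    stop("depth_dose_curve: needs at least 50 samples", call. = FALSE)
  }
  if (length(depth_mm) != length(dose)) {
    stop("depth_dose_curve: depth and dose lengths differ", call. = FALSE)
  }
  steps <- diff(depth_mm)
  if (any(steps <= 0) || diff(range(steps)) > 1e-9 * max(steps)) {
    stop("depth_dose_curve: depth grid must be uniform and strictly increasing",
         call. = FALSE)
  }
  if (any(!is.finite(dose)) || any(dose < 0)) {
    stop("depth_dose_curve: dose must be finite and >= 0", call. = FALSE)
  }
  structure(data.frame(depth_mm = depth_mm, dose = dose),
            class = c("depth_dose_curve", "data.frame"))
}

#' Discrete Gaussian convolution on a uniform grid
#'
#' Convolves a sampled curve with a Gaussian kernel (truncated at 6 sigma,
#' renormalized to unit sum), using zero padding. Because the kernel sums to
#' one, the discrete integral of a curve whose support stays one kernel
#' half-width away from both ends is preserved exactly.
#'
#' @param y Sampled values on a uniform grid.
#' @param sigma Kernel sigma in the grid's units.
#' @param step Grid step in the same units.
#' @return Numeric vector of the same length as `y`.
#' @export
gaussian_convolve <- function(y, sigma, step) {
  stopifnot(step > 0, sigma >= 0)
  if (sigma < step / 2) return(y)
  nk <- ceiling(6 * sigma / step)
  kern <- stats::dnorm((-nk:nk) * step, 0, sigma)
  kern <- kern / sum(kern)
  ypad <- c(rep(0, nk), y, rep(0, nk))
  out <- stats::filter(ypad, kern, method = "convolution", sides = 2)
  as.numeric(out[(nk + 1):(nk + length(y))])
}

#' Simulate a laterally integrated depth-dose curve
#'
#' Analytic pristine Bragg curve: the pre-straggling power-law depth dose
#' `D0(z) ~ (R - z)^(1/p - 1)` (the integrable Bragg-Kleeman singularity,
#' sampled as exact per-bin averages) convolved with a Gaussian of sigma
#' [total_range_sigma()], normalized to peak = 1. The curve is extended
#' internally beyond both grid ends before convolution so no edge artifacts
#' enter the returned window.
#'
#' @param spectrum An [energy_spectrum()].
#' @param particle A [particle_spec()].
#' @param grid Optional depth grid \[mm\]; must be uniform and cover
#'   `[0, R + 6 sigma_R]`. Default: 0 to beyond the distal falloff in
#'   `bin_mm` steps.
#' @param bin_mm Grid bin \[mm\] when `grid` is NULL (default 0.1).
#' @return A [depth_dose_curve()].
#' @export
simulate_idc <- function(spectrum, particle = proton_spec(), grid = NULL,
                         bin_mm = 0.1) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  r_mm <- range_from_energy(spectrum$mean_energy, particle)
  sig_r <- total_range_sigma(spectrum, particle)
  if (is.null(grid)) {
    n <- ceiling((r_mm + 6 * sig_r + 1) / bin_mm)
    grid <- seq(0, by = bin_mm, length.out = n + 1)
  } else {
    steps <- diff(grid)
    if (any(steps <= 0) || diff(range(steps)) > 1e-9 * max(steps)) {
      stop("simulate_idc: grid must be uniform and strictly increasing", call. = FALSE)
    }
    bin_mm <- steps[1]
    if (grid[1] > 1e-9 || max(grid) < r_mm + 6 * sig_r - 1e-9) {
      stop(sprintf(
        "simulate_idc: grid too short, must cover [0, %.1f mm] for E = %.2f",
        r_mm + 6 * sig_r, spectrum$mean_energy), call. = FALSE)
    }
  }
  h <- bin_mm
  pad <- if (sig_r >= h / 2) ceiling(6 * sig_r / h) else 0
  # extended grid: pad on both sides so the returned window is edge-free
  z_ext <- seq(grid[1] - pad * h, by = h, length.out = length(grid) + 2 * pad)
  # Pre-straggling depth dose ~ (R - z)^(1/p - 1): an integrable singularity
  # at z = R. Each sample is the exact average of the integrand over its
  # bin (analytic antiderivative), which keeps the sampled curve continuous
  # in E as R sweeps across grid points and conserves the integral.
  expo1 <- 1 / particle$p
  anti <- function(t) pmax(t, 0)^expo1 / expo1
  d0 <- (anti(r_mm - (z_ext - h / 2)) - anti(r_mm - (z_ext + h / 2))) / h
  dose <- gaussian_convolve(d0, sig_r, h)
  dose <- dose[(pad + 1):(pad + length(grid))]
  dose <- pmax(dose, 0)
  depth_dose_curve(grid, dose / max(dose))
}
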