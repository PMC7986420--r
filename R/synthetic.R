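#' Measurement-noise configuration for synthetic commissioning data
#'
#' @param idc_relative_sigma Multiplicative Gaussian noise sigma per IDC
#'   dose bin (default 0.005, i.e. 0.5%).
#' @param fwhm_sigma_mm Additive Gaussian noise sigma on every spot FWHM
#'   \[mm\] (default 0.05).
#' @param rng_seed Integer seed driving all noise draws (default 1).
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(idc_relative_sigma = 0.005, fwhm_sigma_mm = 0.05,
                         rng_seed = 1) {
  if (idc_relative_sigma < 0 || fwhm_sigma_mm < 0) {
    stop("noise_config: noise sigmas must be >= 0", call. = FALSE)
  }
  structure(list(idc_relative_sigma = idc_relative_sigma,
                 fwhm_sigma_mm = fwhm_sigma_mm,
                 rng_seed = as.integer(rng_seed)),
            class = "noise_config")
}

# Truth curves are low-order polynomials in the normalized energy
# u = (E - Emin)/(Emax - Emin), coefficients lowest order first.
eval_truth_poly <- function(coef, u) {
  out <- rep(coef[length(coef)], length(u))
  for (k in rev(seq_len(length(coef) - 1))) out <- out * u + coef[k]
  out
}

# The stated synthetic world: a large-spot synchrotron-style line with the
# source 1.3 m upstream of the isocenter, an all-air path, a converging
# beam in both planes, ~0.8 MeV energy spread and isocenter spot FWHM of
# roughly 9-15 mm falling with energy.
default_truth_curves <- function() {
  list(
    energy_offset = c(0.6, -0.4, 0.3),       # MeV, added to nominal
    sigma_e = c(0.9, -0.25, 0.15),           # MeV
    sigma_x = c(8.5, -3.2, 0.6),             # mm at source
    theta_x = c(5.0, -2.2, 0.4),             # mrad
    frac_x = c(0.55, 0.12, -0.02),           # epsilon / (pi sigma theta)
    sigma_y = c(8.0, -2.8, 0.5),
    theta_y = c(4.6, -1.9, 0.35),
    frac_y = c(0.60, 0.08, 0.0),
    sign_x = -1, sign_y = -1
  )
}

#' Available synthetic machine presets
#'
#' * `"synchrotron-20"`: 20 uniformly spaced proton energies 62-253 MeV,
#'   source 1300 mm upstream, spot planes at -200, -100, 0, +100, +200 mm.
#' * `"synchrotron-5"`: the same beam line with only 5 uniformly spaced
#'   energies (a research-line style reduced dataset).
#' * `"cyclotron-27"`: 27 proton energies 100-226.7 MeV, source 500 mm
#'   upstream (modeling starts at the nozzle exit), spot planes at -150,
#'   -100, 0, +100, +150 mm.
#'
#' @return Character vector of preset names.
#' @export
machine_presets <- function() c("synchrotron-20", "synchrotron-5", "cyclotron-27")

#' Construct a ground-truth synthetic machine
#'
#' Defines the hidden smooth parameter-vs-energy curves, the beam-line
#' geometry and the measurement layout from which synthetic commissioning
#' data are generated. Deterministic: the preset fixes the truth curves and
#' the seed is recorded for downstream noise generation.
#'
#' @param preset One of [machine_presets()], or `"custom"` together with
#'   `custom`.
#' @param seed Integer seed recorded in the truth (used as the default
#'   noise seed).
#' @param particle A [particle_spec()].
#' @param custom Optional list overriding any of: `energies`,
#'   `positions_mm`, `source_z_mm`, `path_end_z_mm`, `curves` (see
#'   the preset definitions in the source).
#' @return An object of class `machine_truth`.
#' @export
make_machine_truth <- function(preset = "synchrotron-20", seed = 1,
                               particle = proton_spec(), custom = NULL) {
  base <- switch(preset,
    "synchrotron-20" = list(energies = seq(62, 253, length.out = 20),
                            positions_mm = c(-200, -100, 0, 100, 200),
                            source_z_mm = -1300, path_end_z_mm = 300),
    "synchrotron-5" = list(energies = seq(62, 253, length.out = 5),
                           positions_mm = c(-200, -100, 0, 100, 200),
                           source_z_mm = -1300, path_end_z_mm = 300),
    "cyclotron-27" = list(energies = seq(100, 226.7, length.out = 27),
                          positions_mm = c(-150, -100, 0, 100, 150),
                          source_z_mm = -500, path_end_z_mm = 250),
    "custom" = list(),
    stop(sprintf("make_machine_truth: unknown preset '%s'", preset), call. = FALSE)
  )
  spec <- utils::modifyList(c(base, list(curves = default_truth_curves())),
                            if (is.null(custom)) list() else custom)
  required <- c("energies", "positions_mm", "source_z_mm", "path_end_z_mm", "curves")
  if (!all(required %in% names(spec))) {
    stop("make_machine_truth: custom machine must define ",
         paste(setdiff(required, names(spec)), collapse = ", "), call. = FALSE)
  }
  geometry <- beamline_geometry(
    spec$source_z_mm,
    list(list(length_mm = spec$path_end_z_mm - spec$source_z_mm, medium = "air")))
  truth <- structure(
    list(preset = preset, particle = particle,
         energies = spec$energies, positions_mm = spec$positions_mm,
         geometry = geometry, curves = spec$curves,
         rng_seed = as.integer(seed)),
    class = "machine_truth")
  pars <- truth_parameters(truth)
  feasible <- pars$sigma_e > 0 & pars$sigma_e < 0.1 * pars$energy_true &
    pars$sigma_x > 0 & pars$theta_x > 0 &
    pars$epsilon_x >= 0 & pars$epsilon_x <= pi * pars$sigma_x * pars$theta_x &
    pars$sigma_y > 0 & pars$theta_y > 0 &
    pars$epsilon_y >= 0 & pars$epsilon_y <= pi * pars$sigma_y * pars$theta_y
  if (!all(feasible)) {
    stop("make_machine_truth: truth curves infeasible at nominal energies ",
         paste(sprintf("%.1f", pars$energy_nominal[!feasible]), collapse = ", "),
         call. = FALSE)
  }
  truth
}

#' Ground-truth beam parameters of a synthetic machine
#'
#' @param truth A `machine_truth`.
#' @param energies Nominal energies at which to evaluate the truth curves
#'   (default: the machine's own energy list).
#' @return A data.frame with the true per-energy parameters.
#' @export
truth_parameters <- function(truth, energies = truth$energies) {
  stopifnot(inherits(truth, "machine_truth"))
  rng <- range(truth$energies)
  u <- (energies - rng[1]) / (rng[2] - rng[1])
  cv <- truth$curves
  sigma_x <- eval_truth_poly(cv$sigma_x, u)
  theta_x <- eval_truth_poly(cv$theta_x, u)
  sigma_y <- eval_truth_poly(cv$sigma_y, u)
  theta_y <- eval_truth_poly(cv$theta_y, u)
  data.frame(
    energy_nominal = energies,
    energy_true = energies + eval_truth_poly(cv$energy_offset, u),
    sigma_e = eval_truth_poly(cv$sigma_e, u),
    sigma_x = sigma_x, theta_x = theta_x,
    epsilon_x = eval_truth_poly(cv$frac_x, u) * pi * sigma_x * theta_x,
    sign_x = cv$sign_x,
    sigma_y = sigma_y, theta_y = theta_y,
    epsilon_y = eval_truth_poly(cv$frac_y, u) * pi * sigma_y * theta_y,
    sign_y = cv$sign_y
  )
}

#' Generate a synthetic commissioning measurement set
#'
#' Runs the forward engines on the ground-truth parameters and adds
#' measurement noise: multiplicative Gaussian noise on every IDC dose bin
#' and additive Gaussian noise on every spot FWHM. With zero noise the
#' measurements equal the forward model exactly, which turns pipeline
#' recovery into an exactness test.
#'
#' @param truth A `machine_truth`.
#' @param noise A [noise_config()]; its `rng_seed` (default: the truth's
#'   seed) fully determines every output value.
#' @param dir Optional directory; when given, the set is also written to
#'   disk via [write_measurement_set()].
#' @return A `measurement_set` (see [measurement_set()]).
#' @export
generate_measurements <- function(truth, noise = NULL, dir = NULL) {
  stopifnot(inherits(truth, "machine_truth"))
  if (is.null(noise)) noise <- noise_config(rng_seed = truth$rng_seed)
  pars <- truth_parameters(truth)
  set.seed(noise$rng_seed)
  idc <- list()
  spots <- list()
  for (j in seq_along(truth$energies)) {
    p <- pars[j, ]
    spectrum <- energy_spectrum(p$energy_true, p$sigma_e)
    curve <- simulate_idc(spectrum, truth$particle)
    dose <- curve$dose
    if (noise$idc_relative_sigma > 0) {
      dose <- pmax(dose * (1 + stats::rnorm(length(dose), 0, noise$idc_relative_sigma)), 0)
    }
    idc[[as.character(truth$energies[j])]] <-
      depth_dose_curve(curve$depth_mm, dose)
    fx <- spot_fwhm_at(optics_plane(p$sigma_x, p$theta_x, p$epsilon_x, p$sign_x),
                       truth$geometry, spectrum, truth$positions_mm, truth$particle)
    fy <- spot_fwhm_at(optics_plane(p$sigma_y, p$theta_y, p$epsilon_y, p$sign_y),
                       truth$geometry, spectrum, truth$positions_mm, truth$particle)
    if (noise$fwhm_sigma_mm > 0) {
      fx <- fx + stats::rnorm(length(fx), 0, noise$fwhm_sigma_mm)
      fy <- fy + stats::rnorm(length(fy), 0, noise$fwhm_sigma_mm)
    }
    spots[[j]] <- data.frame(energy = truth$energies[j],
                             position_mm = truth$positions_mm,
                             fwhm_x_mm = fx, fwhm_y_mm = fy)
  }
  ms <- measurement_set(
    particle = truth$particle,
    energies = truth$energies,
    geometry = truth$geometry,
    idc = idc,
    spots = do.call(rbind, spots),
    meta = list(preset = truth$preset, truth_seed = truth$rng_seed,
                noise = unclass(noise))
  )
  if (!is.null(dir)) write_measurement_set(ms, dir)
  ms
}
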