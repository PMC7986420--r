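# Physical constants (MeV, mm). Masses from CODATA; air radiation length
# 36.62 g/cm^2 / 0.001204 g/cm^3 ~= 304.2 m at NTP.
AMU_MEV <- 931.49410242
PROTON_MASS_MEV <- 938.27208816
AIR_X0_MM <- 304200
FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))

#' Particle species description for the analytic forward engines
#'
#' Bundles the empirical constants the forward engines need: the
#' Bragg-Kleeman range-energy power law `R_cm = alpha * E^p` and the
#' range-straggling power law `sigma_strag_cm = c * R_cm^m`. Energies are
#' kinetic, in MeV for protons and MeV/u for heavier ions.
#'
#' @param name Species label, e.g. `"proton"`.
#' @param mass_number Nucleon number A (>= 1).
#' @param charge Charge number Z (>= 1).
#' @param alpha Bragg-Kleeman coefficient \[cm MeV^-p\].
#' @param p Bragg-Kleeman exponent, must lie in (1, 2.2).
#' @param straggling_c,straggling_m Range-straggling coefficients for
#'   `sigma_strag_cm = straggling_c * R_cm^straggling_m`.
#' @param mass_mev Total rest mass \[MeV\]; defaults to `mass_number` atomic
#'   mass units (the proton constructor overrides this with the proton mass).
#' @return An object of class `particle_spec`.
#' @export
particle_spec <- function(name, mass_number, charge, alpha, p,
                          straggling_c = 0.012, straggling_m = 0.935,
                          mass_mev = mass_number * AMU_MEV) {
  stopifnot(is.character(name), length(name) == 1)
  if (mass_number < 1 || charge < 1) {
    stop("particle_spec: mass_number and charge must be >= 1", call. = FALSE)
  }
  if (alpha <= 0) stop("particle_spec: alpha must be > 0", call. = FALSE)
  if (p <= 1 || p >= 2.2) {
    stop("particle_spec: Bragg-Kleeman exponent p must lie in (1, 2.2)", call. = FALSE)
  }
  if (straggling_c < 0 || mass_mev <= 0) {
    stop("particle_spec: straggling_c must be >= 0 and mass_mev > 0", call. = FALSE)
  }
  structure(
    list(name = name, mass_number = mass_number, charge = charge,
         alpha = alpha, p = p,
         straggling_c = straggling_c, straggling_m = straggling_m,
         mass_mev = mass_mev),
    class = "particle_spec"
  )
}

#' @rdname particle_spec
#' @details `proton_spec()` uses alpha = 0.0022 cm MeV^-p, p = 1.77 and
#'   straggling 0.012 * R_cm^0.935, the usual water parametrization for
#'   clinical proton energies.
#' @export
proton_spec <- function() {
  particle_spec("proton", 1, 1, alpha = 0.0022, p = 1.77,
                straggling_c = 0.012, straggling_m = 0.935,
                mass_mev = PROTON_MASS_MEV)
}

#' @rdname particle_spec
#' @details `carbon_spec()` scales the proton range constant by A/Z^2 at equal
#'   E/u (alpha/3 for 12C) and the straggling constant by 1/sqrt(A); the
#'   fragmentation tail is not modeled.
#' @export
carbon_spec <- function() {
  particle_spec("carbon", 12, 6, alpha = 0.0022 * 12 / 36, p = 1.77,
                straggling_c = 0.012 / sqrt(12), straggling_m = 0.935)
}

# Momentum times velocity [MeV] for a kinetic energy per nucleon; the
# quantity entering the Highland scattering angle.
pv_mev <- function(energy_per_u, particle) {
  if (any(!is.finite(energy_per_u)) || any(energy_per_u <= 0)) {
    stop("pv_mev: kinetic energy must be positive and finite", call. = FALSE)
  }
  ekin <- energy_per_u * particle$mass_number
  w <- particle$mass_mev + ekin
  (w^2 - particle$mass_mev^2) / w
}
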