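#' Configuration of the tuning process
#'
#' Holds the optimizer stop criteria (simplex parameter change below 1e-4 or
#' weighting-function value below 1e-5), the regularization constant lambda
#' (0.1) and the initial simplex step as a fraction of the initial guess.
#'
#' @param lambda Regularization constant coupling consecutive energies in
#'   the optics objective; >= 0, default 0.1.
#' @param stop_param_change Simplex convergence threshold on the maximum
#'   per-coordinate vertex spread; > 0, default 1e-4.
#' @param stop_objective Stop when the best objective value falls below
#'   this; > 0, default 1e-5.
#' @param max_iterations Iteration cap per optimization, default 400.
#' @param init_step_frac Initial simplex step as a fraction of each starting
#'   coordinate (absolute step for zero coordinates), default 0.05.
#' @param spectrum_rounds Alternation rounds of energy / energy-spread
#'   tuning per nominal energy, default 2.
#' @param rng_seed Optional seed recorded with pipeline runs.
#' @return An object of class `tuning_config`.
#' @export
tuning_config <- function(lambda = 0.1, stop_param_change = 1e-4,
                          stop_objective = 1e-5, max_iterations = 400,
                          init_step_frac = 0.05, spectrum_rounds = 2,
                          rng_seed = NULL) {
  if (lambda < 0) stop("tuning_config: lambda must be >= 0", call. = FALSE)
  if (stop_param_change <= 0 || stop_objective <= 0) {
    stop("tuning_config: stop criteria must be > 0", call. = FALSE)
  }
  if (max_iterations < 1 || init_step_frac <= 0 || spectrum_rounds < 1) {
    stop("tuning_config: invalid iteration/step settings", call. = FALSE)
  }
  structure(list(lambda = lambda, stop_param_change = stop_param_change,
                 stop_objective = stop_objective,
                 max_iterations = max_iterations,
                 init_step_frac = init_step_frac,
                 spectrum_rounds = spectrum_rounds, rng_seed = rng_seed),
            class = "tuning_config")
}

#' Nelder-Mead simplex minimization
#'
#' Derivative-free downhill-simplex minimizer with the standard reflection,
#' expansion, contraction and shrink coefficients (1, 2, 0.5, 0.5) and
#' stable (index-order) tie-breaking, so results are fully deterministic
#' given the starting point and configuration. Terminates when the maximum
#' per-coordinate spread of the simplex falls below
#' `config$stop_param_change`, when the best objective value falls below
#' `config$stop_objective`, or at `config$max_iterations`.
#'
#' @param fn Objective function of a numeric vector; must be finite at
#'   `x0`.
#' @param x0 Numeric starting point.
#' @param config A [tuning_config()].
#' @param step Optional vector of initial simplex steps; default
#'   `config$init_step_frac` times `abs(x0)` (absolute for zero
#'   coordinates).
#' @param trace_fn Optional callback `function(iteration, par, value)`
#'   invoked once per iteration with the current best vertex.
#' @return A list with `par`, `value`, `iterations`, `evaluations` and
#'   `converged` (TRUE unless stopped by the iteration cap).
#' @export
nelder_mead <- function(fn, x0, config = tuning_config(), step = NULL,
                        trace_fn = NULL) {
  n <- length(x0)
  stopifnot(n >= 1)
  f0 <- fn(x0)
  if (!is.finite(f0)) stop("nelder_mead: objective is not finite at x0", call. = FALSE)
  if (is.null(step)) {
    step <- ifelse(abs(x0) > 0, config$init_step_frac * abs(x0), config$init_step_frac)
  }
  verts <- matrix(rep(x0, each = n + 1), nrow = n + 1)
  for (i in seq_len(n)) verts[i + 1, i] <- verts[i + 1, i] + step[i]
  fv <- c(f0, vapply(seq_len(n), function(i) fn(verts[i + 1, ]), numeric(1)))
  nev <- n + 1
  iter <- 0
  repeat {
    ord <- order(fv)  # stable: ties broken by vertex index
    verts <- verts[ord, , drop = FALSE]
    fv <- fv[ord]
    if (!is.null(trace_fn)) trace_fn(iter, verts[1, ], fv[1])
    spread <- max(apply(verts, 2, function(col) max(col) - min(col)))
    if (fv[1] < config$stop_objective || spread < config$stop_param_change ||
        iter >= config$max_iterations) {
      break
    }
    iter <- iter + 1
    centroid <- colMeans(verts[seq_len(n), , drop = FALSE])
    worst <- verts[n + 1, ]
    xr <- centroid + (centroid - worst)
    fr <- fn(xr); nev <- nev + 1
    if (fr < fv[1]) {
      xe <- centroid + 2 * (centroid - worst)
      fe <- fn(xe); nev <- nev + 1
      if (fe < fr) { verts[n + 1, ] <- xe; fv[n + 1] <- fe }
      else { verts[n + 1, ] <- xr; fv[n + 1] <- fr }
    } else if (fr < fv[n]) {
      verts[n + 1, ] <- xr; fv[n + 1] <- fr
    } else if (fr < fv[n + 1]) {
      xc <- centroid + 0.5 * (xr - centroid)  # outside contraction
      fc <- fn(xc); nev <- nev + 1
      if (fc <= fr) { verts[n + 1, ] <- xc; fv[n + 1] <- fc }
      else {
        for (i in 2:(n + 1)) {  # shrink toward best
          verts[i, ] <- verts[1, ] + 0.5 * (verts[i, ] - verts[1, ])
          fv[i] <- fn(verts[i, ]); nev <- nev + 1
        }
      }
    } else {
      xc <- centroid - 0.5 * (centroid - worst)  # inside contraction
      fc <- fn(xc); nev <- nev + 1
      if (fc < fv[n + 1]) { verts[n + 1, ] <- xc; fv[n + 1] <- fc }
      else {
        for (i in 2:(n + 1)) {
          verts[i, ] <- verts[1, ] + 0.5 * (verts[i, ] - verts[1, ])
          fv[i] <- fn(verts[i, ]); nev <- nev + 1
        }
      }
    }
  }
  list(par = as.numeric(verts[1, ]), value = fv[1], iterations = iter,
       evaluations = nev, converged = iter < config$max_iterations)
}

#' Least-squares weighting functions of the tuning stages
#'
#' `energy_objective()` is the squared R80 mismatch of a candidate mean
#' energy; `spread_objective()` the squared BPW80 mismatch of a candidate
#' energy spread; `optics_objective()` the sum of squared FWHM mismatches
#' over all measurement positions for a candidate (sigma, theta, epsilon).
#'
#' @param e_candidate Candidate mean energy \[MeV\].
#' @param measured_r80 Measured R80 \[mm\].
#' @param forward For `energy_objective`: function mapping energy to
#'   simulated R80 \[mm\]. For `spread_objective`: function mapping sigma_E
#'   to simulated BPW80. For `optics_objective`: function mapping the
#'   candidate `c(sigma, theta, epsilon)` to simulated FWHM values at the
#'   record positions \[mm\].
#' @return Objective value \[mm^2\].
#' @export
energy_objective <- function(e_candidate, measured_r80, forward) {
  (measured_r80 - forward(e_candidate))^2
}

#' @rdname energy_objective
#' @param sigma_e_candidate Candidate energy spread \[MeV\].
#' @param measured_bpw80 Measured BPW80 \[mm\].
#' @export
spread_objective <- function(sigma_e_candidate, measured_bpw80, forward) {
  (measured_bpw80 - forward(sigma_e_candidate))^2
}

#' @rdname energy_objective
#' @param candidate Numeric `c(sigma, theta, epsilon)`.
#' @param spot_records Data frame with columns `position_mm` and `fwhm_mm`
#'   (>= 2 rows).
#' @export
optics_objective <- function(candidate, spot_records, forward) {
  if (nrow(spot_records) < 2) {
    stop("optics_objective: needs at least 2 spot positions", call. = FALSE)
  }
  sim <- forward(candidate)
  sum((spot_records$fwhm_mm - sim)^2)
}

# Coerce an optics_plane or numeric triple to c(sigma, theta, epsilon).
optics_triple <- function(x) {
  if (inherits(x, "optics_plane")) c(x$sigma, x$theta, x$epsilon) else as.numeric(x[1:3])
}

#' Regularization term coupling consecutive energies
#'
#' Sum of squared differences of the three optics parameters between the
#' current candidate and the final parameters of the preceding energy. The
#' three terms carry different units (mm, mrad, mm mrad) and are summed
#' unnormalized, as the method prescribes; lambda is tuned for that
#' convention.
#'
#' @param current,previous [optics_plane()] objects or numeric
#'   `c(sigma, theta, epsilon)` triples.
#' @param scale Per-parameter divisors applied to the differences before
#'   squaring. The default `c(1, 1, 1)` gives the plain mixed-units sum;
#'   the tuning sequence passes the preceding energy's parameter
#'   magnitudes, turning the penalty into squared relative changes (see
#'   [tune_optics()]).
#' @return The penalty value (symmetric in its arguments).
#' @export
#' @examples
#' regularization_term(c(3.1, 2.2, 9), c(3, 2, 10))  # 1.05
regularization_term <- function(current, previous, scale = c(1, 1, 1)) {
  sum(((optics_triple(current) - optics_triple(previous)) / scale)^2)
}

#' @rdname energy_objective
#' @param previous Tuned optics of the preceding (lower) energy, or NULL at
#'   the lowest energy, where no regularization is applied.
#' @param lambda Regularization constant.
#' @param scale Passed on to [regularization_term()].
#' @export
regularized_optics_objective <- function(candidate, spot_records, previous,
                                         lambda, forward, scale = c(1, 1, 1)) {
  val <- optics_objective(candidate, spot_records, forward)
  if (!is.null(previous) && lambda > 0) {
    val <- val + lambda * regularization_term(candidate, previous, scale)
  }
  val
}

# Nelder-Mead with deterministic restarts: when the simplex collapses
# (parameter-change stop) before the objective stop is reached, re-start
# around the best point with a smaller initial step. Polishes through the
# micro-scale kinks the discrete depth grid leaves in the objectives.
nelder_mead_polished <- function(fn, x0, config, trace_fn = NULL,
                                 step_fracs = c(1, 0.2, 0.04)) {
  best <- NULL
  iters <- 0L
  evals <- 0L
  for (frac in step_fracs) {
    start <- if (is.null(best)) x0 else best$par
    step <- ifelse(abs(start) > 0, frac * config$init_step_frac * abs(start),
                   frac * config$init_step_frac)
    res <- nelder_mead(fn, start, config, step = step, trace_fn = trace_fn)
    iters <- iters + res$iterations
    evals <- evals + res$evaluations
    if (is.null(best) || res$value < best$value) best <- res
    if (best$value < config$stop_objective) break
  }
  best$iterations <- iters
  best$evaluations <- evals
  best
}

# Forward closure: candidate energy -> simulated R80 at fixed sigma_E.
make_r80_forward <- function(sigma_e, particle) {
  function(e) r80(simulate_idc(energy_spectrum(e, sigma_e), particle))
}

# Penalized wrapper keeping Nelder-Mead candidates physical.
safe_energy_objective <- function(e, measured_r80, sigma_e, particle) {
  if (!is.finite(e) || e <= 1) return(1e6 + (1 - e)^2)
  energy_objective(e, measured_r80, make_r80_forward(min(sigma_e, 0.099 * e), particle))
}

#' Tune the mean beam energy of one nominal energy
#'
#' Minimizes the squared R80 mismatch between the measured IDC and the
#' simulated IDC as a function of the candidate mean energy, at fixed
#' energy spread. The starting point is the Bragg-Kleeman inversion of the
#' measured R80.
#'
#' @param idc Measured depth-dose curve (see [r80()]).
#' @param config A [tuning_config()].
#' @param sigma_e Energy spread \[MeV\] held fixed during the search;
#'   default 0.5% of the initial energy guess.
#' @param particle A [particle_spec()].
#' @param trace_fn Optional optimizer trace callback (see
#'   [nelder_mead()]).
#' @return A list with `energy`, `sigma_e` (as used), `objective`,
#'   `iterations`, `measured_r80`, `achieved_r80`.
#' @export
tune_energy <- function(idc, config = tuning_config(), sigma_e = NULL,
                        particle = proton_spec(), trace_fn = NULL) {
  measured <- r80(idc)
  e0 <- energy_from_range(measured, particle)
  if (is.null(sigma_e)) sigma_e <- 0.005 * e0
  res <- nelder_mead_polished(function(x) {
    safe_energy_objective(x[1], measured, sigma_e, particle)
  }, e0, config, trace_fn = trace_fn)
  e_star <- res$par[1]
  list(energy = e_star, sigma_e = sigma_e, objective = res$value,
       iterations = res$iterations, measured_r80 = measured,
       achieved_r80 = make_r80_forward(sigma_e, particle)(e_star))
}

#' Tune the energy spread of one nominal energy
#'
#' Minimizes the squared BPW80 mismatch as a function of the candidate
#' energy spread, at the already-tuned mean energy. A spread of zero is a
#' valid boundary (straggling-only peak).
#'
#' @param idc Measured depth-dose curve.
#' @param energy Tuned mean energy \[MeV\], held fixed.
#' @param config A [tuning_config()].
#' @param sigma_e0 Starting guess \[MeV\]; default 0.5% of `energy`.
#' @inheritParams tune_energy
#' @return A list with `sigma_e`, `objective`, `iterations`,
#'   `measured_bpw80`, `achieved_bpw80`.
#' @export
tune_spread <- function(idc, energy, config = tuning_config(), sigma_e0 = NULL,
                        particle = proton_spec(), trace_fn = NULL) {
  measured <- bragg_peak_width(idc, 0.8)
  if (is.null(sigma_e0)) sigma_e0 <- 0.005 * energy
  forward <- function(s) bragg_peak_width(simulate_idc(energy_spectrum(energy, s), particle), 0.8)
  obj <- function(x) {
    s <- x[1]
    if (!is.finite(s) || s < 0) return(1e6 + s^2)
    if (s >= 0.099 * energy) return(1e6 + (s - 0.099 * energy)^2)
    spread_objective(s, measured, forward)
  }
  res <- nelder_mead_polished(obj, sigma_e0, config, trace_fn = trace_fn)
  s_star <- max(res$par[1], 0)
  list(sigma_e = s_star, objective = res$value, iterations = res$iterations,
       measured_bpw80 = measured, achieved_bpw80 = forward(s_star))
}

#' Tune mean energy and energy spread of one nominal energy
#'
#' Sequential spectrum tuning: the mean energy is tuned first (range is the
#' energy's direct observable), then the energy spread from the peak width.
#' Because the distal 80% point of the convolved peak shifts weakly with
#' the spread, the two one-dimensional tunings are alternated for
#' `config$spectrum_rounds` rounds so the final pair matches both R80 and
#' BPW80.
#'
#' @inheritParams tune_energy
#' @return A list with `energy`, `sigma_e`, objectives, iteration counts
#'   and the achieved R80/BPW80.
#' @export
tune_spectrum <- function(idc, config = tuning_config(),
                          particle = proton_spec(), trace_fn = NULL) {
  sig <- NULL
  iters_e <- 0L; iters_s <- 0L
  for (round in seq_len(config$spectrum_rounds)) {
    te <- tune_energy(idc, config, sigma_e = sig, particle = particle,
                      trace_fn = trace_fn)
    ts <- tune_spread(idc, te$energy, config,
                      sigma_e0 = if (is.null(sig)) NULL else sig,
                      particle = particle, trace_fn = trace_fn)
    sig <- ts$sigma_e
    iters_e <- iters_e + te$iterations
    iters_s <- iters_s + ts$iterations
  }
  list(energy = te$energy, sigma_e = sig,
       energy_objective = te$objective, spread_objective = ts$objective,
       energy_iterations = iters_e, spread_iterations = iters_s,
       measured_r80 = te$measured_r80, achieved_r80 = te$achieved_r80,
       measured_bpw80 = ts$measured_bpw80, achieved_bpw80 = ts$achieved_bpw80)
}

# Data-driven starting optics. The measured squared beam sizes, after
# subtracting the (optics-independent) scattering contribution, follow the
# free-drift quadratic var(z) = var_x + 2 a cov + a^2 var_xp with
# a = (z - z_source)/1000; a least-squares fit of that quadratic yields
# source-plane moments and in particular the correlation sign, which a
# naive FWHM slope misreads when scattering growth masks a converging
# beam. Degenerate fits fall back to clamped values; the emittance
# fraction is kept away from the waist boundary.
initial_optics_guess <- function(spot_records, geometry, spectrum, particle) {
  z <- spot_records$position_mm
  var_meas <- (spot_records$fwhm_mm / FWHM_PER_SIGMA)^2
  var_scatter <- vapply(z, function(zz) {
    propagate_moments(second_moments(0, 0, 0), geometry, spectrum, zz,
                      particle)$var_x
  }, numeric(1))
  a <- (z - geometry$source_z_mm) * 1e-3
  x <- cbind(1, 2 * a, a^2)
  cf <- tryCatch(qr.solve(x, var_meas - var_scatter),
                 error = function(e) c(NA, NA, NA))
  var_x <- cf[1]; cov <- cf[2]; var_xp <- cf[3]
  if (!all(is.finite(cf)) || var_x <= 0.01 || var_xp <= 0.01) {
    s_iso <- sqrt(max(var_meas[which.min(abs(z))], 0.09))
    var_x <- max(var_x, s_iso^2, 0.09)
    var_xp <- max(var_xp, 1)
    cov <- if (is.finite(cov)) cov else 0
  }
  f2 <- 1 - cov^2 / (var_x * var_xp)  # (epsilon / (pi sigma theta))^2
  f2 <- min(max(f2, 0.04), 0.96)
  sigma0 <- sqrt(var_x)
  theta0 <- sqrt(var_xp)
  list(x0 = c(sigma0, theta0, sqrt(f2) * pi * sigma0 * theta0),
       sign = if (cov >= 0) 1 else -1)
}

# Optics objective with feasibility penalty: infeasible candidates get the
# data term of the clamped candidate plus a large penalty that grows with
# the violation, keeping the simplex finite and pointed back inward.
penalized_optics_objective <- function(cand, spot_records, previous, lambda,
                                       reg_scale, sign, geometry, spectrum,
                                       particle) {
  sigma <- cand[1]; theta <- cand[2]; eps <- cand[3]
  viol <- 0
  if (!all(is.finite(cand))) return(1e12)
  if (sigma <= 0) { viol <- viol + (0.05 - sigma)^2; sigma <- 0.05 }
  if (theta <= 0) { viol <- viol + (0.05 - theta)^2; theta <- 0.05 }
  if (eps < 0) { viol <- viol + eps^2; eps <- 0 }
  emax <- pi * sigma * theta
  if (eps > emax) { viol <- viol + (eps - emax)^2; eps <- emax }
  plane <- optics_plane(sigma, theta, eps, sign)
  forward <- function(p) {
    spot_fwhm_at(optics_plane(p[1], p[2], p[3], sign), geometry, spectrum,
                 spot_records$position_mm, particle)
  }
  val <- regularized_optics_objective(c(sigma, theta, eps), spot_records,
                                      previous, lambda, forward, reg_scale)
  if (viol > 0) val <- val + 1e6 * (1 + viol)
  val
}

#' Tune the beam optics of one plane at one nominal energy
#'
#' Minimizes the sum of squared FWHM mismatches over all spot positions as
#' a function of (sigma, theta, epsilon), optionally with the
#' regularization term toward the preceding energy's result. The
#' correlation sign is fixed from the measured FWHM-vs-position slope and
#' not optimized.
#'
#' @param spot_records Data frame with `position_mm` and `fwhm_mm` for one
#'   plane and energy (>= 2 rows).
#' @param geometry A [beamline_geometry()].
#' @param spectrum The tuned [energy_spectrum()] of this nominal energy.
#' @param config A [tuning_config()].
#' @param previous Tuned [optics_plane()] of the preceding energy, or NULL
#'   at the lowest energy (no regularization there).
#' @param particle A [particle_spec()].
#' @param trace_fn Optional optimizer trace callback.
#' @return A list with `plane` (an [optics_plane()]), `objective` (the
#'   unregularized data term at the optimum), `regularized_objective`,
#'   `iterations`.
#' @export
tune_optics <- function(spot_records, geometry, spectrum,
                        config = tuning_config(), previous = NULL,
                        particle = proton_spec(), trace_fn = NULL) {
  if (nrow(spot_records) < 2) {
    stop("tune_optics: needs at least 2 spot positions", call. = FALSE)
  }
  guess <- initial_optics_guess(spot_records, geometry, spectrum, particle)
  prev_triple <- if (is.null(previous)) NULL else optics_triple(previous)
  # Regularize relative parameter changes: the printed mixed-units sum is
  # scaled by the preceding energy's parameter magnitudes, so lambda acts
  # on dimensionless fractional changes and does not drag the physical
  # energy dependence of the emittance (see the methods vignette).
  reg_scale <- if (is.null(prev_triple)) c(1, 1, 1) else pmax(abs(prev_triple), 1e-3)
  obj <- function(x) {
    penalized_optics_objective(x, spot_records, prev_triple, config$lambda,
                               reg_scale, guess$sign, geometry, spectrum,
                               particle)
  }
  res <- nelder_mead_polished(obj, guess$x0, config, trace_fn = trace_fn)
  p <- res$par
  emax <- pi * max(p[1], 0.05) * max(p[2], 0.05)
  plane <- optics_plane(max(p[1], 0.05), max(p[2], 0.05),
                        min(max(p[3], 0), emax), guess$sign)
  forward <- function(pp) {
    spot_fwhm_at(optics_plane(pp[1], pp[2], pp[3], guess$sign), geometry,
                 spectrum, spot_records$position_mm, particle)
  }
  data_term <- optics_objective(optics_triple(plane), spot_records, forward)
  list(plane = plane, objective = data_term, regularized_objective = res$value,
       iterations = res$iterations)
}

#' Tune the optics of one plane across all energies
#'
#' Iterates the nominal energies lowest-first. The lowest energy is tuned
#' without regularization; every following energy minimizes the regularized
#' objective using the final parameters of the preceding energy in the
#' penalty, which suppresses run-to-run parameter oscillation along the
#' energy axis.
#'
#' @param measurements A `measurement_set` (see [measurement_set()]).
#' @param plane_id `"x"` or `"y"`.
#' @param spectra List of tuned [energy_spectrum()] objects, one per
#'   nominal energy (ascending).
#' @param config A [tuning_config()].
#' @param particle A [particle_spec()].
#' @param trace_fn Optional optimizer trace callback.
#' @return A list of per-energy results as returned by [tune_optics()]. If
#'   an energy fails, an error of class `beamtune_tuning_error` is raised
#'   carrying the completed results in its `partial` field.
#' @export
tune_optics_sequence <- function(measurements, plane_id, spectra,
                                 config = tuning_config(),
                                 particle = proton_spec(), trace_fn = NULL) {
  stopifnot(plane_id %in% c("x", "y"))
  energies <- measurements$energies
  stopifnot(length(spectra) == length(energies))
  fcol <- paste0("fwhm_", plane_id, "_mm")
  results <- vector("list", length(energies))
  previous <- NULL
  for (j in seq_along(energies)) {
    spots <- measurements$spots[measurements$spots$energy == energies[j], ]
    records <- data.frame(position_mm = spots$position_mm, fwhm_mm = spots[[fcol]])
    res <- tryCatch(
      tune_optics(records, measurements$geometry, spectra[[j]], config,
                  previous = if (j > 1) previous else NULL,
                  particle = particle, trace_fn = trace_fn),
      error = function(e) {
        cond <- structure(
          class = c("beamtune_tuning_error", "error", "condition"),
          list(message = sprintf("optics tuning failed at E = %.2f (plane %s): %s",
                                 energies[j], plane_id, conditionMessage(e)),
               call = sys.call(-1), partial = results[seq_len(j - 1)]))
        stop(cond)
      })
    results[[j]] <- res
    previous <- res$plane
  }
  results
}

#' Tune all beam-model parameters of a commissioning dataset
#'
#' Full per-energy tuning: the beam spectrum (mean energy, energy spread)
#' from the IDCs, then the optics of both transverse planes from the spot
#' sizes, sequenced lowest energy first with regularization.
#'
#' @param measurements A `measurement_set`.
#' @param config A [tuning_config()].
#' @param particle A [particle_spec()].
#' @param trace_fn Optional optimizer trace callback.
#' @return An object of class `tuning_result`: a data.frame with one row
#'   per nominal energy (tuned energy, spread, per-plane sigma/theta/
#'   epsilon/sign, objectives, iteration counts), with the particle and
#'   geometry attached as attributes.
#' @export
tune_machine <- function(measurements, config = tuning_config(),
                         particle = proton_spec(), trace_fn = NULL) {
  energies <- measurements$energies
  spec_fits <- lapply(energies, function(e) {
    tune_spectrum(measurements$idc[[as.character(e)]], config, particle, trace_fn)
  })
  spectra <- lapply(spec_fits, function(s) energy_spectrum(s$energy, s$sigma_e))
  ox <- tune_optics_sequence(measurements, "x", spectra, config, particle, trace_fn)
  oy <- tune_optics_sequence(measurements, "y", spectra, config, particle, trace_fn)
  row <- function(j) {
    s <- spec_fits[[j]]; px <- ox[[j]]$plane; py <- oy[[j]]$plane
    data.frame(
      energy_nominal = energies[j], energy = s$energy, sigma_e = s$sigma_e,
      sigma_x = px$sigma, theta_x = px$theta, epsilon_x = px$epsilon,
      sign_x = px$sign,
      sigma_y = py$sigma, theta_y = py$theta, epsilon_y = py$epsilon,
      sign_y = py$sign,
      energy_objective = s$energy_objective,
      spread_objective = s$spread_objective,
      optics_objective_x = ox[[j]]$objective,
      optics_objective_y = oy[[j]]$objective,
      energy_iterations = s$energy_iterations,
      spread_iterations = s$spread_iterations,
      optics_iterations_x = ox[[j]]$iterations,
      optics_iterations_y = oy[[j]]$iterations
    )
  }
  out <- do.call(rbind, lapply(seq_along(energies), row))
  structure(out, class = c("tuning_result", "data.frame"),
            particle = particle, geometry = measurements$geometry,
            lambda = config$lambda)
}
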