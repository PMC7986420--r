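#' Fit an energy-parametrized polynomial to one beam parameter
#'
#' Least-squares polynomial fit of a tuned parameter versus nominal energy.
#' Fourth- to sixth-order polynomials are candidates; the chosen degree is
#' the lowest one whose RMS residual is within 5% of the best candidate's,
#' which guards against over-fitting while still allowing the higher orders
#' when the parameter's energy dependence needs them. Fitting is done in
#' the scaled variable `u = (E - center) / scale` for conditioning; the
#' scaling is part of the returned object.
#'
#' @param energies Nominal energies \[MeV\]; at least `min(degrees) + 1`
#'   distinct values.
#' @param values Tuned parameter values, same length.
#' @param degrees Candidate polynomial degrees (default 4:6); candidates
#'   needing more points than available are dropped.
#' @return An object of class `parameter_polynomial` with fields
#'   `coefficients` (lowest order first, in `u`), `degree`, `center`,
#'   `scale`, `rms`, `residuals`.
#' @export
fit_parameter_polynomial <- function(energies, values, degrees = 4:6) {
  stopifnot(length(energies) == length(values))
  usable <- degrees[degrees + 1 <= length(energies)]
  if (length(usable) == 0) {
    stop(sprintf(
      "fit_parameter_polynomial: %d points given but at least %d needed for degree %d",
      length(energies), min(degrees) + 1, min(degrees)), call. = FALSE)
  }
  center <- mean(range(energies))
  scale <- max((max(energies) - min(energies)) / 2, 1)
  u <- (energies - center) / scale
  fits <- lapply(usable, function(d) {
    x <- outer(u, 0:d, `^`)
    cf <- qr.solve(x, values)
    res <- values - as.numeric(x %*% cf)
    # dof-adjusted residual standard error: raw RMS always rewards higher
    # degrees, defeating the anti-overfit comparison
    list(degree = d, coefficients = as.numeric(cf),
         rms = sqrt(sum(res^2) / max(length(res) - d - 1, 1)),
         residuals = res)
  })
  rms <- vapply(fits, `[[`, numeric(1), "rms")
  floor_rms <- 1e-9 * max(abs(values), 1e-12)  # exact fits compare equal
  rms_eff <- pmax(rms, floor_rms)
  pick <- which(rms_eff <= 1.05 * min(rms_eff))[1]
  out <- fits[[pick]]
  out$center <- center
  out$scale <- scale
  structure(out, class = "parameter_polynomial")
}

#' Evaluate a parameter polynomial at nominal energies
#'
#' @param object A `parameter_polynomial`.
#' @param energies Nominal energies \[MeV\].
#' @param ... Unused.
#' @return Numeric vector of parameter values.
#' @export
predict.parameter_polynomial <- function(object, energies, ...) {
  u <- (energies - object$center) / object$scale
  cf <- object$coefficients
  out <- rep(cf[length(cf)], length(u))
  for (k in rev(seq_len(length(cf) - 1))) out <- out * u + cf[k]  # Horner
  out
}

BEAM_MODEL_PARAMETERS <- c("mean_energy", "sigma_e",
                           "sigma_x", "theta_x", "epsilon_x",
                           "sigma_y", "theta_y", "epsilon_y")

#' Compile tuned per-energy parameters into a polynomial beam model
#'
#' Fits all eight parameter curves (mean energy, energy spread and per-plane
#' sigma, theta, epsilon) as polynomials over nominal energy and validates
#' that the resulting model stays physically feasible (positive widths and
#' divergences, `epsilon <= pi sigma theta`) at 50 evenly spaced probe
#' energies across the modeled range.
#'
#' @param tuning_result A `tuning_result` from [tune_machine()], or any
#'   data.frame with the same per-energy columns (>= 5 energies).
#' @param particle A [particle_spec()]; defaults to the one attached to the
#'   tuning result.
#' @param dose_scaling Dose-scaling calibration factor (default 1).
#' @param provenance Optional list recorded verbatim with the model (e.g.
#'   config and seeds); keep it free of timestamps if byte-stable re-runs
#'   are wanted.
#' @param degrees Candidate polynomial degrees, default 4:6.
#' @return An object of class `beam_model`.
#' @export
build_beam_model <- function(tuning_result, particle = NULL,
                             dose_scaling = 1, provenance = NULL,
                             degrees = 4:6) {
  tr <- as.data.frame(tuning_result)
  if (is.null(particle)) particle <- attr(tuning_result, "particle")
  if (is.null(particle)) particle <- proton_spec()
  if (nrow(tr) < 5) {
    stop(sprintf("build_beam_model: needs >= 5 tuned energies, got %d", nrow(tr)),
         call. = FALSE)
  }
  need <- c("energy_nominal", "energy", BEAM_MODEL_PARAMETERS[-1], "sign_x", "sign_y")
  missing_cols <- setdiff(need, names(tr))
  if (length(missing_cols) > 0) {
    stop("build_beam_model: tuning result lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  en <- tr$energy_nominal
  value_col <- function(p) if (p == "mean_energy") tr$energy else tr[[p]]
  polys <- lapply(BEAM_MODEL_PARAMETERS, function(p) {
    fit_parameter_polynomial(en, value_col(p), degrees)
  })
  names(polys) <- BEAM_MODEL_PARAMETERS
  model <- structure(
    list(schema_version = 1L,
         particle = unclass(particle),
         energy_range = c(min(en), max(en)),
         sign_x = tr$sign_x[which.min(abs(en - stats::median(en)))],
         sign_y = tr$sign_y[which.min(abs(en - stats::median(en)))],
         parameters = polys,
         dose_scaling_factor = dose_scaling,
         provenance = provenance),
    class = "beam_model")
  probe <- seq(model$energy_range[1], model$energy_range[2], length.out = 50)
  pars <- beam_model_parameters(model, probe)
  bad <- probe[pars$sigma_e < 0 | pars$sigma_e >= 0.1 * pars$mean_energy |
               pars$mean_energy <= 0 |
               pars$sigma_x <= 0 | pars$theta_x <= 0 | pars$epsilon_x < 0 |
               pars$epsilon_x > pi * pars$sigma_x * pars$theta_x |
               pars$sigma_y <= 0 | pars$theta_y <= 0 | pars$epsilon_y < 0 |
               pars$epsilon_y > pi * pars$sigma_y * pars$theta_y]
  if (length(bad) > 0) {
    stop("build_beam_model: model infeasible at probe energies: ",
         paste(sprintf("%.1f", bad), collapse = ", "), call. = FALSE)
  }
  model
}

#' Evaluate all beam-model parameter polynomials
#'
#' @param model A `beam_model`.
#' @param energies Nominal energies \[MeV\] inside the model range.
#' @return A data.frame with one row per energy and the eight parameter
#'   columns plus `energy_nominal`.
#' @export
beam_model_parameters <- function(model, energies) {
  stopifnot(inherits(model, "beam_model"))
  out <- data.frame(energy_nominal = energies)
  for (p in BEAM_MODEL_PARAMETERS) {
    out[[p]] <- predict(model$parameters[[p]], energies)
  }
  out
}

# Per-plane optics_plane objects from model parameters at one energy.
model_planes_at <- function(model, energy) {
  pars <- beam_model_parameters(model, energy)
  list(
    x = optics_plane(pars$sigma_x, pars$theta_x,
                     min(pars$epsilon_x, pi * pars$sigma_x * pars$theta_x),
                     model$sign_x),
    y = optics_plane(pars$sigma_y, pars$theta_y,
                     min(pars$epsilon_y, pi * pars$sigma_y * pars$theta_y),
                     model$sign_y),
    spectrum = energy_spectrum(pars$mean_energy, max(pars$sigma_e, 0))
  )
}

#' Dose-scaling calibration factor
#'
#' Matches the absolute dose of simulations to measurements in the
#' spread-out-Bragg-peak region: the factor to multiply simulated doses by.
#' The default estimator is the mean of the pointwise measured/simulated
#' ratios (which zeroes the mean relative difference by construction); the
#' ratio of the means is available as an alternative.
#'
#' @param measured,simulated Equal-length vectors of paired doses, all > 0.
#' @param method `"mean_ratio"` (default) or `"ratio_of_means"`.
#' @return The scalar dose-scaling factor.
#' @export
dose_scaling_factor <- function(measured, simulated,
                                method = c("mean_ratio", "ratio_of_means")) {
  method <- match.arg(method)
  if (length(measured) != length(simulated) || length(measured) == 0) {
    stop("dose_scaling_factor: paired dose lists of equal positive length required",
         call. = FALSE)
  }
  if (any(!is.finite(measured)) || any(!is.finite(simulated)) ||
      any(measured <= 0) || any(simulated <= 0)) {
    stop("dose_scaling_factor: doses must be positive", call. = FALSE)
  }
  if (method == "mean_ratio") mean(measured / simulated) else mean(measured) / mean(simulated)
}

#' Evaluate a beam model against a commissioning measurement set
#'
#' Re-simulates the measured observables from the model at evaluation
#' energies (by default 5 equally spaced over the modeled range, snapped to
#' the nearest measured energies): IDCs through the depth-dose engine for
#' R80/BPW50/BPW80, and lateral profiles in air at every spot-measurement
#' plane for FWHM. Differences are reported as simulation minus
#' measurement, absolute and relative, aggregated per metric.
#'
#' @param model A `beam_model`.
#' @param measurements A `measurement_set`.
#' @param n_eval Number of evaluation energies, default 5.
#' @param estimator FWHM estimator passed to [fwhm()] for the simulated
#'   profiles (`"crossings"` or `"gaussfit"`).
#' @param profile_bin_mm Lateral profile sampling bin \[mm\], default 0.5.
#' @param particle A [particle_spec()]; defaults to the model's.
#' @return An object of class `evaluation_report`: list with `summary`
#'   (per-metric avg/min/max of absolute and relative signed differences,
#'   RMS, and mean absolute values) and `details` (every individual
#'   comparison). Extraction failures are recorded in `failures` rather
#'   than aborting.
#' @export
evaluate_model <- function(model, measurements, n_eval = 5,
                           estimator = c("crossings", "gaussfit"),
                           profile_bin_mm = 0.5, particle = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(model, "beam_model"))
  if (is.null(particle)) particle <- do.call(particle_spec, model$particle)
  energies <- measurements$energies
  targets <- seq(model$energy_range[1], model$energy_range[2],
                 length.out = n_eval)
  eval_energies <- unique(vapply(targets, function(t) {
    energies[which.min(abs(energies - t))]
  }, numeric(1)))
  if (any(eval_energies < model$energy_range[1] - 1e-9) ||
      any(eval_energies > model$energy_range[2] + 1e-9)) {
    stop("evaluate_model: measurement energies outside model range", call. = FALSE)
  }
  details <- list()
  failures <- list()
  for (e in eval_energies) {
    mp <- model_planes_at(model, e)
    res <- tryCatch({
      sim_idc <- simulate_idc(mp$spectrum, particle)
      sim <- idc_metrics(sim_idc)
      meas <- idc_metrics(measurements$idc[[as.character(e)]])
      rbind(
        data.frame(energy = e, metric = "R80", position_mm = NA,
                   sim = sim$r80, meas = meas$r80),
        data.frame(energy = e, metric = "BPW50", position_mm = NA,
                   sim = sim$bpw50, meas = meas$bpw50),
        data.frame(energy = e, metric = "BPW80", position_mm = NA,
                   sim = sim$bpw80, meas = meas$bpw80))
    }, error = function(err) {
      failures[[length(failures) + 1]] <<- sprintf("IDC at E = %.2f: %s", e,
                                                   conditionMessage(err))
      NULL
    })
    if (!is.null(res)) details[[length(details) + 1]] <- res
    spots <- measurements$spots[measurements$spots$energy == e, ]
    for (plane_id in c("x", "y")) {
      plane <- mp[[plane_id]]
      sig <- spot_sigma_at(plane, measurements$geometry, mp$spectrum,
                           spots$position_mm, particle)
      sim_fwhm <- vapply(sig, function(s) {
        fwhm(sample_lateral_profile(s, bin_mm = profile_bin_mm), estimator)
      }, numeric(1))
      details[[length(details) + 1]] <- data.frame(
        energy = e, metric = "FWHM", position_mm = spots$position_mm,
        plane = plane_id, sim = sim_fwhm,
        meas = spots[[paste0("fwhm_", plane_id, "_mm")]])
    }
  }
  details <- do.call(rbind, lapply(details, function(d) {
    if (!"plane" %in% names(d)) d$plane <- NA
    d
  }))
  details$diff <- details$sim - details$meas
  details$rel_pct <- 100 * details$diff / details$meas
  summary <- do.call(rbind, lapply(split(details, details$metric), function(d) {
    data.frame(
      metric = d$metric[1], n = nrow(d),
      avg_abs_mm = mean(d$diff), min_abs_mm = min(d$diff),
      max_abs_mm = max(d$diff),
      avg_rel_pct = mean(d$rel_pct), min_rel_pct = min(d$rel_pct),
      max_rel_pct = max(d$rel_pct),
      rms_mm = sqrt(mean(d$diff^2)),
      mean_absolute_mm = mean(abs(d$diff)),
      mean_absolute_rel_pct = mean(abs(d$rel_pct)))
  }))
  rownames(summary) <- NULL
  structure(list(summary = summary, details = details,
                 eval_energies = eval_energies,
                 failures = unlist(failures)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Beam-model evaluation at energies:",
      paste(sprintf("%.1f", x$eval_energies), collapse = ", "), "MeV\n")
  cat("(differences are simulation - measurement)\n\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("%-6s abs. diff avg %6.3f mm (%6.3f; %6.3f)  rel. diff avg %6.2f%% (%6.2f; %6.2f)  RMS %.3f\n",
                s$metric[i], s$avg_abs_mm[i], s$min_abs_mm[i], s$max_abs_mm[i],
                s$avg_rel_pct[i], s$min_rel_pct[i], s$max_rel_pct[i], s$rms_mm[i]))
  }
  if (length(x$failures) > 0) {
    cat("\nExtraction failures:\n")
    for (f in x$failures) cat(" -", f, "\n")
  }
  invisible(x)
}

#' Serialize / load a beam model as JSON
#'
#' The JSON schema stores explicit units, the coefficient order (lowest
#' first), the energy scaling of each polynomial and a `schema_version`
#' field. Numbers are written at full precision, so save/load round-trips
#' reproduce identical parameter evaluations; models written with identical
#' provenance are byte-identical.
#'
#' @param model A `beam_model`.
#' @param path File path to write to / read from.
#' @return `write_beam_model()` returns `path` invisibly;
#'   `read_beam_model()` returns the `beam_model`.
#' @export
write_beam_model <- function(model, path) {
  stopifnot(inherits(model, "beam_model"))
  payload <- list(
    schema_version = model$schema_version,
    units = list(energy = "MeV", sigma = "mm", theta = "mrad",
                 epsilon = "mm.mrad"),
    coefficient_order = "lowest_first",
    particle = model$particle,
    energy_range = model$energy_range,
    sign_x = model$sign_x, sign_y = model$sign_y,
    parameters = lapply(model$parameters, function(p) {
      list(degree = p$degree, center = p$center, scale = p$scale,
           coefficients = p$coefficients, rms = p$rms)
    }),
    dose_scaling_factor = model$dose_scaling_factor,
    provenance = model$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_beam_model
#' @export
read_beam_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$schema_version) || payload$schema_version != 1) {
    stop("read_beam_model: unsupported schema_version", call. = FALSE)
  }
  polys <- lapply(payload$parameters, function(p) {
    structure(list(degree = p$degree, coefficients = as.numeric(p$coefficients),
                   rms = p$rms, residuals = NULL,
                   center = p$center, scale = p$scale),
              class = "parameter_polynomial")
  })
  structure(
    list(schema_version = 1L,
         particle = payload$particle,
         energy_range = as.numeric(payload$energy_range),
         sign_x = payload$sign_x, sign_y = payload$sign_y,
         parameters = polys[BEAM_MODEL_PARAMETERS],
         dose_scaling_factor = payload$dose_scaling_factor,
         provenance = payload$provenance),
    class = "beam_model")
}
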