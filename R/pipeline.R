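# Artifact names of each pipeline stage inside a run directory.
STAGE_FILES <- list(
  synth = "measurements",
  `tune-energy` = "energy_tuning.csv",
  `tune-spread` = "spectrum_tuning.csv",
  `tune-optics` = "optics_tuning.csv",
  `build-model` = "beam_model.json",
  evaluate = "evaluation_report.csv",
  calibrate = "calibration.json"
)

stage_artifact <- function(run_dir, stage) file.path(run_dir, STAGE_FILES[[stage]])

require_stage <- function(run_dir, stage, needed_by) {
  if (!file.exists(stage_artifact(run_dir, stage))) {
    stop(sprintf(
      "stage '%s' requires the artifacts of stage '%s'; beam energy is modeled first - run '%s' before '%s'",
      needed_by, stage, stage, needed_by), call. = FALSE)
  }
}

write_record <- function(run_dir, record) {
  jsonlite::write_json(record, file.path(run_dir, "record.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
}

read_record <- function(run_dir) {
  p <- file.path(run_dir, "record.json")
  if (!file.exists(p)) list() else jsonlite::read_json(p, simplifyVector = TRUE)
}

mark_failed <- function(run_dir, stage, err) {
  writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(err)),
             file.path(run_dir, "FAILED"))
}

run_stage <- function(run_dir, stage, fun) {
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  failed <- file.path(run_dir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  tryCatch(fun(), error = function(e) {
    mark_failed(run_dir, stage, e)
    stop(e)
  })
}

open_tuning_log <- function(run_dir, label) {
  path <- file.path(run_dir, "tuning_log.txt")
  function(iter, par, value) {
    cat(sprintf("%s iter %d par %s f %.8g\n", label(), iter,
                paste(sprintf("%.6g", par), collapse = " "), value),
        file = path, append = TRUE)
  }
}

#' Pipeline stages of a tuning run
#'
#' Each stage reads its inputs from and writes its artifacts into a run
#' directory, refusing to run before its prerequisites (the beam energy is
#' modeled first, then the energy spread, then the optics). A failing stage
#' leaves partial artifacts in place together with a `FAILED` marker file.
#' [run_pipeline()] chains synth, tuning, model building and evaluation and
#' writes a reproducibility record (`record.json` with config, seeds and
#' package version), so re-running with identical config and seeds gives
#' byte-identical models.
#'
#' @param run_dir Run directory holding all stage artifacts.
#' @param preset Synthetic machine preset, see [machine_presets()].
#' @param seed Integer seed for the synthetic noise draws.
#' @param noise A [noise_config()]; default uses `seed`.
#' @param config A [tuning_config()].
#' @param log Logical: append per-evaluation optimizer traces to
#'   `tuning_log.txt` (default FALSE).
#' @return Invisibly, the main artifact of the stage (see individual
#'   stages).
#' @export
stage_synth <- function(run_dir, preset = "synchrotron-20", seed = 1,
                        noise = NULL) {
  run_stage(run_dir, "synth", function() {
    truth <- make_machine_truth(preset, seed)
    if (is.null(noise)) noise <- noise_config(rng_seed = seed)
    ms <- generate_measurements(truth, noise, dir = stage_artifact(run_dir, "synth"))
    record <- read_record(run_dir)
    record$synth <- list(preset = preset, seed = seed, noise = unclass(noise))
    record$package_version <- as.character(utils::packageVersion("beamtune"))
    write_record(run_dir, record)
    invisible(ms)
  })
}

#' @rdname stage_synth
#' @export
stage_tune_energy <- function(run_dir, config = tuning_config(), log = FALSE) {
  run_stage(run_dir, "tune-energy", function() {
    require_stage(run_dir, "synth", "tune-energy")
    ms <- read_measurement_set(stage_artifact(run_dir, "synth"))
    lbl <- "tune-energy"
    trace <- if (log) open_tuning_log(run_dir, function() lbl) else NULL
    rows <- lapply(ms$energies, function(e) {
      fit <- tune_energy(ms$idc[[as.character(e)]], config, particle = ms$particle,
                         trace_fn = trace)
      data.frame(energy_nominal = e, energy = fit$energy, sigma_e = fit$sigma_e,
                 objective = fit$objective, iterations = fit$iterations)
    })
    out <- do.call(rbind, rows)
    utils::write.csv(out, stage_artifact(run_dir, "tune-energy"), row.names = FALSE)
    invisible(out)
  })
}

#' @rdname stage_synth
#' @export
stage_tune_spread <- function(run_dir, config = tuning_config(), log = FALSE) {
  run_stage(run_dir, "tune-spread", function() {
    require_stage(run_dir, "tune-energy", "tune-spread")
    ms <- read_measurement_set(stage_artifact(run_dir, "synth"))
    lbl <- "tune-spread"
    trace <- if (log) open_tuning_log(run_dir, function() lbl) else NULL
    rows <- lapply(ms$energies, function(e) {
      fit <- tune_spectrum(ms$idc[[as.character(e)]], config,
                           particle = ms$particle, trace_fn = trace)
      data.frame(energy_nominal = e, energy = fit$energy, sigma_e = fit$sigma_e,
                 energy_objective = fit$energy_objective,
                 spread_objective = fit$spread_objective,
                 energy_iterations = fit$energy_iterations,
                 spread_iterations = fit$spread_iterations)
    })
    out <- do.call(rbind, rows)
    utils::write.csv(out, stage_artifact(run_dir, "tune-spread"), row.names = FALSE)
    invisible(out)
  })
}

#' @rdname stage_synth
#' @export
stage_tune_optics <- function(run_dir, config = tuning_config(), log = FALSE) {
  run_stage(run_dir, "tune-optics", function() {
    require_stage(run_dir, "tune-spread", "tune-optics")
    ms <- read_measurement_set(stage_artifact(run_dir, "synth"))
    spec_df <- utils::read.csv(stage_artifact(run_dir, "tune-spread"))
    spectra <- lapply(seq_len(nrow(spec_df)), function(j) {
      energy_spectrum(spec_df$energy[j], max(spec_df$sigma_e[j], 0))
    })
    lbl <- "tune-optics"
    trace <- if (log) open_tuning_log(run_dir, function() lbl) else NULL
    ox <- tune_optics_sequence(ms, "x", spectra, config, ms$particle, trace)
    oy <- tune_optics_sequence(ms, "y", spectra, config, ms$particle, trace)
    out <- do.call(rbind, lapply(seq_along(ms$energies), function(j) {
      px <- ox[[j]]$plane; py <- oy[[j]]$plane
      data.frame(energy_nominal = ms$energies[j],
                 energy = spec_df$energy[j], sigma_e = spec_df$sigma_e[j],
                 sigma_x = px$sigma, theta_x = px$theta,
                 epsilon_x = px$epsilon, sign_x = px$sign,
                 sigma_y = py$sigma, theta_y = py$theta,
                 epsilon_y = py$epsilon, sign_y = py$sign,
                 optics_objective_x = ox[[j]]$objective,
                 optics_objective_y = oy[[j]]$objective,
                 optics_iterations_x = ox[[j]]$iterations,
                 optics_iterations_y = oy[[j]]$iterations)
    }))
    utils::write.csv(out, stage_artifact(run_dir, "tune-optics"), row.names = FALSE)
    invisible(out)
  })
}

#' @rdname stage_synth
#' @export
stage_build_model <- function(run_dir, config = tuning_config()) {
  run_stage(run_dir, "build-model", function() {
    require_stage(run_dir, "tune-optics", "build-model")
    ms <- read_measurement_set(stage_artifact(run_dir, "synth"))
    tuned <- utils::read.csv(stage_artifact(run_dir, "tune-optics"))
    record <- read_record(run_dir)
    model <- build_beam_model(
      tuned, particle = ms$particle,
      provenance = list(synth = record$synth,
                        lambda = config$lambda,
                        stop_param_change = config$stop_param_change,
                        stop_objective = config$stop_objective))
    write_beam_model(model, stage_artifact(run_dir, "build-model"))
    invisible(model)
  })
}

#' @rdname stage_synth
#' @param n_eval Number of evaluation energies (default 5).
#' @export
stage_evaluate <- function(run_dir, n_eval = 5) {
  run_stage(run_dir, "evaluate", function() {
    require_stage(run_dir, "build-model", "evaluate")
    ms <- read_measurement_set(stage_artifact(run_dir, "synth"))
    model <- read_beam_model(stage_artifact(run_dir, "build-model"))
    report <- evaluate_model(model, ms, n_eval = n_eval)
    utils::write.csv(report$summary, stage_artifact(run_dir, "evaluate"),
                     row.names = FALSE)
    utils::write.csv(report$details,
                     file.path(run_dir, "evaluation_details.csv"),
                     row.names = FALSE)
    txt <- utils::capture.output(print(report))
    writeLines(txt, file.path(run_dir, "evaluation_report.txt"))
    invisible(report)
  })
}

#' @rdname stage_synth
#' @param doses_csv CSV with columns `measured` and `simulated` of paired
#'   absolute doses in the spread-out-Bragg-peak region.
#' @export
stage_calibrate <- function(run_dir, doses_csv) {
  run_stage(run_dir, "calibrate", function() {
    require_stage(run_dir, "build-model", "calibrate")
    doses <- utils::read.csv(doses_csv)
    if (!all(c("measured", "simulated") %in% names(doses))) {
      stop("stage_calibrate: dose CSV needs 'measured' and 'simulated' columns",
           call. = FALSE)
    }
    factor <- dose_scaling_factor(doses$measured, doses$simulated)
    model <- read_beam_model(stage_artifact(run_dir, "build-model"))
    model$dose_scaling_factor <- factor
    write_beam_model(model, stage_artifact(run_dir, "build-model"))
    jsonlite::write_json(list(dose_scaling_factor = factor,
                              n_points = nrow(doses)),
                         stage_artifact(run_dir, "calibrate"),
                         auto_unbox = TRUE, digits = I(17), pretty = TRUE)
    invisible(factor)
  })
}

#' @rdname stage_synth
#' @param doses_csv Optional paired-dose CSV for the calibration stage;
#'   when NULL the dose-scaling factor stays 1.
#' @export
run_pipeline <- function(run_dir, preset = "synchrotron-20", seed = 1,
                         noise = NULL, config = tuning_config(), n_eval = 5,
                         doses_csv = NULL, log = FALSE) {
  stage_synth(run_dir, preset, seed, noise)
  stage_tune_energy(run_dir, config, log)
  stage_tune_spread(run_dir, config, log)
  stage_tune_optics(run_dir, config, log)
  stage_build_model(run_dir, config)
  if (!is.null(doses_csv)) stage_calibrate(run_dir, doses_csv)
  report <- stage_evaluate(run_dir, n_eval)
  record <- read_record(run_dir)
  record$config <- unclass(config)
  record$n_eval <- n_eval
  write_record(run_dir, record)
  invisible(report)
}
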