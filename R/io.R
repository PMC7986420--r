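#' Commissioning measurement set
#'
#' The container the tuning pipeline consumes: per nominal energy one
#' laterally integrated depth-dose curve in water and a set of spot FWHM
#' records in air (both planes) at signed isocenter distances, plus the
#' beam-line geometry.
#'
#' @param particle A [particle_spec()].
#' @param energies Strictly increasing nominal energies \[MeV\].
#' @param geometry A [beamline_geometry()].
#' @param idc Named list of [depth_dose_curve()]s, names = energies.
#' @param spots Data frame with columns `energy`, `position_mm`,
#'   `fwhm_x_mm`, `fwhm_y_mm`; >= 2 positions per energy, the same
#'   positions at every energy.
#' @param meta Optional free-form metadata list.
#' @return An object of class `measurement_set`.
#' @export
measurement_set <- function(particle, energies, geometry, idc, spots,
                            meta = list()) {
  if (any(diff(energies) <= 0)) {
    dup <- unique(energies[duplicated(energies)])
    if (length(dup) > 0) {
      stop("measurement_set: duplicate energies: ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
    stop("measurement_set: energies must be strictly increasing", call. = FALSE)
  }
  missing_idc <- setdiff(as.character(energies), names(idc))
  if (length(missing_idc) > 0) {
    stop("measurement_set: missing IDC for energies ",
         paste(missing_idc, collapse = ", "), call. = FALSE)
  }
  need <- c("energy", "position_mm", "fwhm_x_mm", "fwhm_y_mm")
  if (!all(need %in% names(spots))) {
    stop("measurement_set: spot table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  counts <- table(spots$energy)
  if (!all(as.character(energies) %in% names(counts)) || any(counts < 2)) {
    stop("measurement_set: every energy needs >= 2 spot positions", call. = FALSE)
  }
  if (length(unique(counts)) != 1) {
    stop("measurement_set: spot position count must be consistent across energies",
         call. = FALSE)
  }
  structure(list(particle = particle, energies = energies, geometry = geometry,
                 idc = idc, spots = spots, meta = meta),
            class = "measurement_set")
}

#' Read and write depth-dose curve CSV files
#'
#' Two-column CSV (`depth_mm`, `dose`) with one header line; writer and
#' reader round-trip exactly. Depth grids are validated on read, with
#' malformed rows reported by line number.
#'
#' @param curve A [depth_dose_curve()].
#' @param path CSV file path.
#' @return `read_idc()` returns a [depth_dose_curve()]; `write_idc()`
#'   returns `path` invisibly.
#' @export
write_idc <- function(curve, path) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  utils::write.csv(as.data.frame(curve)[c("depth_mm", "dose")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_idc
#' @export
read_idc <- function(path) {
  if (!file.exists(path)) stop("read_idc: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("depth_mm", "dose") %in% names(df))) {
    stop("read_idc: header must name depth_mm and dose columns: ", path,
         call. = FALSE)
  }
  bad <- which(!is.finite(df$depth_mm) | !is.finite(df$dose) | df$dose < 0)
  if (length(bad) > 0) {
    stop(sprintf("read_idc: malformed row at line %d of %s", bad[1] + 1, path),
         call. = FALSE)
  }
  nonmono <- which(diff(df$depth_mm) <= 0)
  if (length(nonmono) > 0) {
    stop(sprintf("read_idc: depth grid not increasing at line %d of %s",
                 nonmono[1] + 2, path), call. = FALSE)
  }
  depth_dose_curve(df$depth_mm, df$dose)
}

#' Read and write spot-size tables
#'
#' CSV with columns `energy_MeV`, `position_mm`, `fwhm_x_mm`, `fwhm_y_mm`:
#' one row per measurement plane and energy.
#'
#' @param spots Data frame with columns `energy`, `position_mm`,
#'   `fwhm_x_mm`, `fwhm_y_mm`.
#' @param path CSV file path.
#' @return `read_spot_table()` returns the data frame (column `energy`);
#'   `write_spot_table()` returns `path` invisibly.
#' @export
write_spot_table <- function(spots, path) {
  out <- data.frame(energy_MeV = spots$energy, position_mm = spots$position_mm,
                    fwhm_x_mm = spots$fwhm_x_mm, fwhm_y_mm = spots$fwhm_y_mm)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) stop("read_spot_table: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("energy_MeV", "position_mm", "fwhm_x_mm", "fwhm_y_mm")
  if (!all(need %in% names(df))) {
    stop("read_spot_table: header must name ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df[need]) | df$fwhm_x_mm <= 0 | df$fwhm_y_mm <= 0)
  if (length(bad) > 0) {
    stop(sprintf("read_spot_table: malformed row at line %d of %s",
                 bad[1] + 1, path), call. = FALSE)
  }
  data.frame(energy = df$energy_MeV, position_mm = df$position_mm,
             fwhm_x_mm = df$fwhm_x_mm, fwhm_y_mm = df$fwhm_y_mm)
}

geometry_to_list <- function(geometry) {
  list(source_z_mm = geometry$source_z_mm,
       phantom_surface_z_mm = geometry$phantom_surface_z_mm,
       segments = lapply(geometry$segments, function(s) {
         out <- list(length_mm = s$length_mm, medium = s$medium)
         if (is.finite(s$radiation_length_mm) &&
             !(s$medium == "air" && s$radiation_length_mm == AIR_X0_MM)) {
           out$radiation_length_mm <- s$radiation_length_mm
         }
         out
       }))
}

geometry_from_list <- function(lst) {
  beamline_geometry(lst$source_z_mm, lst$segments,
                    phantom_surface_z_mm = lst$phantom_surface_z_mm)
}

#' Write a measurement set to a directory
#'
#' Layout: one `idc_<energy>.csv` per energy, `spots.csv`, `geometry.json`
#' and a `manifest.json` listing every artifact with the particle and
#' generation seeds, so the whole set parses back losslessly with
#' [read_measurement_set()].
#'
#' @param ms A [measurement_set()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_measurement_set <- function(ms, dir) {
  stopifnot(inherits(ms, "measurement_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idc_files <- character(0)
  for (e in ms$energies) {
    f <- sprintf("idc_%08.3f.csv", e)
    write_idc(ms$idc[[as.character(e)]], file.path(dir, f))
    idc_files <- c(idc_files, f)
  }
  write_spot_table(ms$spots, file.path(dir, "spots.csv"))
  jsonlite::write_json(geometry_to_list(ms$geometry),
                       file.path(dir, "geometry.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  manifest <- list(format_version = 1L,
                   particle = unclass(ms$particle),
                   energies = ms$energies,
                   idc_files = idc_files,
                   spot_file = "spots.csv",
                   geometry_file = "geometry.json",
                   meta = ms$meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(dir)
}

#' Read a measurement set from a directory
#'
#' @param dir Directory previously written by [write_measurement_set()].
#' @return A [measurement_set()].
#' @export
read_measurement_set <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    stop("read_measurement_set: no manifest.json in ", dir, call. = FALSE)
  }
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  energies <- as.numeric(manifest$energies)
  dup <- unique(energies[duplicated(energies)])
  if (length(dup) > 0) {
    stop("read_measurement_set: duplicate energies in manifest: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (length(manifest$idc_files) != length(energies)) {
    stop("read_measurement_set: manifest lists ", length(manifest$idc_files),
         " IDC files for ", length(energies), " energies", call. = FALSE)
  }
  idc <- list()
  for (j in seq_along(energies)) {
    f <- file.path(dir, manifest$idc_files[j])
    if (!file.exists(f)) {
      stop(sprintf("read_measurement_set: missing IDC for energy %.3f (%s)",
                   energies[j], manifest$idc_files[j]), call. = FALSE)
    }
    idc[[as.character(energies[j])]] <- read_idc(f)
  }
  spots <- read_spot_table(file.path(dir, manifest$spot_file))
  geometry <- geometry_from_list(
    jsonlite::read_json(file.path(dir, manifest$geometry_file),
                        simplifyVector = FALSE))
  particle <- do.call(particle_spec, manifest$particle)
  ord <- order(energies)
  measurement_set(particle, energies[ord], geometry,
                  idc[as.character(energies[ord])],
                  spots[order(spots$energy, spots$position_mm), ],
                  meta = manifest$meta)
}
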