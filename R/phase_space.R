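#' Transverse beam optics of one plane
#'
#' One transverse phase-space plane of a Gaussian pencil beam, described by
#' beam width sigma \[mm\], divergence theta \[mrad\], emittance epsilon
#' \[mm mrad\] and the sign of the position-angle correlation (+1 diverging,
#' -1 converging). The ellipse is feasible only if
#' `epsilon <= pi * sigma * theta`, with equality exactly at the beam waist.
#'
#' @param sigma Beam width sigma at the source plane \[mm\], > 0.
#' @param theta Beam divergence \[mrad\], > 0.
#' @param epsilon Beam emittance \[mm mrad\], >= 0.
#' @param sign Correlation sign, +1 (diverging) or -1 (converging).
#' @return An object of class `optics_plane`.
#' @export
optics_plane <- function(sigma, theta, epsilon, sign = 1) {
  vals <- c(sigma = sigma, theta = theta, epsilon = epsilon, sign = sign)
  if (any(!is.finite(vals))) stop("optics_plane: non-finite input", call. = FALSE)
  if (sigma <= 0 || theta <= 0 || epsilon < 0) {
    stop("optics_plane: requires sigma > 0, theta > 0, epsilon >= 0", call. = FALSE)
  }
  if (!sign %in% c(-1, 1)) stop("optics_plane: sign must be +1 or -1", call. = FALSE)
  if (epsilon > pi * sigma * theta * (1 + 1e-12)) {
    stop(sprintf(
      "optics_plane: infeasible ellipse, epsilon = %.6g exceeds pi*sigma*theta = %.6g",
      epsilon, pi * sigma * theta), call. = FALSE)
  }
  structure(list(sigma = sigma, theta = theta, epsilon = epsilon, sign = sign),
            class = "optics_plane")
}

#' Second moments of the transverse phase-space distribution
#'
#' Internal representation used for transport: position variance \[mm^2\],
#' position-angle covariance \[mm mrad\] and angular variance \[mrad^2\].
#' The determinant `var_x * var_xp - cov_xxp^2` equals `(epsilon/pi)^2` and
#' is invariant under free drift.
#'
#' @param var_x Position variance \[mm^2\], >= 0.
#' @param cov_xxp Position-angle covariance \[mm mrad\].
#' @param var_xp Angular variance \[mrad^2\], >= 0.
#' @return An object of class `second_moments`.
#' @export
second_moments <- function(var_x, cov_xxp, var_xp) {
  vals <- c(var_x, cov_xxp, var_xp)
  if (any(!is.finite(vals))) stop("second_moments: non-finite input", call. = FALSE)
  if (var_x < 0 || var_xp < 0) {
    stop("second_moments: variances must be >= 0", call. = FALSE)
  }
  det <- var_x * var_xp - cov_xxp^2
  if (det < -1e-9 * max(1, var_x * var_xp)) {
    stop("second_moments: covariance matrix not positive semi-definite", call. = FALSE)
  }
  structure(list(var_x = var_x, cov_xxp = cov_xxp, var_xp = var_xp),
            class = "second_moments")
}

#' Emittance of an upright (waist) phase-space ellipse
#'
#' At the beam waist the ellipse is upright and the emittance reduces to
#' `epsilon = pi * sigma * theta`.
#'
#' @param sigma Beam width \[mm\], >= 0.
#' @param theta Beam divergence \[mrad\], >= 0.
#' @return Emittance \[mm mrad\].
#' @export
#' @examples
#' emittance_at_waist(1, 1)   # pi
#' emittance_at_waist(2, 3)   # 6 * pi
emittance_at_waist <- function(sigma, theta) {
  if (any(!is.finite(c(sigma, theta))) || sigma < 0 || theta < 0) {
    stop("emittance_at_waist: sigma and theta must be non-negative", call. = FALSE)
  }
  pi * sigma * theta
}

#' Convert an optics plane to second moments
#'
#' The covariance magnitude follows from the emittance,
#' `cov = sign * sqrt(sigma^2 theta^2 - (epsilon/pi)^2)`: a waist-emittance
#' beam (`epsilon = pi sigma theta`) has zero correlation, while
#' `epsilon = 0` is the fully correlated limit.
#'
#' @param plane An [optics_plane()].
#' @return A [second_moments()] object.
#' @export
moments_from_optics <- function(plane) {
  stopifnot(inherits(plane, "optics_plane"))
  arg <- plane$sigma^2 * plane$theta^2 - (plane$epsilon / pi)^2
  cov <- plane$sign * sqrt(max(arg, 0))
  second_moments(plane$sigma^2, cov, plane$theta^2)
}

#' Convert second moments back to an optics plane
#'
#' @param moments A [second_moments()] object with strictly positive
#'   variances.
#' @return An [optics_plane()]; `sign` is +1 when the covariance is >= 0.
#' @export
optics_from_moments <- function(moments) {
  stopifnot(inherits(moments, "second_moments"))
  det <- max(moments$var_x * moments$var_xp - moments$cov_xxp^2, 0)
  optics_plane(sqrt(moments$var_x), sqrt(moments$var_xp), pi * sqrt(det),
               sign = if (moments$cov_xxp >= 0) 1 else -1)
}

#' Free drift of second moments
#'
#' Transports the moments through `dz` mm of non-scattering material
#' (vacuum). Angles are in mrad, so the transfer matrix carries a factor
#' 1e-3; the determinant (emittance) is preserved.
#'
#' @param moments A [second_moments()] object.
#' @param dz Signed drift length \[mm\]; negative values drift upstream.
#' @return The drifted [second_moments()].
#' @export
drift_moments <- function(moments, dz) {
  stopifnot(inherits(moments, "second_moments"), is.finite(dz))
  a <- dz * 1e-3  # mrad -> mm per mm of drift
  second_moments(
    var_x = moments$var_x + 2 * a * moments$cov_xxp + a^2 * moments$var_xp,
    cov_xxp = moments$cov_xxp + a * moments$var_xp,
    var_xp = moments$var_xp
  )
}

#' Highland scattering power of a material segment
#'
#' Mean squared scattering angle per unit path length \[rad^2/mm\] from the
#' Highland parametrization with logarithmic thickness correction,
#' `theta_0 = (14.1 MeV Z / pv) sqrt(L/X0) (1 + log10(L/X0)/9)`, treated as
#' uniform over the segment (`T = theta_0^2 / L`). The log factor is
#' evaluated on the full segment length, since it is not additive in
#' sub-steps.
#'
#' @param energy Kinetic energy \[MeV or MeV/u\], > 0.
#' @param particle A [particle_spec()].
#' @param segment_length_mm Segment length \[mm\], > 0.
#' @param x0_mm Radiation length of the medium \[mm\].
#' @return Scattering power \[rad^2/mm\].
#' @export
highland_scattering_power <- function(energy, particle, segment_length_mm,
                                      x0_mm = AIR_X0_MM) {
  if (!is.finite(energy) || energy <= 0) {
    stop("highland_scattering_power: energy must be positive", call. = FALSE)
  }
  if (segment_length_mm <= 0 || x0_mm <= 0) {
    stop("highland_scattering_power: lengths must be positive", call. = FALSE)
  }
  if (!is.finite(x0_mm)) return(0)
  t_rel <- segment_length_mm / x0_mm
  corr <- max(1 + log10(t_rel) / 9, 0)
  theta0 <- 14.1 * particle$charge / pv_mev(energy, particle) * sqrt(t_rel) * corr
  theta0^2 / segment_length_mm
}

#' Fermi-Eyges moment increments from air scattering in one segment
#'
#' Integrates the (uniform) Highland scattering power over a segment and
#' returns the second-moment contributions accumulated at the segment exit:
#' `A2 = T L^3/3` \[mm^2\], `A1 = T L^2/2` \[mm mrad\], `A0 = T L`
#' \[mrad^2\]. A vacuum segment contributes nothing.
#'
#' @param spectrum An [energy_spectrum()]; only the mean energy enters.
#' @param segment A list with `length_mm`, `medium` ("air" or "vacuum") and
#'   optionally `radiation_length_mm`.
#' @param particle A [particle_spec()].
#' @return A [second_moments()] object holding the increments.
#' @export
air_scattering_increments <- function(spectrum, segment, particle = proton_spec()) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  len <- segment$length_mm
  if (is.null(len) || !is.finite(len) || len < 0) {
    stop("air_scattering_increments: segment needs a non-negative length_mm", call. = FALSE)
  }
  if (len == 0 || identical(segment$medium, "vacuum")) {
    return(second_moments(0, 0, 0))
  }
  if (!identical(segment$medium, "air")) {
    stop(sprintf("air_scattering_increments: unknown medium '%s'", segment$medium),
         call. = FALSE)
  }
  x0 <- segment$radiation_length_mm
  if (is.null(x0)) x0 <- AIR_X0_MM
  tt <- highland_scattering_power(spectrum$mean_energy, particle, len, x0)
  second_moments(tt * len^3 / 3, tt * len^2 / 2 * 1e3, tt * len * 1e6)
}

#' Beam line geometry for lateral transport
#'
#' Signed axial coordinates with the isocenter at z = 0 and the beam
#' travelling toward +z. Segments are contiguous starting at the source
#' plane; each is vacuum or air.
#'
#' @param source_z_mm Axial position of the source plane \[mm\], upstream of
#'   (i.e. smaller than) every measurement plane; typically negative.
#' @param segments A list of lists with `length_mm` and `medium`
#'   ("vacuum"/"air"), ordered from the source downstream; optional
#'   `radiation_length_mm` per segment.
#' @param phantom_surface_z_mm Where water starts for depth-dose simulation
#'   \[mm\] (default isocenter).
#' @return An object of class `beamline_geometry`.
#' @export
beamline_geometry <- function(source_z_mm, segments,
                              phantom_surface_z_mm = 0) {
  if (!is.finite(source_z_mm)) stop("beamline_geometry: source_z_mm must be finite", call. = FALSE)
  if (length(segments) == 0) stop("beamline_geometry: needs at least one segment", call. = FALSE)
  segments <- lapply(segments, function(s) {
    if (is.null(s$length_mm) || !is.finite(s$length_mm) || s$length_mm <= 0) {
      stop("beamline_geometry: every segment needs length_mm > 0", call. = FALSE)
    }
    if (!s$medium %in% c("vacuum", "air")) {
      stop(sprintf("beamline_geometry: unknown medium '%s'", s$medium), call. = FALSE)
    }
    if (is.null(s$radiation_length_mm)) {
      s$radiation_length_mm <- if (s$medium == "air") AIR_X0_MM else Inf
    }
    s[c("length_mm", "medium", "radiation_length_mm")]
  })
  ends <- source_z_mm + cumsum(vapply(segments, `[[`, numeric(1), "length_mm"))
  structure(
    list(source_z_mm = source_z_mm, segments = segments,
         segment_end_z_mm = ends, path_end_z_mm = ends[length(ends)],
         phantom_surface_z_mm = phantom_surface_z_mm),
    class = "beamline_geometry"
  )
}

#' Propagate source-plane moments to an axial position
#'
#' Walks the geometry segments from the source plane to `z_mm`, applying a
#' free drift everywhere and adding Fermi-Eyges scattering increments over
#' the traversed portion of each air segment.
#'
#' @param source An [optics_plane()] or [second_moments()] at the source
#'   plane.
#' @param geometry A [beamline_geometry()].
#' @param spectrum An [energy_spectrum()] (mean energy sets the scattering
#'   power).
#' @param z_mm Target axial position \[mm\], within the modeled path.
#' @param particle A [particle_spec()].
#' @return The [second_moments()] at `z_mm`.
#' @export
propagate_moments <- function(source, geometry, spectrum, z_mm,
                              particle = proton_spec()) {
  stopifnot(inherits(geometry, "beamline_geometry"))
  m <- if (inherits(source, "optics_plane")) moments_from_optics(source) else source
  stopifnot(inherits(m, "second_moments"))
  if (z_mm < geometry$source_z_mm) {
    stop(sprintf("propagate_moments: z = %.1f mm is upstream of the source plane (%.1f mm)",
                 z_mm, geometry$source_z_mm), call. = FALSE)
  }
  if (z_mm > geometry$path_end_z_mm + 1e-9) {
    stop(sprintf("propagate_moments: z = %.1f mm is beyond the modeled path end (%.1f mm)",
                 z_mm, geometry$path_end_z_mm), call. = FALSE)
  }
  pos <- geometry$source_z_mm
  for (i in seq_along(geometry$segments)) {
    seg <- geometry$segments[[i]]
    seg_end <- geometry$segment_end_z_mm[i]
    l <- min(seg_end, z_mm) - pos
    if (l > 0) {
      m <- drift_moments(m, l)
      if (seg$medium == "air") {
        tt <- highland_scattering_power(spectrum$mean_energy, particle,
                                        seg$length_mm, seg$radiation_length_mm)
        m <- second_moments(m$var_x + tt * l^3 / 3,
                            m$cov_xxp + tt * l^2 / 2 * 1e3,
                            m$var_xp + tt * l * 1e6)
      }
      pos <- pos + l
    }
    if (z_mm <= seg_end) break
  }
  m
}

#' Beam width sigma at arbitrary axial positions
#'
#' Forward model for spot-size measurements in air: the Gaussian beam width
#' at each requested plane, including multiple-Coulomb-scattering growth. In
#' an all-vacuum path this reduces to the closed-form drift of the
#' phase-space ellipse.
#'
#' @param plane An [optics_plane()] at the source plane.
#' @param geometry A [beamline_geometry()].
#' @param spectrum An [energy_spectrum()].
#' @param z_positions_mm Axial positions \[mm\] within the modeled path.
#' @param particle A [particle_spec()].
#' @return Numeric vector of sigma \[mm\], one per position.
#' @export
spot_sigma_at <- function(plane, geometry, spectrum, z_positions_mm,
                          particle = proton_spec()) {
  m0 <- if (inherits(plane, "optics_plane")) moments_from_optics(plane) else plane
  vapply(z_positions_mm, function(z) {
    sqrt(propagate_moments(m0, geometry, spectrum, z, particle)$var_x)
  }, numeric(1))
}

#' @rdname spot_sigma_at
#' @details `spot_fwhm_at()` multiplies sigma by `2 sqrt(2 ln 2)` (Gaussian
#'   identity).
#' @export
spot_fwhm_at <- function(plane, geometry, spectrum, z_positions_mm,
                         particle = proton_spec()) {
  FWHM_PER_SIGMA * spot_sigma_at(plane, geometry, spectrum, z_positions_mm, particle)
}
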