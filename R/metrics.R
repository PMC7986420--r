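# Coerce the various curve representations (depth_dose_curve,
# lateral_profile, two-column data.frame, list with two numeric fields)
# to a plain list(x, y).
curve_xy <- function(curve) {
  if (inherits(curve, "depth_dose_curve")) {
    return(list(x = curve$depth_mm, y = curve$dose))
  }
  if (inherits(curve, "lateral_profile")) {
    return(list(x = curve$offset_mm, y = curve$intensity))
  }
  if (is.data.frame(curve) && ncol(curve) >= 2) {
    return(list(x = curve[[1]], y = curve[[2]]))
  }
  if (is.list(curve) && length(curve) >= 2 &&
      is.numeric(curve[[1]]) && is.numeric(curve[[2]])) {
    return(list(x = curve[[1]], y = curve[[2]]))
  }
  stop("expected a curve with two numeric columns", call. = FALSE)
}

# All x where the piecewise-linear interpolant of (x, y) crosses `level`,
# with the local direction (+1 rising, -1 falling). Strict sign changes are
# interpolated inside the interval; samples exactly at the level are grouped
# into runs and emit crossings at the run edges (first sample for rising,
# last for falling), so exact hits and plateaus behave sensibly.
level_crossings <- function(x, y, level) {
  n <- length(x)
  pos <- numeric(0)
  dir <- numeric(0)
  emit <- function(p, d) { pos <<- c(pos, p); dir <<- c(dir, d) }
  i <- 1
  while (i < n) {
    y1 <- y[i]; y2 <- y[i + 1]
    if (y1 == level) {
      b <- i
      while (b < n && y[b + 1] == level) b <- b + 1
      prev <- if (i > 1) y[i - 1] else NA
      nxt <- if (b < n) y[b + 1] else NA
      # impute a missing side by monotone continuation of the other
      if (is.na(prev) && !is.na(nxt)) prev <- if (nxt > level) level - 1 else level + 1
      if (is.na(nxt) && !is.na(prev)) nxt <- if (prev > level) level - 1 else level + 1
      if (!is.na(prev)) {
        if (prev < level && nxt > level) emit(x[i], 1)
        else if (prev > level && nxt < level) emit(x[b], -1)
        else if (prev < level && nxt < level) { emit(x[i], 1); emit(x[b], -1) }
        else if (prev > level && nxt > level) { emit(x[i], -1); emit(x[b], 1) }
      }
      i <- b + 1
      next
    }
    if (y2 != level && (y1 - level) * (y2 - level) < 0) {
      frac <- (level - y1) / (y2 - y1)
      emit(x[i] + frac * (x[i + 1] - x[i]), sign(y2 - y1))
    }
    i <- i + 1
  }
  if (n >= 2 && y[n] == level && y[n - 1] != level) {
    emit(x[n], sign(y[n] - y[n - 1]))
  }
  list(position = pos, direction = dir)
}

#' Distal 80% range (R80) of a depth-dose curve
#'
#' Depth at which the distal falloff crosses 80% of the curve maximum,
#' linearly interpolated between the bracketing samples. When bin noise
#' produces several distal crossings, the outermost (deepest) one is taken.
#' The result is invariant under positive rescaling of the dose.
#'
#' @param curve A [depth_dose_curve()] or any two-column (depth, dose)
#'   structure.
#' @param level Fraction of the maximum defining the range (default 0.8).
#' @return Depth \[mm\].
#' @export
#' @examples
#' r80(data.frame(depth = 0:4, dose = c(1, 2, 4, 2, 0)))  # 2.4
r80 <- function(curve, level = 0.8) {
  cv <- curve_xy(curve)
  ipk <- which.max(cv$y)
  thr <- level * cv$y[ipk]
  cr <- level_crossings(cv$x, cv$y, thr)
  distal <- cr$position[cr$direction < 0 & cr$position >= cv$x[ipk]]
  if (length(distal) == 0) {
    stop("r80: curve has no distal falloff crossing the threshold", call. = FALSE)
  }
  max(distal)
}

#' Bragg peak width at a fractional level
#'
#' Distance between the proximal and distal crossings of `level * max`
#' (linear interpolation; outermost crossing on each side). BPW50 and BPW80
#' are `level = 0.5` and `0.8`.
#'
#' @param curve A depth-dose curve (see [r80()]).
#' @param level Fraction of the peak maximum, in (0, 1); typically 0.5 or
#'   0.8.
#' @return Width \[mm\].
#' @export
bragg_peak_width <- function(curve, level) {
  stopifnot(level > 0, level < 1)
  cv <- curve_xy(curve)
  ipk <- which.max(cv$y)
  thr <- level * cv$y[ipk]
  cr <- level_crossings(cv$x, cv$y, thr)
  proximal <- cr$position[cr$direction > 0 & cr$position <= cv$x[ipk]]
  distal <- cr$position[cr$direction < 0 & cr$position >= cv$x[ipk]]
  if (length(proximal) == 0 || length(distal) == 0) {
    stop(sprintf("bragg_peak_width: missing %s crossing at level %.2f",
                 if (length(proximal) == 0) "proximal" else "distal", level),
         call. = FALSE)
  }
  max(distal) - min(proximal)
}

#' All depth-dose observables used by the tuning pipeline
#'
#' @param curve A depth-dose curve (see [r80()]).
#' @return A list with `r80`, `bpw50`, `bpw80`, `peak_depth`, `peak_value`.
#' @export
idc_metrics <- function(curve) {
  cv <- curve_xy(curve)
  ipk <- which.max(cv$y)
  out <- list(
    r80 = r80(curve),
    bpw50 = bragg_peak_width(curve, 0.5),
    bpw80 = bragg_peak_width(curve, 0.8),
    peak_depth = cv$x[ipk],
    peak_value = cv$y[ipk]
  )
  stopifnot(out$bpw50 > out$bpw80, out$r80 > out$peak_depth)
  out
}

#' Sampled lateral beam profile
#'
#' A one-dimensional lateral dose profile with a single dominant peak,
#' sampled on a strictly increasing offset grid (default bin 0.5 mm, the
#' scintillator-screen resolution).
#'
#' @param offset_mm Offsets \[mm\], strictly increasing, >= 7 samples.
#' @param intensity Intensities \[arb\], >= 0.
#' @return An object of class `lateral_profile` (also a data.frame).
#' @export
lateral_profile <- function(offset_mm, intensity) {
  if (length(offset_mm) < 7) stop("lateral_profile: needs >= 7 samples", call. = FALSE)
  if (length(offset_mm) != length(intensity)) {
    stop("lateral_profile: offset and intensity lengths differ", call. = FALSE)
  }
  if (any(diff(offset_mm) <= 0)) {
    stop("lateral_profile: offsets must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("lateral_profile: intensity must be finite and >= 0", call. = FALSE)
  }
  structure(data.frame(offset_mm = offset_mm, intensity = intensity),
            class = c("lateral_profile", "data.frame"))
}

#' Sample a Gaussian lateral profile on a regular grid
#'
#' @param sigma_mm Gaussian sigma \[mm\], > 0.
#' @param center_mm Peak position \[mm\].
#' @param bin_mm Grid step \[mm\] (default 0.5, screen resolution).
#' @param halfwidth_mm Half extent of the grid (default 6 sigma, rounded up
#'   to the bin).
#' @return A [lateral_profile()].
#' @export
sample_lateral_profile <- function(sigma_mm, center_mm = 0, bin_mm = 0.5,
                                   halfwidth_mm = NULL) {
  stopifnot(sigma_mm > 0, bin_mm > 0)
  if (is.null(halfwidth_mm)) halfwidth_mm <- ceiling(6 * sigma_mm / bin_mm) * bin_mm
  x <- seq(-halfwidth_mm, halfwidth_mm, by = bin_mm) + center_mm
  lateral_profile(x, exp(-(x - center_mm)^2 / (2 * sigma_mm^2)))
}

#' Full width at half maximum of a lateral profile
#'
#' Linear-interpolated distance between the half-maximum crossings of the
#' two flanks. Scanning proceeds from the peak outwards, so the innermost
#' crossing of each flank is used (robust to far-tail noise). For a sampled
#' Gaussian this reproduces `2 sqrt(2 ln 2) sigma` to about one part in 1e3
#' at 0.5 mm binning.
#'
#' @param profile A [lateral_profile()] or two-column (offset, intensity)
#'   structure.
#' @param estimator `"crossings"` (default, half-max interpolation) or
#'   `"gaussfit"` (log-parabola Gaussian fit, emulating vendor spot
#'   analysis software).
#' @return Width \[mm\].
#' @export
fwhm <- function(profile, estimator = c("crossings", "gaussfit")) {
  estimator <- match.arg(estimator)
  if (estimator == "gaussfit") return(fwhm_gaussian_fit(profile))
  cv <- curve_xy(profile)
  ipk <- which.max(cv$y)
  half <- cv$y[ipk] / 2
  cr <- level_crossings(cv$x, cv$y, half)
  left <- cr$position[cr$direction > 0 & cr$position <= cv$x[ipk]]
  right <- cr$position[cr$direction < 0 & cr$position >= cv$x[ipk]]
  if (length(left) == 0 || length(right) == 0) {
    stop("fwhm: profile does not cross half maximum on both flanks", call. = FALSE)
  }
  min(right) - max(left)  # innermost flank crossings
}

#' @rdname fwhm
#' @export
fwhm_gaussian_fit <- function(profile) {
  cv <- curve_xy(profile)
  keep <- cv$y > 0.1 * max(cv$y)
  x <- cv$x[keep]; y <- cv$y[keep]
  if (sum(keep) < 5) stop("fwhm_gaussian_fit: too few samples above 10% of max", call. = FALSE)
  fit <- stats::lm(log(y) ~ x + I(x^2))
  a2 <- stats::coef(fit)[["I(x^2)"]]
  if (!is.finite(a2) || a2 >= 0) {
    stop("fwhm_gaussian_fit: profile is not log-concave", call. = FALSE)
  }
  FWHM_PER_SIGMA * sqrt(-1 / (2 * a2))
}
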