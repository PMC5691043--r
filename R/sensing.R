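# Central-intensity sensing scans. All scans share one normalization (raw
# intensities under a fixed pupil power), read the optical-axis pixel, and
# return tibbles so results pipe into extremum_fit() and ggplot2.

#' Central (optical-axis) intensity of a PSF
#'
#' Returns the value of the optical-axis pixel, index `floor(n_fft/2)`
#' (0-based), of an intensity PSF on the unshifted focal grid.
#'
#' @param psf An `intensity_psf`.
#' @return Nonnegative scalar.
#' @export
central_intensity <- function(psf) {
  stopifnot(inherits(psf, "intensity_psf"))
  psf$values[psf$center_index, psf$center_index]
}

new_scan <- function(parameter, unit, values, readouts, mask_kind, aberrations,
                     extra = list()) {
  out <- tibble(parameter = values, central_intensity = readouts)
  names(out)[1] <- parameter
  attr(out, "parameter") <- parameter
  attr(out, "unit") <- unit
  attr(out, "mask_kind") <- mask_kind
  attr(out, "aberrations") <- aberrations
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("sted_scan", class(out))
  out
}

scan_settings <- function(grid, optics, beam_fwhm_fraction, polarization) {
  list(
    grid = grid, optics = optics,
    beam = beam_fwhm_fraction, pol = polarization
  )
}

scan_readout <- function(mask, aberrations, s) {
  pf <- compose_pupil(s$grid,
    mask = mask, aberrations = aberrations,
    beam_fwhm_fraction = s$beam, polarization = s$pol
  )
  central_intensity_direct(pf, s$optics)
}

#' Half-space displacement scan (lateral mask alignment)
#'
#' Sweeps the lateral displacement of the half-space phase border across the
#' beam profile and records the central PSF intensity at each offset; the
#' border is perpendicular to `axis`. The readout pixel is fixed on the
#' optical axis (shifting the mask border does not move the PSF). The
#' central-intensity minimum locates the beam center on the modulator, also
#' in the presence of low-order aberrations.
#'
#' @param axis `"x"` or `"y"`: scan direction (border perpendicular to it).
#' @param offsets Numeric vector of border displacements in normalized pupil
#'   units.
#' @param aberrations Optional [zernike_spec()] (or list) present in the
#'   wavefront.
#' @param grid,optics,beam_fwhm_fraction,polarization Simulation setting.
#' @return A `sted_scan` tibble with columns `offset`, `central_intensity`.
#' @export
displacement_scan <- function(axis = c("x", "y"),
                              offsets = seq(-1, 1, by = 0.1),
                              aberrations = NULL,
                              grid = grid_preset(),
                              optics = optics_config(),
                              beam_fwhm_fraction = 0.58,
                              polarization = circular_polarization()) {
  axis <- match.arg(axis)
  aberrations <- as_aberration_list(aberrations)
  s <- scan_settings(grid, optics, beam_fwhm_fraction, polarization)
  angle <- if (axis == "x") 0 else 90
  readouts <- vapply(
    offsets,
    function(d) {
      scan_readout(
        segment_mask("half_space", angle = angle, offset = d, grid = grid),
        aberrations, s
      )
    },
    numeric(1)
  )
  new_scan("offset", "pupil radius units", offsets, readouts,
    "half_space", aberrations,
    extra = list(axis = axis)
  )
}

mask_for_kind <- function(kind, angle, grid, radius = 0.6) {
  switch(kind,
    four_segments = ,
    six_segments = ,
    half_space = segment_mask(kind, angle = angle, grid = grid),
    split_bullseye = split_bullseye_mask(angle, radius = radius, grid = grid),
    abort(sprintf("Unsupported mask kind '%s' for a rotation scan.", kind))
  )
}

mask_period <- function(kind) {
  switch(kind,
    four_segments = 90,
    six_segments = 60,
    split_bullseye = 360,
    half_space = 360,
    abort(sprintf("No rotation period defined for mask '%s'.", kind))
  )
}

#' Mask rotation scan (aberration orientation sensing)
#'
#' Rotates a sensing mask and records the central PSF intensity per angle.
#' Under an aberration of matching azimuthal symmetry the signal is maximal
#' when the mask angle equals the mode orientation; cross-sensitivities to
#' the other low-order modes are small.
#'
#' @param mask_kind `"four_segments"`, `"six_segments"` or
#'   `"split_bullseye"`.
#' @param angles Mask rotation angles in degrees.
#' @param aberrations [zernike_spec()] or list of them.
#' @param radius Split-bullseye radius (ignored otherwise).
#' @inheritParams displacement_scan
#' @return A `sted_scan` tibble with columns `angle`, `central_intensity`.
#' @export
rotation_scan <- function(mask_kind = c(
                            "four_segments", "six_segments",
                            "split_bullseye"
                          ),
                          angles = NULL, aberrations = NULL, radius = 0.6,
                          grid = grid_preset(), optics = optics_config(),
                          beam_fwhm_fraction = 0.58,
                          polarization = circular_polarization()) {
  mask_kind <- match.arg(mask_kind)
  period <- mask_period(mask_kind)
  if (is.null(angles)) {
    angles <- seq(0, period, length.out = 11)[1:10]
  }
  aberrations <- as_aberration_list(aberrations)
  s <- scan_settings(grid, optics, beam_fwhm_fraction, polarization)
  readouts <- vapply(
    angles,
    function(a) {
      scan_readout(mask_for_kind(mask_kind, a, grid, radius), aberrations, s)
    },
    numeric(1)
  )
  new_scan("angle", "deg", angles, readouts, mask_kind, aberrations,
    extra = list(period = period)
  )
}

#' Bias-amplitude scan (aberration amplitude sensing)
#'
#' Adds a compensating Zernike mode of varying PV amplitude, at a fixed
#' orientation, on top of the system aberration (sensing mask applied at
#' `mask_angle`) and records the central intensity. The minimum locates the
#' compensating amplitude, i.e. minus the system amplitude of that mode.
#'
#' @param mask_kind,mask_angle Sensing mask and its (fixed) rotation angle in
#'   degrees.
#' @param mode A [zernike_spec()] template: its mode and orientation are
#'   used, its amplitude is replaced by each value of `amplitudes`.
#' @param amplitudes Compensating PV amplitudes in radians.
#' @param system_aberration [zernike_spec()] or list: the (unknown)
#'   aberration of the system.
#' @inheritParams rotation_scan
#' @return A `sted_scan` tibble with columns `amplitude`, `central_intensity`.
#' @export
amplitude_scan <- function(mask_kind, mask_angle, mode,
                           amplitudes = seq(-0.8 * pi, 0.8 * pi,
                             length.out = 11
                           ),
                           system_aberration = NULL, radius = 0.6,
                           grid = grid_preset(), optics = optics_config(),
                           beam_fwhm_fraction = 0.58,
                           polarization = circular_polarization()) {
  stopifnot(inherits(mode, "zernike_spec"))
  system_aberration <- as_aberration_list(system_aberration)
  s <- scan_settings(grid, optics, beam_fwhm_fraction, polarization)
  mask <- mask_for_kind(mask_kind, mask_angle, grid, radius)
  readouts <- vapply(
    amplitudes,
    function(a) {
      specs <- c(
        system_aberration,
        list(zernike_spec(mode$mode, a, mode$orientation))
      )
      scan_readout(mask, specs, s)
    },
    numeric(1)
  )
  new_scan("amplitude", "rad PV", amplitudes, readouts, mask_kind,
    system_aberration,
    extra = list(mode = mode$mode, mode_orientation = mode$orientation)
  )
}

#' Least-squares extremum of a scan
#'
#' Fits a quadratic through the `n_points` readouts bracketing the best
#' (minimal or maximal) readout and returns the vertex -- the
#' three-measurements-plus-least-squares shortcut to the scan extremum. For
#' periodic parameters (rotation scans) the bracketing handles wrap-around
#' when the scan covers the full period. If the best readout sits at the end
#' of a non-periodic scan, or the fitted curvature has the wrong sign, the
#' result is flagged and the best sampled point is returned.
#'
#' @param scan A `sted_scan` tibble (or any data frame whose first column is
#'   the swept parameter and that has a `central_intensity` column).
#' @param n_points Number of points for the local fit (>= 3).
#' @param objective `"min"` or `"max"`.
#' @return A one-row tibble: `location`, `value`, `flagged`.
#' @examples
#' s <- tibble::tibble(offset = c(-1, 0, 1), central_intensity = c(1, 0, 1))
#' extremum_fit(s)
#' @export
extremum_fit <- function(scan, n_points = 3, objective = c("min", "max")) {
  objective <- match.arg(objective)
  if (n_points < 3) abort("`n_points` must be >= 3.")
  x <- scan[[1]]
  y <- scan$central_intensity
  n <- length(x)
  if (n < 3) abort("Need at least 3 scan points.")
  period <- attr(scan, "period")
  periodic <- !is.null(period) && is.finite(period) &&
    isTRUE(abs((max(x) - min(x)) + (x[2] - x[1]) - period) <
      1e-8 * period)
  best <- if (objective == "min") which.min(y) else which.max(y)
  half <- (n_points - 1) %/% 2
  if (periodic) {
    sel <- ((best - half - 1):(best + (n_points - 1 - half) - 1)) %% n + 1
    xs <- x[sel]
    # unwrap around the best point
    xs <- x[best] + ((xs - x[best] + period / 2) %% period) - period / 2
    ys <- y[sel]
  } else {
    lo <- max(1, min(best - half, n - n_points + 1))
    sel <- lo:(lo + n_points - 1)
    xs <- x[sel]
    ys <- y[sel]
    if (best == 1 || best == n) {
      return(tibble(location = x[best], value = y[best], flagged = TRUE))
    }
  }
  fit <- lm(ys ~ xs + I(xs^2))
  a2 <- coef(fit)[[3]]
  ok <- if (objective == "min") a2 > 0 else a2 < 0
  if (!is.finite(a2) || !ok) {
    return(tibble(location = x[best], value = y[best], flagged = TRUE))
  }
  loc <- -coef(fit)[[2]] / (2 * a2)
  val <- predict_quad(coef(fit), loc)
  tibble(location = loc, value = val, flagged = FALSE)
}

predict_quad <- function(cf, x) cf[[1]] + cf[[2]] * x + cf[[3]] * x^2

#' Intensity centroid shift of a PSF
#'
#' First moment of the intensity distribution relative to the optical-axis
#' pixel, in nm. By default the full field is used; `window_radius` (nm)
#' optionally restricts the moment to a disc around the axis. On an even
#' FFT grid the first row/column (coordinate `-N/2`, which has no `+N/2`
#' partner) is excluded so the moment operator is symmetric about the axis
#' pixel.
#'
#' @param psf An `intensity_psf`.
#' @param window_radius Optional radius (nm) of a centered circular window.
#' @return Named numeric vector `c(dx, dy)` in nm.
#' @export
psf_centroid_shift <- function(psf, window_radius = NULL) {
  stopifnot(inherits(psf, "intensity_psf"))
  v <- psf$values
  if (nrow(v) %% 2 == 0) {
    v <- v[-1, -1, drop = FALSE]
    off <- 1L
  } else {
    off <- 0L
  }
  n <- nrow(v)
  x <- ((1:n) + off - psf$center_index) * psf$step
  if (!is.null(window_radius)) {
    X <- outer(x, rep(1, n))
    Y <- outer(rep(1, n), x)
    v <- v * ((X^2 + Y^2) <= window_radius^2)
  }
  s <- sum(v)
  if (s <= 0) abort("PSF has no energy (all zero).")
  c(
    dx = sum(rowSums(v) * x) / s,
    dy = sum(colSums(v) * x) / s
  )
}
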