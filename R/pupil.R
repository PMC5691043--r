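#' Circular polarization state
#'
#' Complex Jones vector `(1, i * handedness) / sqrt(2)`. The default
#' handedness `+1` is matched to the charge-1 vortex: with it the helical
#' phase cancels the geometric polarization phase on the optical axis at high
#' NA and the doughnut keeps its central zero. The opposite handedness fills
#' the zero with axially polarized light.
#'
#' @param handedness `+1` (default) or `-1`.
#' @return Complex length-2 vector with unit norm.
#' @export
circular_polarization <- function(handedness = 1) {
  if (!handedness %in% c(-1, 1)) abort("`handedness` must be +1 or -1.")
  c(1, handedness * 1i) / sqrt(2)
}

#' Compose the pupil function
#'
#' Builds the pupil field entering the objective: a Gaussian beam amplitude
#' truncated by the aperture, the phase-mask phase plus a sum of Zernike
#' aberration phases, and a transverse polarization state. The beam width is
#' given as the intensity-FWHM diameter of the Gaussian as a fraction of the
#' aperture diameter (default 0.58), i.e. amplitude
#' `exp(-(kx^2 + ky^2) / w^2)` with `w = fwhm_fraction / (2 * sqrt(ln(2)/2))`.
#'
#' @param grid A [pupil_grid()].
#' @param mask A `phase_mask` (default flat) defined on `grid`.
#' @param aberrations A [zernike_spec()] or list of them.
#' @param beam_fwhm_fraction Intensity-FWHM beam diameter over aperture
#'   diameter, in `(0, 2]`.
#' @param polarization Complex Jones 2-vector, unit norm
#'   (default [circular_polarization()]).
#' @return A `pupil_field`: list with `amplitude`, `phase` (radian matrices on
#'   the aperture grid), `polarization`, `beam_fwhm_fraction` and `grid`.
#' @examples
#' g <- pupil_grid(48, 512)
#' pf <- compose_pupil(g, mask = vortex_fork_mask(0, g))
#' @export
compose_pupil <- function(grid = grid_preset(), mask = NULL, aberrations = NULL,
                          beam_fwhm_fraction = 0.58,
                          polarization = circular_polarization()) {
  stopifnot(inherits(grid, "pupil_grid"))
  if (is.null(mask)) mask <- flat_mask(grid)
  stopifnot(inherits(mask, "phase_mask"))
  if (!identical(dim(mask$values), dim(grid$kx))) {
    abort("`mask` was built on a different grid than `grid`.")
  }
  if (beam_fwhm_fraction <= 0 || beam_fwhm_fraction > 2) {
    abort("`beam_fwhm_fraction` must be in (0, 2].")
  }
  if (length(polarization) != 2 ||
    abs(sum(Mod(polarization)^2) - 1) > 1e-9) {
    abort("`polarization` must be a unit-norm complex 2-vector.")
  }
  w <- beam_fwhm_fraction / (2 * sqrt(log(2) / 2))
  amplitude <- ifelse(grid$aperture, exp(-(grid$rho^2) / w^2), 0)
  phase <- mask$values + zernike_sum(as_aberration_list(aberrations), grid)
  phase[!grid$aperture] <- 0
  structure(
    list(
      amplitude = amplitude, phase = phase,
      polarization = as.complex(polarization),
      beam_fwhm_fraction = beam_fwhm_fraction,
      grid = grid, mask = mask
    ),
    class = "pupil_field"
  )
}

#' @export
print.pupil_field <- function(x, ...) {
  cat(sprintf(
    "<pupil_field> %s mask, beam fill %g, pol (%.2f%+.2fi, %.2f%+.2fi)\n",
    x$mask$kind, x$beam_fwhm_fraction,
    Re(x$polarization[1]), Im(x$polarization[1]),
    Re(x$polarization[2]), Im(x$polarization[2])
  ))
  invisible(x)
}

#' Shift-compensating tilt for a coma bias
#'
#' Zernike coma displaces the focal intensity centroid laterally (under the
#' apodized, Gaussian-weighted pupil the built-in tilt term of the balanced
#' coma polynomial does not cancel the weighted mean phase gradient). The
#' displacement is linear in the coma amplitude, so a compensating tilt can
#' be calibrated once at a small reference amplitude and scaled. This
#' function performs that calibration by simulation: it measures the centroid
#' shift per unit coma and per unit tilt at `reference_amplitude` and returns
#' the tilt PV amplitude (radians) that cancels the shift of `amplitude` of
#' coma at the same orientation.
#'
#' @param amplitude Coma PV amplitude in radians (`|amplitude| <= pi`, the
#'   linear regime).
#' @param grid,optics Simulation setting.
#' @param beam_fwhm_fraction Beam fill used in the calibration.
#' @param reference_amplitude PV amplitude used for the linear calibration.
#' @return Tilt PV amplitude in radians (same orientation as the coma).
#' @export
coma_tilt_compensation <- function(amplitude, grid = grid_preset(),
                                   optics = optics_config(),
                                   beam_fwhm_fraction = 0.58,
                                   reference_amplitude = 0.1 * pi) {
  if (abs(amplitude) > pi) {
    abort("`amplitude` must be within the linear regime |amplitude| <= pi.")
  }
  if (amplitude == 0) return(0)
  shift_of <- function(specs) {
    pf <- compose_pupil(grid,
      aberrations = specs,
      beam_fwhm_fraction = beam_fwhm_fraction
    )
    psf_centroid_shift(intensity(propagate(pf, optics)))[["dx"]]
  }
  s_coma <- shift_of(list(zernike_spec("coma", reference_amplitude, 0)))
  s_tilt <- shift_of(list(zernike_spec("tilt", reference_amplitude, 0)))
  -amplitude * (s_coma / s_tilt)
}
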