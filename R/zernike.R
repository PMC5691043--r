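# Low-order Zernike aberration modes, normalized to unit peak-to-valley over
# the unit disk so that quoted amplitudes ("0.4 pi rad PV") apply directly.
#
# Orientation convention (sensor-aligned): orientation theta rotates the mode
# pattern counterclockwise, and the reference (theta = 0) form of each
# azimuthal mode is chosen such that its matching sensing mask at rotation
# angle theta produces the maximal central-intensity signal when the mode sits
# at orientation theta. This is the operational convention of modal sensing
# with segmented masks: the compensating mode is applied at the mask angle of
# maximal signal.

.zernike_modes <- list(
  # f(rho, phi_rel) already PV-normalized to 1
  tilt = list(
    fun = function(rho, phi) rho * cos(phi) / 2,
    period = 360
  ),
  defocus = list(
    fun = function(rho, phi) (2 * rho^2 - 1) / 2,
    period = NA_real_
  ),
  astigmatism = list(
    fun = function(rho, phi) rho^2 * sin(2 * phi) / 2,
    period = 180
  ),
  coma = list(
    fun = function(rho, phi) -(3 * rho^3 - 2 * rho) * cos(phi) / 2,
    period = 360
  ),
  trefoil = list(
    fun = function(rho, phi) rho^3 * sin(3 * phi) / 2,
    period = 120
  ),
  spherical = list(
    fun = function(rho, phi) (6 * rho^4 - 6 * rho^2 + 1) / 1.5,
    period = NA_real_
  )
)

#' Supported Zernike modes
#'
#' @return Tibble with mode names and the azimuthal period (degrees) of the
#'   orientation parameter (`NA` for rotationally symmetric modes).
#' @export
zernike_modes <- function() {
  tibble(
    mode = names(.zernike_modes),
    period_deg = vapply(.zernike_modes, function(m) m$period, numeric(1))
  )
}

#' Specify a Zernike aberration mode
#'
#' Amplitude is the peak-to-valley (PV) phase excursion of the mode over the
#' unit disk, in radians. Orientation (degrees, counterclockwise) is reduced
#' modulo the mode's azimuthal period: 180 for astigmatism, 360 for coma and
#' tilt, 120 for trefoil.
#'
#' @param mode One of `"tilt"`, `"defocus"`, `"astigmatism"`, `"coma"`,
#'   `"trefoil"`, `"spherical"`.
#' @param amplitude PV amplitude in radians.
#' @param orientation Orientation in degrees.
#' @return A `zernike_spec` object.
#' @examples
#' zernike_spec("astigmatism", 0.4 * pi, 30)
#' @export
zernike_spec <- function(mode, amplitude, orientation = 0) {
  if (!is.character(mode) || length(mode) != 1 ||
    !mode %in% names(.zernike_modes)) {
    abort(paste0(
      "Unsupported Zernike mode; must be one of ",
      paste(names(.zernike_modes), collapse = ", "), "."
    ))
  }
  period <- .zernike_modes[[mode]]$period
  if (!is.na(period)) orientation <- orientation %% period else orientation <- 0
  structure(
    list(mode = mode, amplitude = amplitude, orientation = orientation),
    class = "zernike_spec"
  )
}

#' @export
print.zernike_spec <- function(x, ...) {
  cat(sprintf(
    "<zernike_spec> %s, PV %.4g rad (%.3g pi), orientation %g deg\n",
    x$mode, x$amplitude, x$amplitude / pi, x$orientation
  ))
  invisible(x)
}

#' Evaluate a Zernike aberration phase on a pupil grid
#'
#' Returns the phase grid (radians) of the mode scaled so that its
#' peak-to-valley excursion over the unit disk equals `spec$amplitude`.
#' Outside the open aperture the phase is zero.
#'
#' @param spec A [zernike_spec()].
#' @param grid A [pupil_grid()].
#' @return Numeric matrix (`n_aperture` x `n_aperture`) of phase in radians.
#' @examples
#' g <- pupil_grid(48, 512)
#' ph <- zernike_phase(zernike_spec("astigmatism", 0.4 * pi), g)
#' max(ph[g$aperture]) - min(ph[g$aperture]) # ~ 0.4 pi
#' @export
zernike_phase <- function(spec, grid) {
  stopifnot(inherits(spec, "zernike_spec"), inherits(grid, "pupil_grid"))
  m <- .zernike_modes[[spec$mode]]
  phi_rel <- grid$phi - spec$orientation * pi / 180
  ph <- spec$amplitude * m$fun(grid$rho, phi_rel)
  ph[!grid$aperture] <- 0
  ph
}

# Sum a list of zernike_spec phases on a grid (empty list -> zero matrix).
zernike_sum <- function(aberrations, grid) {
  ph <- matrix(0, grid$n_aperture, grid$n_aperture)
  for (spec in aberrations) ph <- ph + zernike_phase(spec, grid)
  ph
}

# Normalize 'aberrations' argument: NULL, a single spec, or a list of specs.
as_aberration_list <- function(aberrations) {
  if (is.null(aberrations)) return(list())
  if (inherits(aberrations, "zernike_spec")) return(list(aberrations))
  if (is.list(aberrations) &&
    all(vapply(aberrations, inherits, logical(1), "zernike_spec"))) {
    return(aberrations)
  }
  abort("`aberrations` must be a zernike_spec or a list of zernike_spec.")
}
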