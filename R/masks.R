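# Binary and vortex phase masks, evaluated analytically at each pupil sample
# (no raster rotation/interpolation, so pi-steps stay sharp). Rotation angles
# are degrees, counterclockwise in the (kx, ky) plane; patterns are evaluated
# in coordinates rotated by -angle. Border pixels follow the printed
# inequalities (the equality branch takes the pi value where the defining
# condition uses ">=").

new_phase_mask <- function(kind, values, grid, angle = 0, offset = 0,
                           radius = NA_real_, tilt_cycles = 0) {
  structure(
    list(
      kind = kind, angle = angle, offset = offset, radius = radius,
      tilt_cycles = tilt_cycles, values = values, grid = grid
    ),
    class = "phase_mask"
  )
}

#' @export
print.phase_mask <- function(x, ...) {
  cat(sprintf(
    "<phase_mask> %s (angle %g deg%s%s) on %dx%d aperture grid\n",
    x$kind, x$angle,
    if (x$offset != 0) sprintf(", offset %g", x$offset) else "",
    if (!is.na(x$radius)) sprintf(", R %g", x$radius) else "",
    x$grid$n_aperture, x$grid$n_aperture
  ))
  invisible(x)
}

# rotate pupil coordinates by -angle (so the pattern appears rotated by +angle)
rotated_coords <- function(grid, angle) {
  th <- -angle * pi / 180
  list(
    kx = cos(th) * grid$kx - sin(th) * grid$ky,
    ky = sin(th) * grid$kx + cos(th) * grid$ky
  )
}

#' Segmented binary phase masks
#'
#' Generates the three segmented 0/pi masks used for alignment and
#' aberration sensing:
#' * `half_space`: pi for `kx >= 0`, 0 otherwise (vertical phase border
#'   through the pupil center at angle 0). `offset` displaces the border
#'   along its normal, in normalized pupil units, for alignment scans.
#' * `four_segments`: pi where `kx * ky >= 0` (quadrant pattern, astigmatism
#'   sensor, 90 degree symmetry).
#' * `six_segments`: pi on alternating 60-degree sectors starting at azimuth
#'   0 (trefoil sensor, 60 degree symmetry).
#'
#' @param kind `"half_space"`, `"four_segments"` or `"six_segments"`.
#' @param angle Pattern rotation in degrees (counterclockwise).
#' @param offset Border displacement in normalized pupil units
#'   (`half_space` only, `|offset| <= 1`).
#' @param grid A [pupil_grid()].
#' @return A `phase_mask` with values in `{0, pi}`.
#' @examples
#' m <- segment_mask("four_segments", grid = pupil_grid(48, 512))
#' unique(as.vector(m$values))
#' @export
segment_mask <- function(kind = c("half_space", "four_segments", "six_segments"),
                         angle = 0, offset = 0, grid = grid_preset()) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "pupil_grid"))
  if (offset != 0 && kind != "half_space") {
    abort("`offset` is only meaningful for the half_space mask.")
  }
  if (abs(offset) > 1) abort("`offset` must satisfy |offset| <= 1.")
  rc <- rotated_coords(grid, angle)
  values <- switch(kind,
    half_space = ifelse(rc$kx - offset >= 0, pi, 0),
    four_segments = ifelse(rc$kx * rc$ky >= 0, pi, 0),
    six_segments = {
      ph <- atan2(rc$ky, rc$kx) %% (2 * pi)
      ifelse(
        (ph < pi / 3) |
          (ph >= 2 * pi / 3 & ph < pi) |
          (ph >= 4 * pi / 3 & ph < 5 * pi / 3),
        pi, 0
      )
    }
  )
  new_phase_mask(kind, values, grid, angle = angle, offset = offset)
}

#' Split-bullseye mask (coma sensor)
#'
#' Pointwise sum, modulo 2 pi, of a circular pi-disc of radius `radius`
#' (normalized pupil units) and the half-space pi-step, with the phase border
#' rotated by `angle`. The default radius 0.6 matches a Gaussian beam filling
#' 58% of the aperture; for a flat-top beam a radius near 0.8 (the outer zero
#' of the coma polynomial) is the natural choice.
#'
#' @param angle Rotation of the split border, degrees.
#' @param radius Disc radius in normalized pupil units, in (0, 1).
#' @param grid A [pupil_grid()].
#' @return A `phase_mask` with values in `{0, pi}`.
#' @export
split_bullseye_mask <- function(angle = 0, radius = 0.6, grid = grid_preset()) {
  stopifnot(inherits(grid, "pupil_grid"))
  if (radius <= 0 || radius >= 1) abort("`radius` must be in (0, 1).")
  rc <- rotated_coords(grid, angle)
  circ <- ifelse(grid$kx^2 + grid$ky^2 <= radius^2, pi, 0)
  split <- ifelse(rc$kx >= 0, pi, 0)
  values <- (circ + split) %% (2 * pi)
  new_phase_mask("split_bullseye", values, grid, angle = angle, radius = radius)
}

#' Vortex and fork masks (STED doughnut)
#'
#' Charge-1 helical phase `atan2(ky, kx)`, optionally with a blazed grating:
#' a linear ramp of `tilt_cycles` full cycles across the pupil diameter,
#' `tilt_cycles * 2 * pi * (kx + 1) / 2`. After wrapping to `[0, 2 pi)` the
#' tilted vortex is the "fork" pattern; the grating deflects the focus off
#' the optical axis so that unmodulated reflections do not fill the doughnut
#' minimum. Sensing computations use `tilt_cycles = 0`.
#'
#' @param tilt_cycles Grating cycles across the pupil diameter (`>= 0`;
#'   0 gives the pure vortex).
#' @param grid A [pupil_grid()].
#' @return A `phase_mask` with values in `[0, 2 pi)`.
#' @export
vortex_fork_mask <- function(tilt_cycles = 0, grid = grid_preset()) {
  stopifnot(inherits(grid, "pupil_grid"))
  if (tilt_cycles < 0) abort("`tilt_cycles` must be >= 0.")
  values <- wrap_phase(grid$phi + tilt_cycles * 2 * pi * (grid$kx + 1) / 2)
  new_phase_mask(if (tilt_cycles > 0) "fork" else "vortex",
    values, grid,
    tilt_cycles = tilt_cycles
  )
}

#' Flat (no-op) mask
#'
#' @param grid A [pupil_grid()].
#' @return A `phase_mask` of zeros.
#' @export
flat_mask <- function(grid = grid_preset()) {
  new_phase_mask("flat", matrix(0, grid$n_aperture, grid$n_aperture), grid)
}

#' Wrap phase values to `[0, 2 pi)`
#'
#' @param phase Numeric phase in radians.
#' @return Wrapped phase.
#' @export
wrap_phase <- function(phase) phase %% (2 * pi)
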