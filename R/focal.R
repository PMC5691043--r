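# Vectorial focal fields of a high-NA objective (Richards-Wolf / Debye
# theory). The transverse pupil polarization is rotated onto the focal
# sphere in the radial/azimuthal (p/s) basis; the p component bends by the
# focusing angle theta and acquires an axial part, the s component stays
# transverse. Each rotated component is weighted by cos(theta)^(-1/2)
# (aplanatic sqrt(cos) apodization times the solid-angle-to-(kx,ky) Jacobian
# 1/cos) and transformed to the focal plane by zero-padded 2D FFT. The
# direct-quadrature oracle evaluates the identical integrand by explicit
# summation at arbitrary focal points and pins the FFT bookkeeping.

fftshift2 <- function(m) {
  n <- nrow(m)
  s <- floor(n / 2)
  m[c((s + 1):n, 1:s), c((s + 1):n, 1:s)]
}

ifftshift2 <- function(m) {
  n <- nrow(m)
  s <- ceiling(n / 2)
  m[c((s + 1):n, 1:s), c((s + 1):n, 1:s)]
}

# Weighted pupil component grids (ex, ey, ez integrands) for a pupil_field.
pupil_components <- function(pupil, optics) {
  g <- pupil$grid
  sinth <- pmin(g$rho, 1) * optics$numerical_aperture / optics$refractive_index
  costh <- sqrt(pmax(0, 1 - sinth^2))
  weight <- ifelse(g$aperture, costh^(-0.5), 0)
  P <- pupil$amplitude * exp(1i * pupil$phase) * weight
  cphi <- cos(g$phi)
  sphi <- sin(g$phi)
  px <- pupil$polarization[1]
  py <- pupil$polarization[2]
  a_p <- px * cphi + py * sphi
  a_s <- -px * sphi + py * cphi
  list(
    ex = P * (a_p * costh * cphi - a_s * sphi),
    ey = P * (a_p * costh * sphi + a_s * cphi),
    ez = P * (a_p * sinth)
  )
}

#' Propagate a pupil field to the focal plane
#'
#' Computes the three complex focal-field components of `pupil` focused by
#' the high-NA objective described by `optics`, by zero-padded 2D-FFT
#' evaluation of the vectorial Debye integrals. The focal pixel pitch is
#' [focal_sampling()]; the optical axis is the pixel at `center_index`
#' (1-based, `floor(n_fft/2) + 1`). The half-pixel offset of the symmetric
#' pupil sampling is compensated by an analytic phase ramp, so the returned
#' complex fields equal the direct quadrature [debye_quadrature_oracle()] at
#' the focal grid points.
#'
#' Scaling is chosen so that total focal energy
#' `sum(|E|^2) * step^2` equals the weighted pupil energy
#' `sum(|P_w|^2) * dk^2` (`dk = 2/n_aperture`).
#'
#' @param pupil A `pupil_field` from [compose_pupil()].
#' @param optics An [optics_config()].
#' @return A `focal_field`: complex matrices `ex`, `ey`, `ez`
#'   (`n_fft` x `n_fft`, rows index x), `step` (nm), `center_index`.
#' @export
propagate <- function(pupil, optics = optics_config()) {
  stopifnot(inherits(pupil, "pupil_field"), inherits(optics, "optics_config"))
  g <- pupil$grid
  if (!identical(dim(pupil$amplitude), dim(g$kx)) ||
    !identical(dim(pupil$phase), dim(g$kx))) {
    abort("Pupil field and grid shapes do not match.")
  }
  comp <- pupil_components(pupil, optics)
  n <- g$n_fft
  c0 <- floor(n / 2) + 1L
  idx <- c0 + ((0:(g$n_aperture - 1)) - floor(g$n_aperture / 2))
  step <- focal_sampling(optics, g$n_aperture, g$n_fft)
  dk <- 2 / g$n_aperture
  scale <- dk / (n * step)
  x <- ((1:n) - c0) * step
  ramp <- exp(1i * g$delta * (2 * pi * optics$numerical_aperture /
    optics$wavelength) * x)
  ramp2 <- outer(ramp, ramp)
  tr <- function(m) {
    pad <- matrix(0i, n, n)
    pad[idx, idx] <- m
    fftshift2(fft(ifftshift2(pad), inverse = TRUE)) * scale * ramp2
  }
  structure(
    list(
      ex = tr(comp$ex), ey = tr(comp$ey), ez = tr(comp$ez),
      step = step, center_index = c0, optics = optics
    ),
    class = "focal_field"
  )
}

#' @export
print.focal_field <- function(x, ...) {
  cat(sprintf(
    "<focal_field> %dx%d, step %.3g nm\n",
    nrow(x$ex), ncol(x$ex), x$step
  ))
  invisible(x)
}

#' Intensity point-spread function
#'
#' @param field A `focal_field` from [propagate()].
#' @param normalization `"raw"` (default) or `"peak"` (max scaled to 1).
#' @return An `intensity_psf`: nonnegative matrix `values`, `step` (nm),
#'   `center_index`, `normalization`.
#' @export
intensity <- function(field, normalization = c("raw", "peak")) {
  stopifnot(inherits(field, "focal_field"))
  normalization <- match.arg(normalization)
  v <- Mod(field$ex)^2 + Mod(field$ey)^2 + Mod(field$ez)^2
  if (normalization == "peak") {
    mx <- max(v)
    if (mx > 0) v <- v / mx
  }
  structure(
    list(
      values = v, step = field$step,
      center_index = field$center_index, normalization = normalization
    ),
    class = "intensity_psf"
  )
}

#' @export
print.intensity_psf <- function(x, ...) {
  cat(sprintf(
    "<intensity_psf> %dx%d, step %.3g nm, %s\n",
    nrow(x$values), ncol(x$values), x$step, x$normalization
  ))
  invisible(x)
}

#' Direct-quadrature oracle for the vectorial Debye integral
#'
#' Evaluates the same weighted vectorial integrand as [propagate()] by
#' explicit summation `sum_k P_w(k) exp(i 2 pi NA/lambda (kx x + ky y))`
#' at a small list of focal-plane points. Intended as an independent check
#' of the FFT path (same discretization, different transform evaluation).
#'
#' @param pupil A `pupil_field`.
#' @param optics An [optics_config()].
#' @param points Two-column matrix or data frame of focal coordinates
#'   `(x, y)` in nm relative to the optical axis (at most a few hundred
#'   points).
#' @return Tibble with columns `x`, `y`, complex `ex`, `ey`, `ez`.
#' @export
debye_quadrature_oracle <- function(pupil, optics = optics_config(), points) {
  stopifnot(inherits(pupil, "pupil_field"))
  pts <- as.matrix(points)
  if (ncol(pts) != 2) abort("`points` must have two columns (x, y) in nm.")
  g <- pupil$grid
  comp <- pupil_components(pupil, optics)
  dk <- 2 / g$n_aperture
  step <- focal_sampling(optics, g$n_aperture, g$n_fft)
  scale <- dk / (g$n_fft * step)
  kfac <- 2 * pi * optics$numerical_aperture / optics$wavelength
  kx <- as.vector(g$kx)
  ky <- as.vector(g$ky)
  ex <- as.vector(comp$ex)
  ey <- as.vector(comp$ey)
  ez <- as.vector(comp$ez)
  out <- t(vapply(
    seq_len(nrow(pts)),
    function(i) {
      ph <- exp(1i * kfac * (kx * pts[i, 1] + ky * pts[i, 2]))
      c(sum(ex * ph), sum(ey * ph), sum(ez * ph)) * scale
    },
    complex(3)
  ))
  tibble(
    x = pts[, 1], y = pts[, 2],
    ex = out[, 1], ey = out[, 2], ez = out[, 3]
  )
}

#' Simulate an intensity PSF for a mask/aberration setting
#'
#' Convenience wrapper: composes the pupil, propagates it, and returns the
#' intensity PSF.
#'
#' @inheritParams compose_pupil
#' @param optics An [optics_config()].
#' @param normalization Passed to [intensity()].
#' @return An `intensity_psf`.
#' @export
simulate_psf <- function(grid = grid_preset(), mask = NULL, aberrations = NULL,
                         optics = optics_config(),
                         beam_fwhm_fraction = 0.58,
                         polarization = circular_polarization(),
                         normalization = "raw") {
  pf <- compose_pupil(grid,
    mask = mask, aberrations = aberrations,
    beam_fwhm_fraction = beam_fwhm_fraction, polarization = polarization
  )
  intensity(propagate(pf, optics), normalization = normalization)
}

# Central (optical-axis) intensity computed directly from the zero-frequency
# component of the weighted pupil -- identical by construction to the value
# of the center pixel of intensity(propagate(...)), at a fraction of the
# cost. Used by the sensing scans.
central_intensity_direct <- function(pupil, optics) {
  g <- pupil$grid
  comp <- pupil_components(pupil, optics)
  step <- focal_sampling(optics, g$n_aperture, g$n_fft)
  scale <- (2 / g$n_aperture) / (g$n_fft * step)
  sum(Mod(c(sum(comp$ex), sum(comp$ey), sum(comp$ez)) * scale)^2)
}
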