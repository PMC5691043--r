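# Shared fixtures: reduced-resolution grid (48 samples / 512-point FFT keeps
# the 24.8 nm focal step of the full 96/1024 setting) and default optics.

test_grid <- pupil_grid(48, 512)
test_optics <- optics_config() # 766 nm, NA 1.45, n = 1.5

# value of a mask at the grid sample nearest to (kx, ky)
mask_value_at <- function(mask, kx, ky) {
  i <- which.min(abs(mask$grid$k - kx))
  j <- which.min(abs(mask$grid$k - ky))
  mask$values[i, j]
}

# central intensity for a mask/aberration setting (direct axis readout)
central_of <- function(mask = NULL, aberrations = NULL, grid = test_grid,
                       optics = test_optics, ...) {
  psf <- simulate_psf(
    grid = grid, mask = mask, aberrations = aberrations,
    optics = optics, ...
  )
  central_intensity(psf)
}

# unmodulated (flat-mask, plane-wavefront) peak intensity, cached per grid
unmod_peak <- local({
  cache <- list()
  function(grid = test_grid, optics = test_optics) {
    key <- sprintf("%d_%d_%g", grid$n_aperture, grid$n_fft,
      optics$numerical_aperture)
    if (is.null(cache[[key]])) {
      psf <- simulate_psf(grid = grid, optics = optics)
      cache[[key]] <<- max(psf$values)
    }
    cache[[key]]
  }
})

# modulation (max - min central intensity) of a rotation scan
scan_modulation <- function(scan) diff(range(scan$central_intensity))
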