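# Pupil grids, Zernike aberration phases and binary/vortex phase masks.

test_that("pupil grid sampling is symmetric and validated", {
  g <- pupil_grid(48, 512)
  expect_equal(g$k, -rev(g$k)) # symmetric about the pupil center
  expect_false(any(g$k == 0)) # even n: no sample on the axes
  expect_equal(pupil_grid(49, 512)$k[25], 0) # odd n: center sampled
  expect_error(pupil_grid(96, 48), "n_fft")
  expect_error(pupil_grid(-1, 512), "positive")
})

test_that("zernike phases have the specified peak-to-valley amplitude", {
  fine <- pupil_grid(512, 512)
  pv <- function(spec) {
    ph <- zernike_phase(spec, fine)
    max(ph[fine$aperture]) - min(ph[fine$aperture])
  }
  # PV equals the quoted amplitude on a fine disk grid
  expect_equal(pv(zernike_spec("astigmatism", 0.4 * pi)), 0.4 * pi,
    tolerance = 1e-2
  )
  # PV scales linearly in amplitude (relative error < 1e-6)
  for (mode in c("astigmatism", "coma", "trefoil", "spherical")) {
    pvs <- vapply(
      c(0.1 * pi, 0.4 * pi, 0.8 * pi),
      function(a) pv(zernike_spec(mode, a)), numeric(1)
    )
    expect_equal(pvs / pvs[1], c(1, 4, 8), tolerance = 1e-6)
  }
  # zero amplitude: identically zero grid
  expect_equal(
    zernike_phase(zernike_spec("coma", 0), test_grid),
    matrix(0, 48, 48)
  )
  expect_error(zernike_spec("quadrafoil", 0.1), "Unsupported")
})

test_that("rotating astigmatism by 45 degrees gives the orthogonal partner", {
  g <- test_grid
  rotated <- zernike_phase(zernike_spec("astigmatism", 0.4 * pi, 45), g)
  # the 0-degree mode is the sin(2 phi) form; its orthogonal partner is the
  # cos(2 phi) form, picked up with inverted sign after a +45 deg rotation
  partner <- 0.4 * pi / 2 * g$rho^2 * cos(2 * g$phi)
  partner[!g$aperture] <- 0
  expect_equal(rotated, -partner, tolerance = 1e-12)
})

test_that("orientation is reduced modulo the mode's azimuthal period", {
  expect_equal(zernike_spec("astigmatism", 1, 190)$orientation, 10)
  expect_equal(zernike_spec("trefoil", 1, 125)$orientation, 5)
  expect_equal(zernike_spec("coma", 1, 370)$orientation, 10)
  expect_equal(zernike_spec("defocus", 1, 90)$orientation, 0)
})

test_that("segment masks follow their defining inequalities", {
  g <- pupil_grid(97, 512) # odd grid samples the reference points exactly
  hs <- segment_mask("half_space", grid = g)
  expect_equal(mask_value_at(hs, 0.5, 0), pi)
  expect_equal(mask_value_at(hs, -0.5, 0), 0)
  fs <- segment_mask("four_segments", grid = g)
  expect_equal(mask_value_at(fs, 0.3, 0.4), pi) # kx * ky >= 0
  expect_equal(mask_value_at(fs, -0.3, 0.4), 0)
  ss <- segment_mask("six_segments", grid = g)
  expect_equal(mask_value_at(ss, 0, 0.5), 0) # azimuth 90 deg in [60, 120)
  expect_equal(mask_value_at(ss, 0.5, 0.1), pi) # azimuth in [0, 60)
  # binary kinds take only values {0, pi}
  for (m in list(hs, fs, ss)) {
    expect_true(all(m$values %in% c(0, pi)))
  }
  expect_error(
    segment_mask("four_segments", offset = 0.5, grid = g),
    "offset"
  )
  expect_error(segment_mask("half_space", offset = 1.5, grid = g), "offset")
})

test_that("segment masks respect their rotational symmetry", {
  # rotating the alternating patterns by one sector (90 deg four-segments,
  # 60 deg six-segments) swaps the 0 and pi phases -- a global pi offset
  # that leaves the focal intensity unchanged; pointwise equality returns
  # after two sectors
  for (kind in c("four_segments", "six_segments")) {
    sector <- if (kind == "four_segments") 90 else 60
    m0 <- segment_mask(kind, angle = 0, grid = test_grid)
    m1 <- segment_mask(kind, angle = sector, grid = test_grid)
    m2 <- segment_mask(kind, angle = 2 * sector, grid = test_grid)
    expect_equal(m1$values, pi - m0$values)
    expect_equal(m2$values, m0$values)
  }
})

test_that("half-space masks at opposite angles are complementary", {
  g <- test_grid
  a <- segment_mask("half_space", angle = 30, offset = 0.2, grid = g)
  b <- segment_mask("half_space", angle = 210, offset = -0.2, grid = g)
  rc <- stedsense:::rotated_coords(g, 30)
  off_border <- abs(rc$kx - 0.2) > 0.05 & g$aperture
  expect_equal(a$values[off_border], pi - b$values[off_border])
})

test_that("split bullseye is the circle-plus-split sum modulo 2 pi", {
  g <- pupil_grid(97, 512)
  sbe <- split_bullseye_mask(0, 0.6, g)
  expect_equal(mask_value_at(sbe, 0.02, 0.02), 0) # inside circle, kx >= 0
  expect_equal(mask_value_at(sbe, 0.7, 0), pi) # outside circle, kx >= 0
  expect_equal(mask_value_at(sbe, -0.3, 0), pi) # inside circle, kx < 0
  expect_true(all(sbe$values %in% c(0, pi)))
  circ <- ifelse(g$kx^2 + g$ky^2 <= 0.36, pi, 0)
  split <- segment_mask("half_space", grid = g)$values
  expect_equal(sbe$values, (circ + split) %% (2 * pi))
  expect_error(split_bullseye_mask(0, 1.2, g), "radius")
})

test_that("split bullseye degenerates to half-space patterns at extreme radii", {
  g <- test_grid
  hs0 <- segment_mask("half_space", angle = 0, grid = g)
  hs180 <- segment_mask("half_space", angle = 180, grid = g)
  inner <- g$rho < 0.99 & g$aperture
  # R -> 1: every aperture point is inside the circle -> complemented split
  big <- split_bullseye_mask(0, 0.999, g)
  expect_equal(big$values[inner], hs180$values[inner])
  # R -> 0: no sample inside the circle -> plain split
  small <- split_bullseye_mask(0, 0.001, g)
  expect_equal(small$values[g$aperture], hs0$values[g$aperture])
})

test_that("vortex and fork masks carry the helical phase and grating ramp", {
  g <- pupil_grid(97, 512)
  v <- vortex_fork_mask(0, g)
  expect_equal(mask_value_at(v, 0.9, 0), 0) # azimuth 0
  expect_equal(mask_value_at(v, 0, 0.9), pi / 2) # azimuth 90 deg
  # winding number of the wrapped phase around the axis is 1
  theta <- seq(0, 2 * pi, length.out = 101)[-101]
  ring <- vapply(
    theta,
    function(t) mask_value_at(v, 0.5 * cos(t), 0.5 * sin(t)),
    numeric(1)
  )
  d <- diff(c(ring, ring[1]))
  winding <- sum(((d + pi) %% (2 * pi)) - pi) / (2 * pi)
  expect_equal(winding, 1, tolerance = 1e-9)
  # fork: wrapped vortex plus linear ramp of tilt_cycles across the diameter
  f <- vortex_fork_mask(18, g)
  expected <- wrap_phase(g$phi + 18 * 2 * pi * (g$kx + 1) / 2)
  expect_equal(f$values, expected)
  unwrapped_span <- 18 * 2 * pi * ((1 + 1) / 2 - 0) # kx from -1 to +1
  expect_equal(unwrapped_span, 18 * 2 * pi)
  expect_error(vortex_fork_mask(-1, g), "tilt_cycles")
})

test_that("composed pupils have the specified Gaussian fill and phase", {
  g <- test_grid
  pf <- compose_pupil(g, beam_fwhm_fraction = 0.58)
  expect_true(all(pf$amplitude[!g$aperture] == 0))
  # intensity-FWHM: |A|^2 halves at rho = 0.29 (interpolated radial profile)
  rho <- as.vector(g$rho[g$aperture])
  amp2 <- as.vector(pf$amplitude[g$aperture])^2
  at <- function(r) {
    approx(rho[order(rho)], amp2[order(rho)], xout = r, ties = mean)$y
  }
  expect_equal(at(0.29) / at(min(rho)), 0.5, tolerance = 2e-2)
  # flat mask, no aberrations: phase identically zero
  expect_equal(pf$phase, matrix(0, 48, 48))
  expect_error(
    compose_pupil(g, polarization = c(1, 1)),
    "unit-norm"
  )
  expect_error(compose_pupil(g, beam_fwhm_fraction = 0), "beam_fwhm_fraction")
})

test_that("coma tilt compensation cancels the focal centroid shift", {
  shift_x <- function(ab) {
    psf <- simulate_psf(grid = test_grid, aberrations = ab)
    psf_centroid_shift(psf)[["dx"]]
  }
  expect_equal(coma_tilt_compensation(0, test_grid), 0)
  tilt <- coma_tilt_compensation(0.4 * pi, test_grid)
  expect_equal(
    coma_tilt_compensation(-0.4 * pi, test_grid), -tilt,
    tolerance = 1e-8
  )
  raw <- shift_x(zernike_spec("coma", 0.4 * pi, 0))
  compensated <- shift_x(list(
    zernike_spec("coma", 0.4 * pi, 0),
    zernike_spec("tilt", tilt, 0)
  ))
  expect_lt(abs(compensated), 0.1 * abs(raw))
})
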