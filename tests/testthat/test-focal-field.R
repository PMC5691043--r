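# FFT evaluation of the vectorial Debye integrals, focal sampling,
# intensity and the direct-quadrature oracle.

test_that("focal sampling step follows the padding formula", {
  # full-resolution setting: 24.8 nm at 766 nm, NA 1.45, 96/1024
  expect_equal(signif(focal_sampling(test_optics, 96, 1024), 3), 24.8)
  # no zero padding: lambda / (2 NA)
  expect_equal(
    focal_sampling(test_optics, 256, 256),
    test_optics$wavelength / (2 * test_optics$numerical_aperture)
  )
  # doubling the padded size halves the step
  expect_equal(
    focal_sampling(test_optics, 96, 2048),
    focal_sampling(test_optics, 96, 1024) / 2
  )
  # the reduced test grid keeps the same step as the full setting
  expect_equal(
    focal_sampling(test_optics, 48, 512),
    focal_sampling(test_optics, 96, 1024)
  )
})

test_that("an unaberrated circular-polarization pupil focuses to a
           symmetric on-axis peak", {
  psf <- simulate_psf(grid = test_grid)
  v <- psf$values
  c0 <- psf$center_index
  expect_equal(which(v == max(v), arr.ind = TRUE)[1, ], c(row = c0, col = c0))
  # rotational symmetry: compare the symmetric subgrid with its 90-degree
  # rotation (drop the first row/column so the center pixel is central)
  sym <- v[2:nrow(v), 2:ncol(v)]
  rot <- t(sym)[ncol(sym):1, ]
  expect_lt(max(abs(sym - rot)) / max(v), 1e-6)
})

test_that("focal energy equals weighted pupil energy", {
  for (mask in list(NULL, vortex_fork_mask(0, test_grid),
    segment_mask("four_segments", grid = test_grid))) {
    pf <- compose_pupil(test_grid, mask = mask)
    field <- propagate(pf, test_optics)
    focal_energy <- sum(intensity(field)$values) * field$step^2
    comp <- stedsense:::pupil_components(pf, test_optics)
    pupil_energy <- sum(Mod(comp$ex)^2 + Mod(comp$ey)^2 + Mod(comp$ez)^2) *
      (2 / test_grid$n_aperture)^2
    expect_equal(focal_energy, pupil_energy, tolerance = 1e-6)
  }
})

test_that("the half-space central residual is axially polarized", {
  pf <- compose_pupil(test_grid, mask = segment_mask("half_space",
    grid = test_grid
  ))
  field <- propagate(pf, test_optics)
  c0 <- field$center_index
  ez2 <- Mod(field$ez[c0, c0])^2
  et2 <- Mod(field$ex[c0, c0])^2 + Mod(field$ey[c0, c0])^2
  expect_gt(ez2, 0)
  expect_lt(et2, 1e-4 * ez2)
})

test_that("linear polarization parallel to the phase border removes the
           central residual", {
  mask <- segment_mask("half_space", grid = test_grid) # border along y
  circ <- central_of(mask)
  parallel <- central_of(mask, polarization = c(0, 1))
  expect_lt(parallel, 1e-4 * circ)
})

test_that("the matched-handedness vortex has a doughnut zero, the opposite
           handedness fills it", {
  mask <- vortex_fork_mask(0, test_grid)
  psf <- simulate_psf(grid = test_grid, mask = mask)
  ring_peak <- max(psf$values)
  expect_lt(central_intensity(psf), 1e-3 * ring_peak)
  filled <- simulate_psf(
    grid = test_grid, mask = mask,
    polarization = circular_polarization(-1)
  )
  expect_gt(central_intensity(filled), 0.1 * max(filled$values))
})

test_that("intensity handles normalization, zero fields and global phases", {
  pf <- compose_pupil(test_grid)
  field <- propagate(pf, test_optics)
  expect_equal(max(intensity(field, "peak")$values), 1)
  rotated <- field
  phase <- exp(1i * 0.7)
  rotated$ex <- field$ex * phase
  rotated$ey <- field$ey * phase
  rotated$ez <- field$ez * phase
  expect_equal(intensity(rotated)$values, intensity(field)$values)
  zero <- field
  zero$ex[] <- 0i
  zero$ey[] <- 0i
  zero$ez[] <- 0i
  expect_true(all(intensity(zero)$values == 0))
})

test_that("FFT fields agree with the direct Debye quadrature", {
  c0 <- floor(test_grid$n_fft / 2) + 1
  step <- focal_sampling(test_optics, 48, 512)
  # on-axis, flat pupil
  pf <- compose_pupil(test_grid)
  field <- propagate(pf, test_optics)
  oracle <- debye_quadrature_oracle(pf, test_optics, cbind(0, 0))
  expect_equal(field$ex[c0, c0], oracle$ex[1], tolerance = 1e-3)
  # five random mask/aberration settings, 3x3 focal patch
  withr::with_seed(42, {
    masks <- list(
      segment_mask("four_segments", grid = test_grid),
      split_bullseye_mask(30, 0.6, test_grid),
      vortex_fork_mask(0, test_grid),
      segment_mask("half_space", offset = 0.3, grid = test_grid),
      segment_mask("six_segments", angle = 15, grid = test_grid)
    )
    for (m in masks) {
      ab <- zernike_spec(
        sample(c("astigmatism", "coma", "trefoil"), 1),
        runif(1, 0.1, 0.6) * pi, runif(1, 0, 180)
      )
      pf <- compose_pupil(test_grid, mask = m, aberrations = ab)
      field <- propagate(pf, test_optics)
      offs <- expand.grid(dx = -1:1, dy = -1:1)
      pts <- cbind(offs$dx * step, offs$dy * step)
      oracle <- debye_quadrature_oracle(pf, test_optics, pts)
      fft_vals <- mapply(
        function(dx, dy) field$ex[c0 + dx, c0 + dy],
        offs$dx, offs$dy
      )
      scale <- max(Mod(oracle$ex))
      expect_lt(max(Mod(fft_vals - oracle$ex)) / scale, 1e-3)
    }
  })
})

test_that("a pure tilt translates the focus by the Fourier-shift amount", {
  a <- 0.3 * pi # PV tilt; phase a/2 * kx -> shift a * lambda / (4 pi NA)
  shift <- a * test_optics$wavelength /
    (4 * pi * test_optics$numerical_aperture)
  plain <- compose_pupil(test_grid)
  tilted <- compose_pupil(test_grid,
    aberrations = zernike_spec("tilt", a, 0)
  )
  at_origin <- debye_quadrature_oracle(plain, test_optics, cbind(0, 0))
  # the tilt translates the field by `shift`, so the tilted field at -shift
  # equals the untilted field at the origin
  at_shift <- debye_quadrature_oracle(tilted, test_optics, cbind(-shift, 0))
  expect_equal(Mod(at_shift$ex[1]), Mod(at_origin$ex[1]), tolerance = 1e-9)
  expect_equal(Mod(at_shift$ez[1]), Mod(at_origin$ez[1]), tolerance = 1e-9)
})

test_that("the quadrature oracle is linear in the pupil field", {
  pf1 <- compose_pupil(test_grid)
  pf2 <- compose_pupil(test_grid, mask = vortex_fork_mask(0, test_grid))
  combined <- pf1
  csum <- pf1$amplitude * exp(1i * pf1$phase) +
    pf2$amplitude * exp(1i * pf2$phase)
  combined$amplitude <- Mod(csum)
  combined$phase <- Arg(csum)
  pts <- cbind(c(0, 30), c(0, -20))
  o1 <- debye_quadrature_oracle(pf1, test_optics, pts)
  o2 <- debye_quadrature_oracle(pf2, test_optics, pts)
  o12 <- debye_quadrature_oracle(combined, test_optics, pts)
  expect_equal(o12$ex, o1$ex + o2$ex, tolerance = 1e-9)
  expect_equal(o12$ez, o1$ez + o2$ez, tolerance = 1e-9)
})

test_that("the axial intensity share vanishes at low NA", {
  low_na <- optics_config(766, 0.3, 1.5)
  for (mask in list(NULL, segment_mask("half_space", grid = test_grid),
    vortex_fork_mask(0, test_grid))) {
    pf <- compose_pupil(test_grid, mask = mask)
    field <- propagate(pf, low_na)
    ez_share <- sum(Mod(field$ez)^2) /
      sum(Mod(field$ex)^2 + Mod(field$ey)^2 + Mod(field$ez)^2)
    expect_lt(ez_share, 0.01)
  }
})

test_that("propagate rejects mismatched pupil/grid shapes", {
  pf <- compose_pupil(test_grid)
  pf$amplitude <- pf$amplitude[1:10, 1:10]
  expect_error(propagate(pf, test_optics))
})
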