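# stedsense

Binary phase masks for aligning and aberration-testing SLM-based STED
microscopes — simulation, sensing protocol and resolution analysis in R.

A STED microscope needs a depletion focus with a true central intensity
zero. When the beam is shaped by a spatial light modulator (SLM), lateral
pattern misalignment and low-order aberrations (astigmatism, coma, trefoil)
both deform the "doughnut" in confusingly similar ways. `stedsense`
implements binary (0/π) phase masks whose focal patterns each respond
selectively to one disturbance, so that misalignment and individual
aberration modes can be read off a single scalar — the central intensity of
the point-spread function (PSF), measured in practice on an isolated
scatterer ("guide star") with the confocal point detector.

The package is aimed at microscope builders and optics modellers. It
provides:

* a **vectorial focal-field simulator** (Richards–Wolf / Debye theory, high
  NA, arbitrary polarization) evaluated by zero-padded 2D FFT, with an
  independent direct-quadrature oracle pinning the numerics;
* **mask generators**: half-space, four-segments, six-segments,
  split-bullseye, vortex/fork, plus PV-normalized Zernike aberrations;
* **sensing scans** (displacement, rotation, bias-amplitude) and a
  **closed-loop modal sensing protocol** (`modal_sense()`) that estimates
  orientation and amplitude of astigmatism, trefoil and coma and corrects
  them;
* **STED metrics**: doughnut quality, 2D-Lorentzian spot fits of bead
  images, and the resolution-law fit
  `FWHM(P) = FWHM_confocal (1 + P/P_sat)^(-1/2)`, with broom-style
  `tidy()`/`glance()` and ggplot2 `autoplot()` methods;
* **I/O and CLI**: 8-bit SLM bitmaps (PNG), float TIFF PSF images, CSV
  scans, JSON reports, YAML scene configs, and a small command-line tool
  (`inst/scripts/stedsense.R`).

The model and its numerical conventions are documented in the methods
vignette, `vignettes/phase-mask-sensing.Rmd`.

## Worked example

Simulate an astigmatism-degraded STED doughnut, then run the closed-loop
sensing protocol against the same aberration:

```r
library(stedsense)

g <- grid_preset("reduced")      # 48 samples / 512-point FFT, 24.8 nm pixels
psf <- simulate_psf(grid = g, mask = vortex_fork_mask(0, g),
                    aberrations = zernike_spec("astigmatism", 0.4 * pi, 30))
m <- doughnut_metrics(psf)
sprintf("central/crest %.3f, uniformity %.2f", m$central_to_crest, m$uniformity)
#> "central/crest 0.006, uniformity 0.67"

report <- modal_sense(zernike_spec("astigmatism", 0.4 * pi, 30), grid = g)
report
#> <sensing_report>
#>   doughnut central/crest: 0.0058 -> 0.0000
#> # A tibble: 3 × 8
#>   mode  sensor orientation amplitude correction_amplitude correction_orientation
#> 1 asti… four_…        30.1      1.26                -1.26                   30.1
#> 2 tref… six_s…        NA        0                    0                      NA
#> 3 coma  split…        NA        0                    0                      NA
```

Reading the report: the four-segments sensor located the astigmatism at
30.1° (injected: 30°) with PV amplitude 1.26 rad (injected: 0.4π ≈ 1.257),
and applied the negative as a correction; trefoil and coma scans showed no
modulation above the detection floor and were skipped. The doughnut's
central-to-crest intensity ratio drops from 0.6% to ~1e-7 and its crest
uniformity recovers from 0.67 to 0.99 (`glance(report)`).

Scans are tibbles and plot directly:

```r
sc <- rotation_scan("four_segments",
                    aberrations = zernike_spec("astigmatism", 0.4 * pi, 0),
                    grid = g)
autoplot(sc)
extremum_fit(sc, objective = "max")   # least-squares refined orientation
```

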