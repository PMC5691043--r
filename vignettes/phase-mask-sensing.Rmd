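---
title: "Binary phase masks for SLM-STED alignment and modal aberration sensing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary phase masks for SLM-STED alignment and modal aberration sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stedsense)
```

## The problem

A STED microscope depletes fluorescence with a shaped high-intensity beam
whose focus must contain a true intensity zero (the "doughnut"). When the
beam is shaped by a liquid-crystal spatial light modulator (SLM), two things
routinely degrade that zero: lateral misalignment between the displayed
phase pattern and the beam, and low-order wavefront aberrations
(astigmatism, coma, trefoil) from imperfect optics. Both deform the doughnut
in visually similar ways, which makes tuning by doughnut inspection
error-prone.

`stedsense` implements a family of *binary* (0/π) phase masks whose focal
intensity patterns respond selectively to one disturbance each, together
with the vectorial focal-field simulator needed to study them, the
central-intensity scans and closed-loop modal sensing protocol built on
them, and the downstream STED resolution analysis (2D-Lorentzian spot fits
and the inverse-square-root resolution law).

## Focal-field model

Fields are computed with the vectorial diffraction theory of Richards and
Wolf for an aplanatic, index-matched objective (default: wavelength 766 nm,
NA 1.45, n = 1.5), evaluated on the focal plane only. The pupil function is

* a Gaussian beam amplitude `exp(-(kx² + ky²)/w²)` truncated by the open
  aperture `kx² + ky² < 1`, with the beam size given as the *intensity*-FWHM
  diameter as a fraction of the aperture diameter (default 0.58, so
  `w = 0.29/sqrt(ln 2 / 2)` in pupil-radius units);
* a phase `Σ aⱼ Zⱼ + φ_mask`, with Zernike amplitudes quoted as
  peak-to-valley (PV) radians over the unit disk;
* a transverse polarization state, by default circular `(1, i)/√2`.

Each pupil sample is rotated into the radial/azimuthal basis of the focal
sphere (the radial component bends by the focusing angle θ and acquires the
axial field `E_z`), weighted by `cos θ^(-1/2)` — the aplanatic `√cos θ`
apodization times the solid-angle-to-`(kx, ky)` Jacobian `1/cos θ` — and
transformed to the focal plane by a zero-padded 2D FFT. The exact
apodization bookkeeping is pinned not by convention but by an independent
*direct-quadrature oracle* (`debye_quadrature_oracle()`) that evaluates the
same integrand by explicit summation; the test suite requires agreement at
the 1e-3 relative level on focal patches (observed: ~1e-14).

The circular handedness `(1, i)/√2` is the one matched to the charge-1
vortex: with it the helical phase cancels the geometric polarization phase
on axis and the doughnut zero survives high-NA focusing (central intensity
below 1e-3 of the crest; the opposite handedness fills the zero with
axially polarized light and is available via
`circular_polarization(-1)`).

### Sampling

`pupil_grid(n_aperture, n_fft)` places `n_aperture` equidistant samples
across the aperture diameter and pads to `n_fft` FFT points, giving a focal
pixel pitch `step = n_aperture·λ/(n_fft·2·NA)` — 24.8 nm for the
full-resolution 96/1024 setting. Samples sit symmetrically about the pupil
center, `k_j = (j − (n−1)/2)·(2/n)`: for even `n` this is half a pixel off
the FFT lattice, so **no sample falls on the kx = 0 / ky = 0 lines where
the binary masks step by π**. This matters: with samples on the borders,
the border rows carry full pixel weight and produce a spurious
central-intensity background of order 1% of the Airy peak — larger than
real sensing signals. The half-pixel offset is compensated by an analytic
phase ramp after the FFT, so the complex fields still equal the direct
quadrature at the grid points; the optical-axis pixel stays at index
`floor(n_fft/2)`. Two presets are used throughout: `"full"` (96/1024) for
headline numbers and `"reduced"` (48/512, same 24.8 nm step, quarter cost)
for tests and interactive work.

## Masks and aberration modes

The masks follow their printed set definitions exactly, evaluated
analytically at each sample (no raster rotation or interpolation, so
π-steps stay sharp; border samples take the value of the `≥` branch):
`half_space` (π for kx ≥ 0, displaceable along the border normal),
`four_segments` (π where kx·ky ≥ 0), `six_segments` (alternating 60°
sectors), `split_bullseye` (circle of radius R, default 0.6 for the 0.58
Gaussian fill, plus half-space, mod 2π), and the vortex with optional
blazed grating ("fork", `tilt_cycles` full cycles across the pupil
diameter; sensing computations always use `tilt_cycles = 0` since the
grating only separates diffraction orders on the real instrument). Note a
small but deliberate geometric fact encoded in the tests: rotating the
four- or six-segment pattern by *one* sector (90°/60°) yields the pointwise
complement — a global π offset with identical focal intensity — and
pointwise equality returns after two sectors.

Zernike modes are PV-normalized so "0.4π rad" means `max − min = 0.4π` over
the unit disk. Orientation is a separate parameter with a deliberate,
*sensor-aligned* reference: the 0°-oriented form of each azimuthal mode
(astigmatism `ρ² sin 2φ`, trefoil `ρ³ sin 3φ`, coma `−(3ρ³ − 2ρ) cos φ`) is
chosen so that the matching sensing mask at rotation angle θ produces its
maximal central-intensity signal when the mode sits at orientation θ. This
mirrors how the protocol is actually used — the compensating mode is
applied *at the mask angle of maximal signal* — and makes orientation
read-outs directly comparable to mask angles. Orientations are reported in
each mode's fundamental domain (astigmatism [0°, 180°), trefoil [0°, 120°),
coma [0°, 360°)).

## Sensing scans and the closed loop

All sensing uses a single scalar: the intensity at the optical-axis pixel.
The scans compute it directly from the zero-frequency component of the
weighted pupil — identical by construction to the center pixel of the full
FFT propagation (asserted in the tests) and orders of magnitude cheaper,
which is what makes dense scan grids and the closed loop fast.

* `displacement_scan()` sweeps the half-space border across the beam; the
  minimum locates the beam center on the SLM, robustly against 0.4π-level
  low-order aberrations.
* `rotation_scan()` rotates a sensing mask; under a matching-symmetry
  aberration the signal is maximal at the mode orientation. Cross
  sensitivities are small (four-segments: coma and trefoil modulations are
  ~3% and ~0.1% of the astigmatism modulation at equal 0.4π bias); the
  six-segments astigmatism cross-talk is an axial-polarization effect and
  drops by more than an order of magnitude from NA 1.45 to NA 0.5.
* `amplitude_scan()` varies a compensating bias at fixed orientation; the
  minimum is the negative of the system amplitude.
* `extremum_fit()` refines scan extrema with a least-squares quadratic
  through the points bracketing the best readout (the
  "three measurements per degree of freedom" shortcut), with wrap-around
  handling on full-period rotation scans; monotone scans are flagged and
  the endpoint returned.

`modal_sense()` chains these: displacement centering in x and y, then per
mode *astigmatism → trefoil → coma* (astigmatism first, so the
six-segments sensor sees an astigmatism-corrected wavefront), a rotation
scan (default: the mask period in 10 steps) and an amplitude scan (default:
11 steps over ±0.8π) whose fitted minimum becomes the accumulated
correction. One iteration is the default; a second can be run by feeding
the corrected state back in, but is not needed at the study conditions.

Two numerical choices deserve note. First, the *signal floor*: a mode is
declared absent (and its amplitude scan skipped) when the rotation-scan
modulation is below `2e-4` of the unmodulated Airy peak. The floor sits
between the discretization-level modulation of an aberration-free
wavefront (2e-5…6e-5 of the peak on the 48-sample grid) and the weakest
in-scope signal (trefoil at 0.2π PV, ~8e-4), with ~3–4× margin to both;
it is configurable in `sense_config()`. Second, the sign ambiguity of the
segmented sensors (period = half the mode period for astigmatism/trefoil)
is resolved by the amplitude scan: a positive fitted compensation simply
means the aberration sits half a mode-period away, and the estimate is
folded accordingly.

At the full-resolution setting, injecting {0.4π astigmatism @ 30°, 0.3π
coma @ 100°, 0.2π trefoil @ 40°} is recovered to ≲1% in amplitude and a
few degrees in orientation, and the corrected vortex doughnut has a
central-to-crest ratio of ~1e-5 with crest uniformity ~0.99 (computed by
`doughnut_metrics()`: crest located on the azimuthally averaged radial
profile, uniformity = min/max around the crest ring).

## STED resolution analysis and synthetic data

`lorentzian2d_fit()` fits `A/(1 + r²/γ²) + b` to single spots
(FWHM = 2γ·step) and can exclude peaks outside a configurable intensity
interval (default [0.3, 1.5]× a reference peak) — the cluster-rejection
rule for bead images; diverged fits are flagged rather than averaged.
`resolution_law_fit()` fits `FWHM(P) = FWHM_confocal·(1 + P/P_sat)^(-1/2)`
by nonlinear least squares and has `tidy()`/`glance()`/`autoplot()`
methods.

The synthetic-data generator (`simulate_bead_scan()`) emulates a confocal
scan of an isolated bead: expected image = intensity PSF ⊗ uniform disk of
the bead diameter (sub-pixel area-weighted kernel), scaled to a photon
budget at the brightest pixel, with Poisson shot noise under a fixed seed.
It deliberately does **not** model depletion photophysics (effective STED
spots are generated directly from the resolution law as Lorentzian
profiles via `synthetic_sted_psf()`), coherent scattering of the gold
guide star, detector afterpulsing, drift, or background — so passing the
end-to-end check demonstrates self-consistency of the
generate–measure–refit pipeline (P_sat recovered within ~5% at the default
conditions: widths from the law with FWHM_confocal = 250 nm and
P_sat = 1.2 mW at powers {0, 5, 15, 35} mW, 8 beads of 20 nm per power,
10 nm scan pixels, 3e4 peak counts), not agreement with any instrument.
The small systematic excess of the recovered P_sat (~4%) is the expected
bead-size broadening of the narrowest spots.

## Known limitations

* **Focal plane only.** No axial stacks; the circular-mask "bottle" beam
  is generated but only its focal cross-section is analyzed.
* **Centroid-based shift suppression is not reproducible.** For any binary
  0/π mask the pupil is a signed real amplitude, and the intensity-centroid
  identity `<x> ∝ ∫A² ∂φ/∂kx` makes the *full-field* first-moment shift
  under a coma bias exactly mask-independent in the continuum — simulations
  at both grid presets give a split-bullseye-to-plain slope ratio of
  0.93–0.96, and local pattern measures (thresholded or intensity-weighted
  centroids, cross-correlation, valley-fit) behave no better. The package
  therefore reports the honest first-moment shift (`psf_centroid_shift()`,
  optionally windowed); the practical benefit of the split-bullseye sensor
  — a broad, flat central valley whose axis readout stays valid while
  biasing coma, making tilt compensation unnecessary during sensing — does
  not rest on centroid suppression. The built-in
  `coma_tilt_compensation()` calibrates the compensating tilt by
  simulation where it is needed (plain-pupil work).
* **Low-order modes only.** Sensors exist for astigmatism, coma and
  trefoil; higher-order or combined complex wavefronts are out of scope,
  as is any greyscale (non-binary) sensing mask.
* **Linear SLM response.** The phase-to-grey lookup (`slm_lut()`) assumes
  the 0–2π range maps linearly onto grey 0–255 (grey = ⌊phase/2π·256⌋,
  capped at 255); instrument-specific gamma tables can be swapped in.
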