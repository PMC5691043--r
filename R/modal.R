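# Closed-loop modal wavefront sensing with binary masks: displacement
# centering with the half-space mask, then per mode (astigmatism -> trefoil
# -> coma, so that the six-segments sensor sees an astigmatism-corrected
# wavefront) a rotation scan locating the orientation of maximal signal and
# a bias-amplitude scan locating the compensating amplitude. One iteration
# by default.

sensor_for_mode <- function(mode) {
  switch(mode,
    astigmatism = "four_segments",
    trefoil = "six_segments",
    coma = "split_bullseye",
    abort(sprintf("No sensing mask is defined for mode '%s'.", mode))
  )
}

#' Configuration of the modal sensing protocol
#'
#' @param modes Modes to sense, in order. The default order corrects
#'   astigmatism before applying the six-segments trefoil sensor (whose
#'   astigmatism cross-sensitivity at high NA would otherwise bias it).
#' @param n_rotation Number of mask angles per rotation scan (the mask's
#'   symmetry period divided into `n_rotation` steps).
#' @param n_amplitude Number of bias amplitudes per amplitude scan.
#' @param amplitude_range Half-range of the bias-amplitude scan, radians PV.
#' @param n_displacement Number of offsets per half-space centering scan.
#' @param signal_floor Minimum rotation-scan modulation (max - min), as a
#'   fraction of the unmodulated flat-mask central peak, required to proceed
#'   to the amplitude scan. Below it the mode is reported aberration-free
#'   and skipped.
#' @param radius Split-bullseye radius.
#' @param fit_points Points used by [extremum_fit()].
#' @return A list of protocol settings.
#' @export
sense_config <- function(modes = c("astigmatism", "trefoil", "coma"),
                         n_rotation = 10, n_amplitude = 11,
                         amplitude_range = 0.8 * pi,
                         n_displacement = 11,
                         signal_floor = 2e-4, radius = 0.6,
                         fit_points = 3) {
  list(
    modes = modes, n_rotation = n_rotation, n_amplitude = n_amplitude,
    amplitude_range = amplitude_range, n_displacement = n_displacement,
    signal_floor = signal_floor, radius = radius, fit_points = fit_points
  )
}

#' Closed-loop modal wavefront sensing
#'
#' Runs the full stepwise sensing/correction protocol against a (simulated)
#' system aberration: half-space displacement centering in x and y, then for
#' each configured mode a rotation scan of its sensing mask (orientation =
#' angle of maximal signal, refined by least-squares) followed by a
#' bias-amplitude scan at that orientation (correction = amplitude of
#' minimal signal). Corrections accumulate, so later sensors see the
#' already-corrected wavefront. Doughnut quality metrics of the vortex PSF
#' are recorded before and after correction.
#'
#' @param system_aberration [zernike_spec()] or list: the aberration to be
#'   sensed.
#' @param config A [sense_config()].
#' @param grid,optics,beam_fwhm_fraction,polarization Simulation setting.
#' @return A `sensing_report`: list with `estimates` (tibble: mode,
#'   orientation, amplitude, correction amplitude/orientation, modulation,
#'   skipped), `corrections` (list of [zernike_spec()]), `displacement`
#'   (tibble), `doughnut_before`, `doughnut_after` and the scans.
#' @export
modal_sense <- function(system_aberration = NULL, config = sense_config(),
                        grid = grid_preset(), optics = optics_config(),
                        beam_fwhm_fraction = 0.58,
                        polarization = circular_polarization()) {
  system_aberration <- as_aberration_list(system_aberration)
  sim <- list(
    grid = grid, optics = optics,
    beam_fwhm_fraction = beam_fwhm_fraction, polarization = polarization
  )
  # reference level for the detectability floor
  peak_unmod <- central_intensity_direct(
    compose_pupil(grid,
      beam_fwhm_fraction = beam_fwhm_fraction,
      polarization = polarization
    ),
    optics
  )
  floor_abs <- config$signal_floor * peak_unmod

  # 1) displacement centering (half-space x and y)
  offsets <- seq(-1, 1, length.out = config$n_displacement)
  displacement <- purrr::map_dfr(c("x", "y"), function(ax) {
    sc <- displacement_scan(ax,
      offsets = offsets, aberrations = system_aberration,
      grid = grid, optics = optics,
      beam_fwhm_fraction = beam_fwhm_fraction, polarization = polarization
    )
    ex <- extremum_fit(sc, config$fit_points, "min")
    tibble(
      axis = ax, offset = ex$location, value = ex$value,
      flagged = ex$flagged
    )
  })

  corrections <- list()
  scans <- list()
  rows <- list()
  for (mode in config$modes) {
    kind <- sensor_for_mode(mode)
    period_mask <- mask_period(kind)
    period_mode <- .zernike_modes[[mode]]$period
    angles <- seq(0, period_mask, length.out = config$n_rotation + 1)
    angles <- angles[-length(angles)]
    current <- c(system_aberration, corrections)
    rot <- rotation_scan(kind,
      angles = angles, aberrations = current,
      radius = config$radius, grid = grid, optics = optics,
      beam_fwhm_fraction = beam_fwhm_fraction, polarization = polarization
    )
    scans[[paste0(mode, "_rotation")]] <- rot
    modulation <- diff(range(rot$central_intensity))
    if (modulation < floor_abs) {
      rows[[mode]] <- tibble(
        mode = mode, sensor = kind,
        orientation = NA_real_, amplitude = 0,
        correction_amplitude = 0, correction_orientation = NA_real_,
        modulation = modulation, skipped = TRUE
      )
      next
    }
    ori <- extremum_fit(rot, config$fit_points, "max")$location %% period_mask
    amps <- seq(-config$amplitude_range, config$amplitude_range,
      length.out = config$n_amplitude
    )
    amp_scan <- amplitude_scan(kind, ori,
      mode = zernike_spec(mode, 0, ori),
      amplitudes = amps, system_aberration = current,
      radius = config$radius, grid = grid, optics = optics,
      beam_fwhm_fraction = beam_fwhm_fraction, polarization = polarization
    )
    scans[[paste0(mode, "_amplitude")]] <- amp_scan
    corr_amp <- extremum_fit(amp_scan, config$fit_points, "min")$location
    corrections <- c(corrections, list(zernike_spec(mode, corr_amp, ori)))
    # estimated aberration = minus the correction, reported with positive
    # amplitude in the mode's fundamental orientation domain
    est_amp <- -corr_amp
    est_ori <- ori
    if (est_amp < 0) {
      est_amp <- -est_amp
      est_ori <- est_ori + period_mode / 2
    }
    est_ori <- est_ori %% period_mode
    rows[[mode]] <- tibble(
      mode = mode, sensor = kind,
      orientation = est_ori, amplitude = est_amp,
      correction_amplitude = corr_amp, correction_orientation = ori,
      modulation = modulation, skipped = FALSE
    )
  }

  doughnut_psf <- function(ab) {
    simulate_psf(
      grid = grid, mask = vortex_fork_mask(0, grid), aberrations = ab,
      optics = optics, beam_fwhm_fraction = beam_fwhm_fraction,
      polarization = polarization
    )
  }
  before <- doughnut_metrics(doughnut_psf(system_aberration))
  after <- doughnut_metrics(doughnut_psf(c(system_aberration, corrections)))

  structure(
    list(
      estimates = dplyr::bind_rows(rows),
      corrections = corrections,
      displacement = displacement,
      doughnut_before = before,
      doughnut_after = after,
      scans = scans,
      config = config
    ),
    class = "sensing_report"
  )
}

#' @export
print.sensing_report <- function(x, ...) {
  cat("<sensing_report>\n")
  cat(sprintf(
    "  doughnut central/crest: %.4f -> %.4f\n",
    x$doughnut_before$central_to_crest, x$doughnut_after$central_to_crest
  ))
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.sensing_report <- function(x, ...) x$estimates

#' @export
glance.sensing_report <- function(x, ...) {
  tibble(
    n_modes = nrow(x$estimates),
    n_corrected = sum(!x$estimates$skipped),
    central_to_crest_before = x$doughnut_before$central_to_crest,
    central_to_crest_after = x$doughnut_after$central_to_crest,
    uniformity_before = x$doughnut_before$uniformity,
    uniformity_after = x$doughnut_after$uniformity
  )
}
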