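# Writers for SLM bitmaps (8-bit PNG), PSF images (32-bit float grayscale
# TIFF with pixel-size metadata), scan tables (CSV) and sensing reports
# (JSON), plus a plain-text (YAML) configuration reader.

#' SLM lookup table and display geometry
#'
#' A linear phase-to-grey lookup: `grey = floor(phase / (2 pi) * 256)`,
#' capped at 255, mapping the calibrated 0 to 2 pi phase response onto video
#' grey levels 0-255. Display geometry defaults to a 1920 x 1080 panel with
#' 8 um pixel pitch.
#'
#' @param width,height Display size in pixels.
#' @param pitch_um Pixel pitch in micrometres.
#' @return An `slm_lut` object with a `grey(phase)` mapping function.
#' @examples
#' lut <- slm_lut()
#' lut$grey(c(0, pi, 2 * pi - 1e-9)) # 0, 128, 255
#' @export
slm_lut <- function(width = 1920L, height = 1080L, pitch_um = 8) {
  structure(
    list(
      width = as.integer(width), height = as.integer(height),
      pitch_um = pitch_um,
      grey = function(phase) {
        pmin(floor(wrap_phase(phase) / (2 * pi) * 256), 255)
      }
    ),
    class = "slm_lut"
  )
}

#' Render a phase mask as an SLM bitmap
#'
#' Maps the mask phase (wrapped to `[0, 2 pi)`) to 8-bit grey levels via the
#' LUT and places the mask's aperture grid on the display canvas centered at
#' the given display pixel; alignment in single-pixel steps supports the
#' displacement-scan centering. Pixels outside the mask grid are grey 0.
#'
#' @param mask A `phase_mask`.
#' @param lut An [slm_lut()].
#' @param center Integer display pixel `(col, row)` at which to center the
#'   mask (defaults to the display center).
#' @return Integer matrix (`height` x `width`) of grey levels 0-255.
#' @export
render_mask_bitmap <- function(mask, lut = slm_lut(), center = NULL) {
  stopifnot(inherits(mask, "phase_mask"), inherits(lut, "slm_lut"))
  if (is.null(center)) {
    center <- c(floor(lut$width / 2) + 1L, floor(lut$height / 2) + 1L)
  }
  if (center[1] < 1 || center[1] > lut$width ||
    center[2] < 1 || center[2] > lut$height) {
    abort("`center` lies outside the display.")
  }
  grey <- lut$grey(mask$values)
  n <- mask$grid$n_aperture
  canvas <- matrix(0L, lut$height, lut$width)
  # mask rows index x (columns of the display), mask cols index y (rows)
  col0 <- center[1] - floor(n / 2)
  row0 <- center[2] - floor(n / 2)
  cols <- col0:(col0 + n - 1)
  rows <- row0:(row0 + n - 1)
  if (min(cols) < 1 || max(cols) > lut$width ||
    min(rows) < 1 || max(rows) > lut$height) {
    abort("Mask does not fit on the display at this center offset.")
  }
  canvas[rows, cols] <- t(grey)[seq_len(n), seq_len(n)]
  storage.mode(canvas) <- "integer"
  canvas
}

#' Write an SLM bitmap as 8-bit grayscale PNG
#'
#' @param bitmap Integer grey-level matrix from [render_mask_bitmap()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(bitmap, path) {
  png::writePNG(bitmap / 255, target = path)
  invisible(path)
}

#' Write an intensity PSF as grayscale TIFF
#'
#' 32-bit float single-plane TIFF of the peak-scaled values (TIFF floats are
#' stored in `[0, 1]`), with a JSON sidecar `<path>.json` recording the
#' pixel size (nm), the peak scale factor and the intensity scale so the
#' absolute values round-trip. `scale = "log"` stores
#' `log10` of the peak-normalized intensity mapped from `[log10(floor), 0]`
#' onto `[0, 1]` -- the logarithmic display used for sensing PSFs.
#'
#' @param psf An `intensity_psf`.
#' @param path Output path.
#' @param scale `"linear"` or `"log"`.
#' @param log_floor Relative floor applied before taking log10.
#' @return The path, invisibly.
#' @export
write_psf_image <- function(psf, path, scale = c("linear", "log"),
                            log_floor = 1e-8) {
  stopifnot(inherits(psf, "intensity_psf"))
  scale <- match.arg(scale)
  v <- psf$values
  if (any(v < 0)) abort("Intensity values must be nonnegative.")
  peak <- max(v)
  if (scale == "log") {
    rel <- if (peak > 0) v / peak else v
    lg <- log10(pmax(rel, log_floor))
    stored <- 1 - lg / log10(log_floor) # [0, 1], 1 = peak
  } else {
    stored <- if (peak > 0) v / peak else v
  }
  tiff::writeTIFF(stored,
    where = path, bits.per.sample = 32L,
    reduce = FALSE, compression = "none"
  )
  jsonlite::write_json(
    list(
      schema = "stedsense/psf_image/1", step_nm = psf$step,
      peak = peak, scale = scale, log_floor = log_floor,
      normalization = psf$normalization
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a PSF TIFF written by [write_psf_image()]
#'
#' Restores absolute linear intensities (including from log-scaled files)
#' using the JSON sidecar; without a sidecar the raw stored values are
#' returned with unknown pixel size.
#'
#' @param path File path.
#' @return An `intensity_psf`.
#' @export
read_psf_image <- function(path) {
  img <- unclass(tiff::readTIFF(path))
  meta_path <- paste0(path, ".json")
  step <- NA_real_
  normalization <- "raw"
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    step <- meta$step_nm
    normalization <- meta$normalization %||% "raw"
    if (identical(meta$scale, "log")) {
      img <- 10^((img - 1) * -log10(meta$log_floor)) * meta$peak
    } else {
      img <- img * meta$peak
    }
  }
  structure(
    list(
      values = img, step = step,
      center_index = floor(nrow(img) / 2) + 1L, normalization = normalization
    ),
    class = "intensity_psf"
  )
}

#' Write a sensing scan as CSV
#'
#' Columns: `parameter` (name), `value`, `central_intensity`.
#'
#' @param scan A `sted_scan` tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "sted_scan"))
  out <- data.frame(
    parameter = attr(scan, "parameter"),
    value = scan[[1]],
    central_intensity = scan$central_intensity
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a sensing report as JSON
#'
#' @param report A `sensing_report` from [modal_sense()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sensing_report <- function(report, path) {
  stopifnot(inherits(report, "sensing_report"))
  payload <- list(
    schema = "stedsense/sensing_report/1",
    estimates = report$estimates,
    displacement = report$displacement,
    corrections = lapply(
      report$corrections,
      function(z) list(mode = z$mode, amplitude = z$amplitude,
        orientation = z$orientation)
    ),
    doughnut_before = report$doughnut_before,
    doughnut_after = report$doughnut_after
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE
  )
  invisible(path)
}

#' Read a plain-text (YAML) mask/optics configuration
#'
#' Recognized keys: `optics` (wavelength, numerical_aperture,
#' refractive_index), `grid` (n_aperture, n_fft or preset), `beam`
#' (fwhm_fraction), `mask` (kind, angle_deg, offset, radius, tilt_cycles)
#' and `modes` (list of mode, amplitude_pi, orientation_deg).
#'
#' @param path YAML file path.
#' @return List with `optics`, `grid`, `beam_fwhm_fraction`, `mask`
#'   (a `phase_mask`) and `aberrations` (list of [zernike_spec()]).
#' @export
read_scene_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  grid <- if (!is.null(cfg$grid$preset)) {
    grid_preset(cfg$grid$preset)
  } else if (!is.null(cfg$grid)) {
    pupil_grid(cfg$grid$n_aperture %||% 96L, cfg$grid$n_fft %||% 1024L)
  } else {
    grid_preset()
  }
  optics <- if (!is.null(cfg$optics)) {
    optics_config(
      cfg$optics$wavelength %||% 766,
      cfg$optics$numerical_aperture %||% 1.45,
      cfg$optics$refractive_index %||% 1.5
    )
  } else {
    optics_config()
  }
  mask <- if (!is.null(cfg$mask)) {
    kind <- cfg$mask$kind
    switch(kind,
      flat = flat_mask(grid),
      vortex = ,
      fork = vortex_fork_mask(cfg$mask$tilt_cycles %||% 0, grid),
      split_bullseye = split_bullseye_mask(
        cfg$mask$angle_deg %||% 0, cfg$mask$radius %||% 0.6, grid
      ),
      segment_mask(kind, cfg$mask$angle_deg %||% 0,
        cfg$mask$offset %||% 0,
        grid = grid
      )
    )
  } else {
    flat_mask(grid)
  }
  aberrations <- lapply(cfg$modes, function(m) {
    zernike_spec(m$mode, (m$amplitude_pi %||% 0) * pi, m$orientation_deg %||% 0)
  })
  list(
    optics = optics, grid = grid,
    beam_fwhm_fraction = cfg$beam$fwhm_fraction %||% 0.58,
    mask = mask, aberrations = aberrations
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
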