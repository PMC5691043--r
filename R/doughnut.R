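#' Doughnut quality metrics
#'
#' Quantifies the quality of a doughnut-shaped PSF (vortex mask): the crest
#' is located as the radius maximizing the azimuthal mean intensity; the
#' reported metrics are the ratio of the central (optical-axis) intensity to
#' the crest intensity, the min/max uniformity of the intensity around the
#' crest ring, and the crest radius in nm. A PSF without annular structure
#' (azimuthal-mean maximum at the axis) is flagged.
#'
#' @param psf An `intensity_psf`.
#' @param n_theta Number of azimuthal samples on the crest ring.
#' @return List with `central_to_crest`, `uniformity`, `crest_radius_nm`,
#'   `crest_intensity`, `flagged`.
#' @export
doughnut_metrics <- function(psf, n_theta = 360) {
  stopifnot(inherits(psf, "intensity_psf"))
  v <- psf$values
  n <- nrow(v)
  c0 <- psf$center_index
  x <- (1:n) - c0
  # radial profile by integer-radius binning
  R <- sqrt(outer(x^2, x^2, "+"))
  rbin <- round(R)
  rmax <- floor(n / 2) - 2
  keep <- rbin <= rmax
  prof <- as.numeric(tapply(v[keep], rbin[keep], mean))
  radii <- sort(unique(rbin[keep]))
  crest_bin <- radii[which.max(prof)]
  flagged <- crest_bin < 1
  if (flagged) {
    return(list(
      central_to_crest = NA_real_, uniformity = NA_real_,
      crest_radius_nm = NA_real_, crest_intensity = NA_real_,
      flagged = TRUE
    ))
  }
  # refine crest radius by parabola through the three neighbouring bins
  i <- which.max(prof)
  if (i > 1 && i < length(prof)) {
    y3 <- prof[(i - 1):(i + 1)]
    denom <- y3[1] - 2 * y3[2] + y3[3]
    crest_r <- crest_bin + if (denom < 0) 0.5 * (y3[1] - y3[3]) / denom else 0
  } else {
    crest_r <- crest_bin
  }
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ring <- bilinear_at(
    v, c0 + crest_r * cos(theta),
    c0 + crest_r * sin(theta)
  )
  crest_intensity <- max(prof)
  list(
    central_to_crest = v[c0, c0] / crest_intensity,
    uniformity = min(ring) / max(ring),
    crest_radius_nm = crest_r * psf$step,
    crest_intensity = crest_intensity,
    flagged = FALSE
  )
}

# bilinear interpolation of matrix m (rows = x) at fractional indices
bilinear_at <- function(m, xi, yi) {
  x0 <- floor(xi)
  y0 <- floor(yi)
  fx <- xi - x0
  fy <- yi - y0
  idx <- function(a, b) m[cbind(a, b)]
  idx(x0, y0) * (1 - fx) * (1 - fy) +
    idx(x0 + 1, y0) * fx * (1 - fy) +
    idx(x0, y0 + 1) * (1 - fx) * fy +
    idx(x0 + 1, y0 + 1) * fx * fy
}
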