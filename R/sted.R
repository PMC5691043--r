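# STED performance analysis: 2D-Lorentzian FWHM estimation of bead spots,
# the square-root resolution law FWHM(P) = FWHM_confocal / sqrt(1 + P/Psat),
# and synthetic bead-scan fixtures (PSF convolved with the bead profile plus
# shot noise).

#' Fit a 2D Lorentzian peak
#'
#' Least-squares fit of `A / (1 + ((x - x0)^2 + (y - y0)^2) / gamma^2) + b`
#' to a single-spot image; the FWHM is `2 * gamma * step` nm. Spots whose
#' raw peak value falls outside `intensity_window` (used to reject clusters
#' of beads, which appear larger and brighter) are flagged and excluded from
#' downstream averages, as are diverged fits.
#'
#' @param image Numeric matrix of counts (rows index x).
#' @param step Pixel size in nm.
#' @param intensity_window Optional `c(lo, hi)` accepted range for the peak
#'   value (same units as `image`).
#' @return A `lorentz_fit`: list with `fwhm_nm`, `center_nm` (x, y relative
#'   to the image center), `peak`, `background`, `converged`, `excluded`,
#'   and the `nls` fit object (or NULL).
#' @examples
#' img <- outer(-20:20, -20:20, function(x, y) 100 / (1 + (x^2 + y^2) / 25))
#' lorentzian2d_fit(img, step = 10)$fwhm_nm # 2 * 5 * 10 = 100
#' @export
lorentzian2d_fit <- function(image, step, intensity_window = NULL) {
  stopifnot(is.matrix(image), step > 0)
  nx <- nrow(image)
  ny <- ncol(image)
  pk <- which(image == max(image), arr.ind = TRUE)[1, ]
  peak_raw <- max(image)
  excluded <- !is.null(intensity_window) &&
    (peak_raw < intensity_window[1] || peak_raw > intensity_window[2])
  df <- data.frame(
    x = as.vector(row(image)), y = as.vector(col(image)),
    z = as.vector(image)
  )
  bg0 <- stats::quantile(df$z, 0.1, names = FALSE)
  start <- list(
    A = peak_raw - bg0, x0 = pk[[1]], y0 = pk[[2]],
    g = max(2, nx / 10), b = bg0
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ A / (1 + ((x - x0)^2 + (y - y0)^2) / g^2) + b,
      data = df, start = start,
      lower = c(A = 0, x0 = 1, y0 = 1, g = 0.3, b = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(
      list(
        fwhm_nm = NA_real_, center_nm = c(NA_real_, NA_real_),
        peak = peak_raw, background = bg0,
        converged = FALSE, excluded = TRUE, fit = NULL, step = step
      ),
      class = "lorentz_fit"
    ))
  }
  cf <- coef(fit)
  structure(
    list(
      fwhm_nm = 2 * abs(cf[["g"]]) * step,
      center_nm = c(
        (cf[["x0"]] - (nx + 1) / 2) * step,
        (cf[["y0"]] - (ny + 1) / 2) * step
      ),
      peak = cf[["A"]] + cf[["b"]], background = cf[["b"]],
      converged = TRUE, excluded = excluded, fit = fit, step = step
    ),
    class = "lorentz_fit"
  )
}

#' @export
print.lorentz_fit <- function(x, ...) {
  cat(sprintf(
    "<lorentz_fit> FWHM %.3g nm%s%s\n", x$fwhm_nm,
    if (!x$converged) " (diverged)" else "",
    if (x$excluded) " [excluded]" else ""
  ))
  invisible(x)
}

#' @export
tidy.lorentz_fit <- function(x, ...) {
  tibble(
    fwhm_nm = x$fwhm_nm, center_x_nm = x$center_nm[1],
    center_y_nm = x$center_nm[2], peak = x$peak,
    background = x$background, converged = x$converged,
    excluded = x$excluded
  )
}

#' Fit the STED resolution law
#'
#' Nonlinear least-squares fit of
#' `FWHM(P) = FWHM_confocal * (1 + P / P_sat)^(-1/2)`
#' to measured spot widths versus depletion power: the inverse-square-root
#' resolution scaling of STED microscopy. `FWHM_confocal` is the
#' zero-power (confocal) width and `P_sat` the saturation power of the
#' depletion transition.
#'
#' @param data Data frame with columns `power` (mW) and `fwhm` (nm); at
#'   least 3 rows spanning more than one power.
#' @return A `resolution_fit`: list with `fwhm_confocal`, `p_sat`,
#'   `residuals`, `covariance`, `data` and the underlying `nls` object.
#' @examples
#' d <- tibble::tibble(power = c(0, 5, 15, 35))
#' d$fwhm <- 250 / sqrt(1 + d$power / 1.2)
#' resolution_law_fit(d)
#' @export
resolution_law_fit <- function(data) {
  if (!all(c("power", "fwhm") %in% names(data))) {
    abort("`data` must have columns `power` and `fwhm`.")
  }
  data <- as_tibble(data[c("power", "fwhm")])
  if (nrow(data) < 3) abort("Need at least 3 (power, fwhm) points.")
  if (any(data$power < 0)) abort("Powers must be >= 0.")
  if (length(unique(data$power)) < 2) {
    abort("Degenerate data: all powers are equal.")
  }
  f0_start <- if (any(data$power == 0)) {
    mean(data$fwhm[data$power == 0])
  } else {
    max(data$fwhm)
  }
  psat_start <- max(stats::median(data$power), 1e-3)
  fit <- minpack.lm::nlsLM(
    fwhm ~ f0 / sqrt(1 + power / psat),
    data = data,
    start = list(f0 = f0_start, psat = psat_start),
    lower = c(f0 = 1e-6, psat = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- coef(fit)
  structure(
    list(
      fwhm_confocal = cf[["f0"]], p_sat = cf[["psat"]],
      residuals = stats::residuals(fit),
      covariance = tryCatch(stats::vcov(fit), error = function(e) NULL),
      data = data, fit = fit
    ),
    class = "resolution_fit"
  )
}

#' Predicted FWHM from a resolution-law fit
#'
#' @param object A `resolution_fit`.
#' @param power Powers (mW) at which to evaluate the law.
#' @return Numeric vector of FWHM (nm).
#' @export
predict_resolution <- function(object, power) {
  stopifnot(inherits(object, "resolution_fit"))
  object$fwhm_confocal / sqrt(1 + power / object$p_sat)
}

#' @export
print.resolution_fit <- function(x, ...) {
  cat(sprintf(
    "<resolution_fit> FWHM_confocal = %.4g nm, P_sat = %.4g mW (n = %d)\n",
    x$fwhm_confocal, x$p_sat, nrow(x$data)
  ))
  invisible(x)
}

#' @export
tidy.resolution_fit <- function(x, ...) {
  se <- if (!is.null(x$covariance)) sqrt(diag(x$covariance)) else rep(NA, 2)
  tibble(
    term = c("fwhm_confocal", "p_sat"),
    estimate = c(x$fwhm_confocal, x$p_sat),
    std.error = as.numeric(se)
  )
}

#' @export
glance.resolution_fit <- function(x, ...) {
  tibble(
    fwhm_confocal = x$fwhm_confocal,
    p_sat = x$p_sat,
    sigma = sqrt(mean(x$residuals^2)),
    nobs = nrow(x$data)
  )
}

#' Synthetic effective STED spot profile
#'
#' A 2D-Lorentzian intensity profile of given FWHM, peak-normalized, as an
#' `intensity_psf` on its own pixel grid. The effective fluorescence spot of
#' a STED microscope is well described by a Lorentzian-like peak whose width
#' follows the resolution law; the depletion photophysics itself is not
#' modelled.
#'
#' @param fwhm_nm Full width at half maximum, nm.
#' @param step Pixel size, nm.
#' @param n Grid size (pixels per dimension).
#' @return An `intensity_psf`.
#' @export
synthetic_sted_psf <- function(fwhm_nm, step = 10, n = 65) {
  stopifnot(fwhm_nm > 0, step > 0, n >= 5)
  c0 <- floor(n / 2) + 1L
  x <- ((1:n) - c0) * step
  g <- fwhm_nm / 2
  v <- 1 / (1 + outer(x^2, x^2, "+") / g^2)
  structure(
    list(values = v, step = step, center_index = c0, normalization = "peak"),
    class = "intensity_psf"
  )
}

# uniform-disk convolution kernel with sub-pixel area weighting
disk_kernel <- function(diameter_nm, step, oversample = 8) {
  r <- diameter_nm / 2 / step # radius in pixels
  if (r <= 0) {
    return(matrix(1, 1, 1))
  }
  half <- ceiling(r + 1)
  n <- 2 * half + 1
  sub <- (seq_len(oversample) - 0.5) / oversample - 0.5
  k <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      cx <- i - half - 1
      cy <- j - half - 1
      xx <- outer(cx + sub, rep(1, oversample))
      yy <- outer(rep(1, oversample), cy + sub)
      k[i, j] <- mean(xx^2 + yy^2 <= r^2)
    }
  }
  if (sum(k) == 0) k[half + 1, half + 1] <- 1
  k / sum(k)
}

# FFT-free direct 2D convolution, 'same' size (kernels are small)
convolve2d_same <- function(img, kern) {
  kn <- nrow(kern)
  if (kn == 1) {
    return(img * kern[1, 1])
  }
  half <- (kn - 1) / 2
  n <- nrow(img)
  m <- ncol(img)
  pad <- matrix(0, n + 2 * half, m + 2 * half)
  pad[(half + 1):(half + n), (half + 1):(half + m)] <- img
  out <- matrix(0, n, m)
  for (i in seq_len(kn)) {
    for (j in seq_len(kn)) {
      if (kern[i, j] == 0) next
      out <- out + kern[i, j] *
        pad[(i):(i + n - 1), (j):(j + m - 1)]
    }
  }
  out
}

#' Simulate a confocal bead scan
#'
#' Expected image = intensity PSF convolved with a uniform disk of the bead
#' diameter (incoherent scattering/fluorescence approximation), scaled so
#' that the brightest pixel's expectation equals `photon_budget`; observed
#' counts are Poisson-distributed with the given seed (deterministic per
#' seed). `photon_budget = Inf` disables noise and returns the expected
#' image as counts.
#'
#' @param psf An `intensity_psf` (simulated or [synthetic_sted_psf()]).
#' @param bead_diameter_nm Bead diameter in nm (>= 0; 0 = point emitter).
#' @param photon_budget Expected counts in the brightest pixel.
#' @param seed Integer seed for the shot noise.
#' @return A `bead_image`: list with matrices `expected` and `counts`,
#'   `step`, `bead_diameter_nm`, `photon_budget`, `seed`.
#' @export
simulate_bead_scan <- function(psf, bead_diameter_nm = 20,
                               photon_budget = 1e4, seed = 1L) {
  stopifnot(inherits(psf, "intensity_psf"))
  if (bead_diameter_nm < 0) abort("`bead_diameter_nm` must be >= 0.")
  kern <- disk_kernel(bead_diameter_nm, psf$step)
  expected <- convolve2d_same(psf$values, kern)
  mx <- max(expected)
  if (mx > 0 && is.finite(photon_budget)) {
    expected <- expected / mx * photon_budget
  }
  counts <- if (is.finite(photon_budget)) {
    withr::with_seed(as.integer(seed), {
      matrix(rpois(length(expected), expected),
        nrow(expected), ncol(expected)
      )
    })
  } else {
    expected
  }
  structure(
    list(
      expected = expected, counts = counts, step = psf$step,
      bead_diameter_nm = bead_diameter_nm,
      photon_budget = photon_budget, seed = seed
    ),
    class = "bead_image"
  )
}

#' @export
print.bead_image <- function(x, ...) {
  cat(sprintf(
    "<bead_image> %dx%d, step %g nm, bead %g nm, budget %g, seed %s\n",
    nrow(x$counts), ncol(x$counts), x$step, x$bead_diameter_nm,
    x$photon_budget, format(x$seed)
  ))
  invisible(x)
}
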