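# ggplot2 display methods.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an intensity PSF
#'
#' Raster image of the focal intensity; `trans = "log10"` mirrors the
#' logarithmic display used for sensing PSFs (emphasizes the residual
#' structure in the central valley).
#'
#' @param object An `intensity_psf`.
#' @param trans `"identity"` or `"log10"`.
#' @param zoom_nm Optional half-width (nm) of a centered crop.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.intensity_psf <- function(object, trans = "identity",
                                   zoom_nm = NULL, ...) {
  v <- object$values
  n <- nrow(v)
  x <- ((1:n) - object$center_index) * object$step
  df <- tibble(
    x = rep(x, times = n), y = rep(x, each = n),
    intensity = as.vector(v)
  )
  if (!is.null(zoom_nm)) {
    df <- dplyr::filter(df, abs(.data$x) <= zoom_nm, abs(.data$y) <= zoom_nm)
  }
  if (trans == "log10") {
    df$intensity <- log10(pmax(df$intensity, max(df$intensity) * 1e-8))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
    fill = .data$intensity
  )) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = if (trans == "log10") {
      "log10 I"
    } else {
      "I"
    }) +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' Plot a sensing scan
#'
#' Central PSF intensity versus the swept parameter.
#'
#' @param object A `sted_scan` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sted_scan <- function(object, ...) {
  par_name <- attr(object, "parameter")
  unit <- attr(object, "unit")
  df <- tibble(
    parameter = object[[1]],
    central_intensity = object$central_intensity
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter, .data$central_intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("%s (%s)", par_name, unit),
      y = "central intensity",
      title = sprintf("%s scan", attr(object, "mask_kind"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a resolution-law fit
#'
#' Measured FWHM versus STED power with the fitted
#' inverse-square-root law.
#'
#' @param object A `resolution_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.resolution_fit <- function(object, ...) {
  pw <- seq(min(object$data$power), max(object$data$power), length.out = 200)
  curve <- tibble(power = pw, fwhm = predict_resolution(object, pw))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$power, .data$fwhm)) +
    ggplot2::geom_line(data = curve, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "STED power (mW)", y = "FWHM (nm)",
      title = sprintf(
        "FWHM_confocal = %.0f nm, P_sat = %.2g mW",
        object$fwhm_confocal, object$p_sat
      )
    ) +
    ggplot2::theme_minimal()
}
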