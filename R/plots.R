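#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods render each result type with ggplot2: kernels and
#' radial profiles as log-log dose-distance curves (the conventional view,
#' since point-kernel doses fall by many decades over the electron range),
#' electron spectra as weight histograms, and pixel grids / dose maps as
#' rasters.
#'
#' @param object the object to plot.
#' @param log_log draw dose-distance curves on log10 axes (default TRUE);
#'   zero-dose bins are dropped from log plots.
#' @param ... unused.
#' @return A ggplot object.
#' @name nanodpk-autoplot
NULL

#' @rdname nanodpk-autoplot
#' @export
autoplot.dose_point_kernel <- function(object, log_log = TRUE, ...) {
  df <- tidy(object)
  if (log_log) df <- df[df$dose_keV_per_g_per_src > 0 & df$r_mid_nm > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$r_mid_nm,
                                        .data$dose_keV_per_g_per_src)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "radius (nm)", y = "dose (keV/g per source electron)",
                  title = sprintf("Dose point kernel (%s)", attr(object, "medium")))
  if (log_log) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' @rdname nanodpk-autoplot
#' @export
autoplot.radial_dose_profile <- function(object, log_log = TRUE, ...) {
  df <- tidy(object)
  if (log_log) df <- df[df$dose_keV_per_g_per_src > 0 & df$d_mid_nm > 0, ]
  meta <- attr(object, "meta")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$d_mid_nm,
                                        .data$dose_keV_per_g_per_src)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from surface (nm)",
                  y = "dose (keV/g per source electron)",
                  title = meta$geometry %||% "radial dose profile",
                  subtitle = if (!is.null(meta$factor)) {
                    sprintf("factor %s (alpha = %.3g)", meta$factor,
                            as.numeric(meta$alpha))
                  })
  if (log_log) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' @rdname nanodpk-autoplot
#' @export
autoplot.electron_spectrum <- function(object, ...) {
  df <- tibble::tibble(e = spectrum_centers(object), w = object$weight)
  ggplot2::ggplot(df[df$w > 0, ], ggplot2::aes(.data$e, .data$w)) +
    ggplot2::geom_col(width = attr(object, "bin_width")) +
    ggplot2::labs(x = "electron energy (keV)",
                  y = "electrons per incident photon per bin")
}

#' @rdname nanodpk-autoplot
#' @export
autoplot.pixel_grid <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$ix, .data$iy, fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(gold = "goldenrod", water = "grey90")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (pixels)", y = "y (pixels)", fill = NULL)
}

#' @rdname nanodpk-autoplot
#' @export
autoplot.dose_map <- function(object, ...) {
  df <- tidy(object)
  df$dose[df$label == "gold"] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(.data$ix, .data$iy, fill = .data$dose)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = "log10", na.value = "black") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (pixels)", y = "y (pixels)",
                  fill = if (object$relative) "relative dose" else "dose (keV/g)")
}
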