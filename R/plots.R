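#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a depth-dose curve
#'
#' @param object An [idd_curve].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.idd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_mm, y = .data$dose)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Depth in water (mm)", y = "Dose (norm.)",
                  title = sprintf("IDD, nominal energy %s MeV",
                                  format(nominal_energy(object)))) +
    ggplot2::theme_minimal()
}

#' Plot an effective energy spectrum
#'
#' @param object An `energy_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.energy_spectrum <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$energy_mev, y = .data$weight)) +
    ggplot2::geom_col(width = 0.4) +
    ggplot2::labs(x = "Energy (MeV)", y = "Weight",
                  title = "Effective energy spectrum") +
    ggplot2::theme_minimal()
}

#' Plot per-point gamma values
#'
#' @param object A `gamma_result`.
#' @param ... Unused.
#' @return A ggplot (line for 1-D results, raster for 2-D).
#' @export
autoplot.gamma_result <- function(object, ...) {
  g <- object$gamma_values
  if (is.matrix(g)) {
    df <- tibble::tibble(
      col = rep(seq_len(ncol(g)), each = nrow(g)),
      row = rep(seq_len(nrow(g)), times = ncol(g)),
      gamma = as.vector(g))
    ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                     fill = .data$gamma)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::coord_equal() +
      ggplot2::labs(title = sprintf("Gamma map, %s", format(object$criteria)),
                    x = NULL, y = NULL) +
      ggplot2::theme_minimal()
  } else {
    df <- tibble::tibble(index = seq_along(g), gamma = g)
    ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$gamma)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 1, linetype = 2) +
      ggplot2::labs(title = sprintf("Gamma, %s", format(object$criteria)),
                    x = "Reference point", y = "gamma") +
      ggplot2::theme_minimal()
  }
}

#' Plot a planar dose distribution
#'
#' @param object A [dose_plane()].
#' @param ... Unused.
#' @return A ggplot raster of the plane.
#' @export
autoplot.dose_plane <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$dose)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("Planar dose at z = %+.0f mm",
                                  object$z_mm)) +
    ggplot2::theme_minimal()
}

#' Plot measured spot sigmas and the fitted free-drift model
#'
#' @param sigma_table [spot_sigma_table()] output (one energy).
#' @param optics Optional [fit_gantry_optics()] rows for the same energy.
#' @return A ggplot of sigma vs z per axis.
#' @export
plot_sigma_drift <- function(sigma_table, optics = NULL) {
  p <- ggplot2::ggplot(sigma_table,
                       ggplot2::aes(.data$z_mm, .data$sigma_mm,
                                    colour = .data$axis)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "z from isocenter (mm)", y = "Spot sigma (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(optics)) {
    zf <- seq(min(sigma_table$z_mm), max(sigma_table$z_mm), length.out = 121)
    fitdf <- purrr::pmap_dfr(optics, function(energy_mev, axis, A_mm2,
                                               B_mm_mrad, C_mrad2, ...) {
      tibble::tibble(axis = axis, z_mm = zf,
                     sigma_mm = sqrt(A_mm2 + 2 * B_mm_mrad * zf / 1000 +
                                       C_mrad2 * (zf / 1000)^2))
    })
    p <- p + ggplot2::geom_line(data = fitdf)
  }
  p
}
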