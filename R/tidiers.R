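#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a gamma result
#'
#' @param x A `gamma_result`.
#' @param ... Unused.
#' @return Tibble with one row per reference point: `gamma`, `evaluated`
#'   (whether the point enters the summary).
#' @export
tidy.gamma_result <- function(x, ...) {
  tibble::tibble(gamma = as.vector(x$gamma_values),
                 evaluated = as.vector(x$evaluated))
}

#' @rdname tidy.gamma_result
#' @return For `glance`: one row with `passing_rate`, `mean_gamma`,
#'   `n_evaluated`, `dta_mm`, `dose_diff_pct`.
#' @export
glance.gamma_result <- function(x, ...) {
  tibble::tibble(passing_rate = x$passing_rate, mean_gamma = x$mean_gamma,
                 n_evaluated = x$n_evaluated,
                 dta_mm = x$criteria$dta_mm,
                 dose_diff_pct = x$criteria$dose_diff_pct)
}

#' Tidy an effective energy spectrum
#'
#' @param x An `energy_spectrum`.
#' @param ... Unused.
#' @return Tibble of `energy_mev`, `weight`.
#' @export
tidy.energy_spectrum <- function(x, ...) {
  tibble::tibble(energy_mev = x$energy_mev, weight = x$weight)
}

#' @rdname tidy.energy_spectrum
#' @return For `glance`: `nominal_energy`, `mean_energy`, `scale`,
#'   `residual`.
#' @export
glance.energy_spectrum <- function(x, ...) {
  tibble::tibble(nominal_energy = attr(x, "nominal_energy"),
                 mean_energy = spectrum_mean_energy(x),
                 scale = attr(x, "scale"),
                 residual = attr(x, "residual"))
}

#' Tidy Fermi--Eyges moments
#'
#' @param x An `optics_moments`.
#' @param ... Unused.
#' @return Tibble with one row per moment (`term`, `estimate`, `unit`).
#' @export
tidy.optics_moments <- function(x, ...) {
  tibble::tibble(
    term = c("spatial_variance", "spatial_angular_covariance",
             "angular_variance"),
    estimate = c(x$A, x$B, x$C),
    unit = c("mm^2", "mm*mrad", "mrad^2")
  )
}

#' @rdname tidy.optics_moments
#' @return For `glance`: `A_mm2`, `B_mm_mrad`, `C_mrad2`, `sigma_iso_mm`,
#'   `axis`.
#' @export
glance.optics_moments <- function(x, ...) {
  tibble::tibble(A_mm2 = x$A, B_mm_mrad = x$B, C_mrad2 = x$C,
                 sigma_iso_mm = sqrt(x$A), axis = x$axis)
}

#' Tidy a Gaussian profile fit
#'
#' @param x A `gaussian_fit`.
#' @param ... Unused.
#' @return Tibble of `term`, `estimate`.
#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble::tibble(term = c("mu", "sigma", "amplitude", "baseline"),
                 estimate = c(x$mu, x$sigma, x$amplitude, x$baseline))
}

#' @rdname tidy.gaussian_fit
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(mu_mm = x$mu, sigma_mm = x$sigma,
                 rms_residual = x$rms_residual)
}
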