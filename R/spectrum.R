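#' Build a pristine Bragg-peak basis
#'
#' Pre-calculates mono-energetic pristine Bragg peaks around a nominal
#' energy, on a shared depth grid, each normalized to unit maximum. A
#' measured IDD curve is later modelled as a non-negative linear
#' combination of these members; the weights are the effective energy
#' spectrum.
#'
#' @param nominal_energy Centre energy (MeV).
#' @param half_width Half-width of the member energy span (MeV); default
#'   10 MeV.
#' @param step Member spacing (MeV); default 0.5 MeV.
#' @param grid_mm Shared depth grid; defaults to the configuration grid.
#' @param config A [beamline_config()].
#' @return A `pristine_basis`: list with `energies` (MeV, increasing),
#'   `curves` (depth x member matrix), `depth_mm`, `config`.
#' @export
build_basis <- function(nominal_energy, half_width = 10, step = 0.5,
                        grid_mm = depth_grid(config),
                        config = beamline_config()) {
  stopifnot(half_width > 0, step > 0)
  energies <- seq(nominal_energy - half_width, nominal_energy + half_width,
                  by = step)
  energies <- energies[energies > 0]
  curves <- vapply(
    energies,
    function(e) mono_bragg(range_from_energy(e, config), grid_mm, config)$dose,
    numeric(length(grid_mm))
  )
  structure(
    list(energies = energies, curves = curves,
         depth_mm = grid_mm, config = config,
         nominal_energy = nominal_energy),
    class = "pristine_basis"
  )
}

#' @export
print.pristine_basis <- function(x, ...) {
  cat(sprintf("<pristine_basis> %d members, %.1f-%.1f MeV, %d depth points\n",
              length(x$energies), min(x$energies), max(x$energies),
              length(x$depth_mm)))
  invisible(x)
}

#' Fit an effective energy spectrum to a measured IDD curve
#'
#' Solves the non-negative least-squares problem
#' \eqn{\min_w \| d - B w \|_2, w \ge 0} where the columns of B are the
#' pristine basis peaks, then normalizes the weights to sum to one. The
#' overall amplitude is kept as a separate `scale` attribute so spectra are
#' comparable across energies after curves are normalized to unity.
#'
#' @param measured An [idd_curve] on the basis depth grid (resample first).
#' @param basis A [build_basis()] result.
#' @return An `energy_spectrum`: tibble with columns `energy_mev`, `weight`
#'   (non-negative, summing to 1), with attributes `scale` (sum of raw
#'   weights), `residual` (L2 norm of the fit residual) and
#'   `nominal_energy`.
#' @export
fit_spectrum <- function(measured, basis) {
  stopifnot(inherits(measured, "idd_curve"), inherits(basis, "pristine_basis"))
  if (length(basis$energies) == 0) stop("empty basis", call. = FALSE)
  if (nrow(measured) != length(basis$depth_mm) ||
      max(abs(measured$depth_mm - basis$depth_mm)) > 1e-6) {
    stop("measured curve and basis must share the depth grid; resample first",
         call. = FALSE)
  }
  sol <- pracma::lsqnonneg(basis$curves, measured$dose)
  w <- sol$x
  total <- sum(w)
  if (total <= 0) stop("degenerate fit: all weights zero", call. = FALSE)
  out <- tibble::tibble(energy_mev = basis$energies, weight = w / total)
  class(out) <- c("energy_spectrum", class(out))
  attr(out, "scale") <- total
  attr(out, "residual") <- sqrt(sum((basis$curves %*% w - measured$dose)^2))
  attr(out, "nominal_energy") <- basis$nominal_energy
  out
}

#' Mean energy of a spectrum
#' @param spectrum An `energy_spectrum`.
#' @return Weighted mean energy (MeV).
#' @export
spectrum_mean_energy <- function(spectrum) {
  sum(spectrum$energy_mev * spectrum$weight)
}

#' Reconstruct the model ("computed") IDD curve from a spectrum
#'
#' Weighted sum of the basis members, renormalized to unit maximum. This is
#' the model-based curve that the fit reproduces from a measurement.
#'
#' @param spectrum An `energy_spectrum` whose energies are members of the
#'   basis.
#' @param basis The [build_basis()] the spectrum was fitted against.
#' @return An [idd_curve] with max dose 1.
#' @export
reconstruct_idd <- function(spectrum, basis) {
  stopifnot(inherits(basis, "pristine_basis"))
  idx <- match(round(spectrum$energy_mev, 9), round(basis$energies, 9))
  if (anyNA(idx)) {
    stop("spectrum contains energies not present in the basis", call. = FALSE)
  }
  dose <- as.numeric(basis$curves[, idx, drop = FALSE] %*% spectrum$weight)
  normalize_unity(idd_curve(basis$depth_mm, dose,
                            nominal_energy = attr(spectrum, "nominal_energy")))
}

#' R80 energy of an effective energy spectrum
#'
#' The single equivalent mono-energetic beam energy whose R80 range equals
#' that of the spectrum's reconstructed curve.
#'
#' @inheritParams reconstruct_idd
#' @param config A [beamline_config()]; defaults to the basis config.
#' @return Energy in MeV.
#' @export
r80_energy <- function(spectrum, basis, config = basis$config) {
  energy_from_range(r80(reconstruct_idd(spectrum, basis)) / 10, config)
}
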