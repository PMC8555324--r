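#' Integrated depth-dose curve
#'
#' Constructs an `idd_curve`: a tibble with columns `depth_mm` and `dose`
#' on a strictly increasing uniform depth grid, carrying the nominal beam
#' energy and grid step as attributes. This is the package's container for
#' both measured and model-computed IDD curves.
#'
#' @param depth_mm Uniform, strictly increasing depth grid (mm).
#' @param dose Non-negative dose values, same length as `depth_mm`.
#' @param nominal_energy Nominal beam energy (MeV), or `NA`.
#' @return A tibble of class `idd_curve`.
#' @export
idd_curve <- function(depth_mm, dose, nominal_energy = NA_real_) {
  stopifnot(length(depth_mm) == length(dose))
  if (any(dose < 0)) stop("dose must be non-negative", call. = FALSE)
  step <- unique_grid_step(depth_mm)
  out <- tibble::tibble(depth_mm = as.numeric(depth_mm),
                        dose = as.numeric(dose))
  class(out) <- c("idd_curve", class(out))
  attr(out, "nominal_energy") <- as.numeric(nominal_energy)
  attr(out, "grid_step") <- step
  out
}

#' @export
print.idd_curve <- function(x, ...) {
  cat(sprintf("<idd_curve> %d points, step %.3g mm, nominal energy %s MeV\n",
              nrow(x), attr(x, "grid_step"),
              format(attr(x, "nominal_energy"))))
  NextMethod()
}

#' Nominal energy of a curve or dataset element
#' @param x An object carrying a `nominal_energy` attribute.
#' @return Energy in MeV.
#' @export
nominal_energy <- function(x) attr(x, "nominal_energy")

#' Resample a depth-dose curve by cubic-spline interpolation
#'
#' Interpolates the curve onto a new uniform grid spanning the same depth
#' range (no extrapolation), e.g. from a 1.0 mm measurement grid to the
#' 0.1 mm analysis grid. Knot values are preserved exactly.
#'
#' @param curve An [idd_curve].
#' @param step_mm New grid step (mm), positive.
#' @return An [idd_curve] on the new grid.
#' @export
resample_curve <- function(curve, step_mm) {
  stopifnot(inherits(curve, "idd_curve"), step_mm > 0, nrow(curve) >= 4)
  z0 <- curve$depth_mm[1]
  z1 <- curve$depth_mm[nrow(curve)]
  new_grid <- seq(z0, z1, by = step_mm)
  # keep the exact endpoint when the step does not divide the span
  if (new_grid[length(new_grid)] < z1 - 1e-9) new_grid <- c(new_grid, z1)
  if (new_grid[1] < z0 - 1e-9 || new_grid[length(new_grid)] > z1 + 1e-9) {
    stop("resampling must not extrapolate", call. = FALSE)
  }
  f <- stats::splinefun(curve$depth_mm, curve$dose, method = "fmm")
  dose <- pmax(f(new_grid), 0)
  idd_curve(new_grid, dose, nominal_energy = nominal_energy(curve))
}

#' Renormalize a curve to unit maximum
#'
#' @param curve An [idd_curve] with a positive maximum.
#' @return The curve divided by its maximum (max exactly 1).
#' @export
normalize_unity <- function(curve) {
  stopifnot(inherits(curve, "idd_curve"))
  m <- max(curve$dose)
  if (m <= 0) stop("cannot normalize an all-zero curve", call. = FALSE)
  idd_curve(curve$depth_mm, curve$dose / m,
            nominal_energy = nominal_energy(curve))
}

#' Distal R80 range of a depth-dose curve
#'
#' Depth distal to the global maximum where the dose first crosses 80% of
#' the maximum, located by linear interpolation between the bracketing grid
#' points. This is the standard proton range surrogate.
#'
#' @param curve An [idd_curve], single-peaked.
#' @return Depth in mm.
#' @export
r80 <- function(curve) {
  stopifnot(inherits(curve, "idd_curve"))
  dose <- curve$dose
  z <- curve$depth_mm
  ipk <- which.max(dose)
  thr <- 0.8 * dose[ipk]
  distal <- dose[ipk:length(dose)]
  below <- which(distal <= thr)
  if (length(below) == 0) {
    stop("no distal 80% crossing: curve truncated before falloff",
         call. = FALSE)
  }
  j <- below[1]
  if (j == 1) return(z[ipk])
  i1 <- ipk + j - 2
  i2 <- ipk + j - 1
  z[i1] + (thr - dose[i1]) * (z[i2] - z[i1]) / (dose[i2] - dose[i1])
}
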