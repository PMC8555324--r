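#' Gamma-analysis acceptance criteria
#'
#' @param dta_mm Distance-to-agreement tolerance (mm), positive.
#' @param dose_diff_pct Dose-difference tolerance, in percent of the global
#'   normalization dose (the reference maximum), positive.
#' @param low_dose_threshold_pct Reference points below this percentage of
#'   the reference maximum are excluded from the summary (0 disables).
#' @return An object of class `gamma_criteria`.
#' @examples
#' gamma_criteria(1, 1)            # IDD curves
#' gamma_criteria(3, 3, 10)        # patient QA planes
#' @export
gamma_criteria <- function(dta_mm, dose_diff_pct, low_dose_threshold_pct = 0) {
  stopifnot(dta_mm > 0, dose_diff_pct > 0,
            low_dose_threshold_pct >= 0, low_dose_threshold_pct < 100)
  structure(
    list(dta_mm = dta_mm, dose_diff_pct = dose_diff_pct,
         low_dose_threshold_pct = low_dose_threshold_pct),
    class = "gamma_criteria"
  )
}

#' @export
format.gamma_criteria <- function(x, ...) {
  sprintf("%g mm/%g%%%s", x$dta_mm, x$dose_diff_pct,
          if (x$low_dose_threshold_pct > 0)
            sprintf(" (%g%% threshold)", x$low_dose_threshold_pct) else "")
}

new_gamma_result <- function(gamma, evaluated, criteria) {
  g <- gamma[evaluated]
  structure(
    list(gamma_values = gamma, evaluated = evaluated,
         # boundary inclusive (gamma = 1 passes), guarded against fp noise
         passing_rate = 100 * mean(g <= 1 + 1e-9),
         mean_gamma = mean(g),
         n_evaluated = sum(evaluated),
         criteria = criteria),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %s: passing %.2f%%, mean gamma %.4f (n = %d)\n",
              format(x$criteria), x$passing_rate, x$mean_gamma, x$n_evaluated))
  invisible(x)
}

#' 1-D gamma analysis of two depth-dose curves
#'
#' For each reference point, the gamma index is the minimum over evaluated
#' positions of \eqn{\sqrt{\Delta z^2/\delta_{dta}^2 +
#' \Delta D^2/\delta_{dd}^2}}, with the dose difference expressed in
#' percent of the reference maximum (global normalization). The evaluated
#' curve is spline-resampled to a step of dta/10 for the search; the search
#' window is |dz| <= 3 dta, so reported gamma values are capped by the
#' window limit.
#'
#' Both curves are expected normalized to unity; curves are compared on the
#' overlap of their depth ranges.
#'
#' @param reference,evaluated [idd_curve] objects (reference = measured by
#'   convention).
#' @param criteria A [gamma_criteria()].
#' @return A `gamma_result` with per-point gamma values, passing rate (% of
#'   evaluated points with gamma <= 1), mean gamma and the evaluated count.
#' @export
gamma_1d <- function(reference, evaluated, criteria) {
  stopifnot(inherits(reference, "idd_curve"), inherits(evaluated, "idd_curve"),
            inherits(criteria, "gamma_criteria"))
  dta <- criteria$dta_mm
  dd <- criteria$dose_diff_pct
  dnorm_ref <- max(reference$dose)
  # search lattice: dta/10, but never coarser than the evaluated grid, so
  # loosening the criteria can only lower gamma (monotonicity)
  h <- min(dta / 10, attr(evaluated, "grid_step"))
  z0 <- evaluated$depth_mm[1]
  z1 <- evaluated$depth_mm[nrow(evaluated)]
  if (z1 <= reference$depth_mm[1] || z0 >= max(reference$depth_mm)) {
    stop("curves have no depth overlap", call. = FALSE)
  }
  fine_z <- seq(z0, z1, by = h)
  fe <- stats::splinefun(evaluated$depth_mm, evaluated$dose,
                         method = "fmm")(fine_z)
  zr <- reference$depth_mm
  dr <- reference$dose
  # candidate positions are the fine-grid samples of the evaluated curve
  # within the search window; distances are measured from the exact
  # reference depth, so off-lattice reference grids are handled correctly
  i0 <- round((zr - z0) / h)
  nwin <- ceiling(3 * dta / h) + 1
  g2 <- rep(Inf, length(zr))
  for (k in -nwin:nwin) {
    idx <- i0 + k + 1
    ok <- idx >= 1 & idx <= length(fine_z)
    if (!any(ok)) next
    dz <- fine_z[idx[ok]] - zr[ok]
    inwin <- abs(dz) <= 3 * dta + 1e-9
    if (!any(inwin)) next
    sel <- which(ok)[inwin]
    dD <- 100 * (fe[idx[sel]] - dr[sel]) / dnorm_ref
    cand <- (dz[inwin] / dta)^2 + (dD / dd)^2
    g2[sel] <- pmin(g2[sel], cand)
  }
  gamma <- sqrt(g2)
  evaluated_mask <- is.finite(gamma) &
    dr >= criteria$low_dose_threshold_pct / 100 * dnorm_ref
  if (!any(evaluated_mask)) stop("no evaluable reference points", call. = FALSE)
  new_gamma_result(gamma, evaluated_mask, criteria)
}

#' 2-D gamma analysis of two planar dose distributions
#'
#' Same gamma formula as [gamma_1d()] with Euclidean in-plane distance.
#' The evaluated plane is bilinearly interpolated on a dta/10 sub-grid of
#' offsets within a search disk of radius 3 dta around each reference
#' point. By convention the measured plane is the reference and the
#' computed (planned) plane is the evaluated distribution.
#'
#' @param reference,evaluated [dose_plane()] objects.
#' @param criteria A [gamma_criteria()].
#' @return A `gamma_result`; `gamma_values` is a matrix matching the
#'   reference grid.
#' @export
gamma_2d <- function(reference, evaluated, criteria) {
  stopifnot(inherits(reference, "dose_plane"), inherits(evaluated, "dose_plane"),
            inherits(criteria, "gamma_criteria"))
  dta <- criteria$dta_mm
  dd <- criteria$dose_diff_pct
  dnorm_ref <- max(reference$dose)
  axr <- plane_axes(reference)
  axe <- plane_axes(evaluated)
  if (min(axr$x) > max(axe$x) || max(axr$x) < min(axe$x) ||
      min(axr$y) > max(axe$y) || max(axr$y) < min(axe$y)) {
    stop("planes have no spatial overlap", call. = FALSE)
  }
  X <- rep(axr$x, each = nrow(reference$dose))
  Y <- rep(axr$y, times = ncol(reference$dose))
  Dr <- as.vector(reference$dose)
  h <- min(dta / 10, evaluated$pitch_mm)
  off <- seq(-3 * dta, 3 * dta, by = h)
  grid <- expand.grid(dx = off, dy = off)
  grid <- grid[grid$dx^2 + grid$dy^2 <= (3 * dta)^2 + 1e-9, ]
  # search near offsets first so the running minimum tightens quickly
  grid <- grid[order(grid$dx^2 + grid$dy^2), ]
  g2 <- rep(Inf, length(Dr))
  for (k in seq_len(nrow(grid))) {
    dx <- grid$dx[k]; dy <- grid$dy[k]
    d2 <- (dx^2 + dy^2) / dta^2
    if (all(g2 <= d2)) next   # no offset this far out can improve any point
    de <- plane_interp(evaluated, X + dx, Y + dy)
    ok <- !is.na(de)
    if (!any(ok)) next
    dD <- 100 * (de[ok] - Dr[ok]) / dnorm_ref
    g2[ok] <- pmin(g2[ok], d2 + (dD / dd)^2)
  }
  gamma <- sqrt(g2)
  mask <- is.finite(gamma) &
    Dr >= criteria$low_dose_threshold_pct / 100 * dnorm_ref
  if (!any(mask)) stop("no evaluable reference points", call. = FALSE)
  res <- new_gamma_result(gamma, mask, criteria)
  res$gamma_values <- matrix(gamma, nrow = nrow(reference$dose))
  res
}

#' Summarize a gamma result
#'
#' @param result A `gamma_result`.
#' @return A one-row tibble with `passing_rate` (percent of evaluated
#'   points with gamma <= 1, boundary inclusive), `mean_gamma` and
#'   `n_evaluated`.
#' @export
gamma_summary <- function(result) {
  stopifnot(inherits(result, "gamma_result"))
  if (result$n_evaluated == 0) stop("empty evaluation set", call. = FALSE)
  tibble::tibble(passing_rate = result$passing_rate,
                 mean_gamma = result$mean_gamma,
                 n_evaluated = result$n_evaluated)
}
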