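#' Default 5-spot test pattern
#'
#' Centre spot plus four corner spots at (+-80, +-80) mm.
#'
#' @param spacing_mm Corner offset from the axis (mm).
#' @return Tibble with columns `x_mm`, `y_mm` (5 rows).
#' @export
spot_pattern <- function(spacing_mm = 80) {
  tibble::tibble(
    x_mm = c(0, -spacing_mm, spacing_mm, -spacing_mm, spacing_mm),
    y_mm = c(0, -spacing_mm, -spacing_mm, spacing_mm, spacing_mm)
  )
}

#' Extract the five spots from a 5-spot test-pattern image
#'
#' Subtracts the detector background (median of the outer 5% image border,
#' clamped at zero), cuts a square region of interest of half-width
#' `8 * nominal_sigma_mm` around each nominal pattern position, and
#' recenters each ROI on its intensity centroid (nearest pixel).
#'
#' @param plane A [dose_plane()] holding the 5-spot image.
#' @param pattern Nominal spot positions, as from [spot_pattern()].
#' @param nominal_sigma_mm Nominal spot sigma (mm) setting the ROI size.
#' @return List of five [dose_plane()] ROIs (equal sizes), each carrying a
#'   `centroid` attribute with the estimated spot centre in beam
#'   coordinates (mm).
#' @export
extract_spots <- function(plane, pattern = spot_pattern(),
                          nominal_sigma_mm) {
  stopifnot(inherits(plane, "dose_plane"), nrow(pattern) == 5,
            nominal_sigma_mm > 0)
  half_mm <- 8 * nominal_sigma_mm
  # contaminated ROI: another spot's nominal position inside the window
  for (i in 1:4) for (j in (i + 1):5) {
    cheb <- max(abs(pattern$x_mm[i] - pattern$x_mm[j]),
                abs(pattern$y_mm[i] - pattern$y_mm[j]))
    if (cheb < half_mm) {
      stop("overlapping ROIs: spots closer than the ROI half-width",
           call. = FALSE)
    }
  }
  ax <- plane_axes(plane)
  border <- max(1, round(0.05 * min(dim(plane$dose))))
  d <- plane$dose
  edge <- c(d[seq_len(border), ], d[nrow(d) - seq_len(border) + 1, ],
            d[, seq_len(border)], d[, ncol(d) - border + seq_len(border)])
  d <- pmax(d - stats::median(edge), 0)
  if (max(d) <= 0) stop("no spots: image is empty after background subtraction",
                        call. = FALSE)
  half_px <- round(half_mm / plane$pitch_mm)
  lapply(seq_len(5), function(k) {
    ic <- which.min(abs(ax$x - pattern$x_mm[k]))
    ir <- which.min(abs(ax$y - pattern$y_mm[k]))
    roi_idx <- function(i, n) {
      if (i - half_px < 1 || i + half_px > n) {
        stop("ROI extends beyond the image; need >= 8 sigma margin",
             call. = FALSE)
      }
      (i - half_px):(i + half_px)
    }
    sub <- d[roi_idx(ir, nrow(d)), roi_idx(ic, ncol(d))]
    # centroid in beam coordinates, then recenter the window on it
    xs <- ax$x[roi_idx(ic, ncol(d))]
    ys <- ax$y[roi_idx(ir, nrow(d))]
    tot <- sum(sub)
    if (tot <= 0) stop("no spots: empty ROI", call. = FALSE)
    cx <- sum(colSums(sub) * xs) / tot
    cy <- sum(rowSums(sub) * ys) / tot
    if (abs(cx - pattern$x_mm[k]) > 5 || abs(cy - pattern$y_mm[k]) > 5) {
      stop(sprintf("spot %d centroid > 5 mm from its nominal position", k),
           call. = FALSE)
    }
    ic2 <- which.min(abs(ax$x - cx))
    ir2 <- which.min(abs(ax$y - cy))
    sub2 <- d[roi_idx(ir2, nrow(d)), roi_idx(ic2, ncol(d))]
    out <- dose_plane(sub2, plane$pitch_mm, origin = c(ax$x[ic2], ax$y[ir2]),
                      z_mm = plane$z_mm, energy = plane$energy)
    attr(out, "centroid") <- c(cx, cy)
    out
  })
}

#' Equivalent average spot
#'
#' Pixelwise arithmetic mean of the five recentered spot ROIs, giving the
#' equivalent average planar dose distribution used for profile fitting.
#'
#' @param sub_images List of equally sized [dose_plane()] ROIs.
#' @return A [dose_plane()] centred at (0, 0).
#' @export
average_spot <- function(sub_images) {
  dims <- vapply(sub_images, function(p) dim(p$dose), integer(2))
  if (any(dims != dims[, 1])) stop("ROI shape mismatch", call. = FALSE)
  m <- Reduce(`+`, lapply(sub_images, `[[`, "dose")) / length(sub_images)
  p1 <- sub_images[[1]]
  dose_plane(m, p1$pitch_mm, origin = c(0, 0), z_mm = p1$z_mm,
             energy = p1$energy)
}

#' Cross-sectional profiles of a spot
#'
#' 1-D profiles through the intensity centroid row and column (nearest grid
#' line) of a centred spot image, in X and Y.
#'
#' @param spot A [dose_plane()], typically from [average_spot()].
#' @return Tibble with columns `axis` ("x"/"y"), `pos_mm`, `dose`.
#' @export
cross_sections <- function(spot) {
  stopifnot(inherits(spot, "dose_plane"))
  ax <- plane_axes(spot)
  d <- spot$dose
  tot <- sum(d)
  ic <- which.min(abs(ax$x - sum(colSums(d) * ax$x) / tot))
  ir <- which.min(abs(ax$y - sum(rowSums(d) * ax$y) / tot))
  dplyr::bind_rows(
    tibble::tibble(axis = "x", pos_mm = ax$x, dose = d[ir, ]),
    tibble::tibble(axis = "y", pos_mm = ax$y, dose = d[, ic])
  )
}

#' Fit a single Gaussian to a lateral profile
#'
#' Nonlinear least squares of \eqn{A \exp(-(x-\mu)^2 / 2\sigma^2) + b},
#' initialized from the profile moments (centroid, RMS width, minimum).
#' The baseline term absorbs any residual detector background.
#'
#' @param profile Data frame with columns `pos_mm` and `dose` (>= 10
#'   points, positive peak).
#' @return A `gaussian_fit`: list with `mu`, `sigma` (mm), `amplitude`,
#'   `baseline` and `rms_residual` (RMS residual relative to the fitted
#'   amplitude).
#' @export
fit_gaussian <- function(profile) {
  stopifnot(all(c("pos_mm", "dose") %in% names(profile)),
            nrow(profile) >= 10)
  x <- profile$pos_mm
  y <- profile$dose
  if (max(y) <= 0) stop("profile has no positive peak", call. = FALSE)
  b0 <- min(y)
  w <- pmax(y - b0, 0)
  mu0 <- sum(w * x) / sum(w)
  s0 <- sqrt(sum(w * (x - mu0)^2) / sum(w))
  # round the starts: denormal-scale or last-bit-perturbed values make
  # numericDeriv's finite-difference Jacobian spuriously rank-deficient
  if (abs(b0) < 1e-9 * max(y)) b0 <- 0
  if (abs(mu0) < 1e-9 * diff(range(x))) mu0 <- 0
  s0 <- signif(s0, 7)
  mu0 <- signif(mu0, 7)
  b0 <- signif(b0, 7)
  df <- data.frame(x = x, y = y)
  form <- y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)) + b
  lo <- c(A = 0, mu = min(x), sigma = 1e-3, b = -Inf)
  fit_lm <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(form, data = df, start = start, lower = lo,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  # Levenberg-Marquardt first; nl2sol ("port") as fallback — nlsLM can fail
  # to wrap an exact-fit (zero-residual) solution on noiseless profiles
  fit_port <- function(start) {
    tryCatch(
      stats::nls(form, data = df, start = start, lower = lo,
                 algorithm = "port",
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
  }
  start0 <- list(A = max(y) - b0, mu = mu0, sigma = s0, b = b0)
  start1 <- list(A = 1.05 * (max(y) - b0), mu = mu0 + 0.1 * s0,
                 sigma = 1.1 * s0, b = b0 + 0.01 * max(y))
  fit <- fit_lm(start0)
  if (is.null(fit)) fit <- fit_port(start0)
  if (is.null(fit)) fit <- fit_lm(start1)
  if (is.null(fit)) fit <- fit_port(start1)
  if (is.null(fit)) stop("Gaussian fit did not converge", call. = FALSE)
  cf <- as.list(stats::coef(fit))
  if (cf$sigma <= 2e-3) stop("sigma hit its lower bound", call. = FALSE)
  structure(
    list(mu = cf$mu, sigma = abs(cf$sigma), amplitude = cf$A,
         baseline = cf$b,
         rms_residual = sqrt(mean(stats::resid(fit)^2)) / cf$A),
    class = "gaussian_fit"
  )
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> mu = %.3f mm, sigma = %.3f mm, rms %.2e\n",
              x$mu, x$sigma, x$rms_residual))
  invisible(x)
}

#' Fermi--Eyges phase-space moments
#'
#' Constructs the second moments of the transverse phase space at the
#' reference plane (isocenter): spatial variance A (mm^2), spatial-angular
#' covariance B (mm mrad) and angular variance C (mrad^2). Under free
#' drift, \eqn{\sigma^2(z) = A + 2 B z + C z^2} with z in metres
#' (mrad * m = mm, so all three terms carry mm^2). B < 0 denotes a beam
#' converging towards larger z.
#'
#' @param A Spatial variance (mm^2), > 0.
#' @param B Spatial-angular covariance (mm mrad).
#' @param C Angular variance (mrad^2). Physically >= 0, but a least-squares
#'   estimate from noisy sigmas may come out slightly negative; such
#'   estimates are accepted as long as sigma^2(z) stays positive over the
#'   measurement span.
#' @param axis `"x"` or `"y"`.
#' @param z_ref Reference plane (mm); 0 = isocenter.
#' @return An object of class `optics_moments`.
#' @export
optics_moments <- function(A, B, C, axis = "x", z_ref = 0) {
  stopifnot(A > 0)
  om <- structure(
    list(A = A, B = B, C = C, axis = axis, z_ref = z_ref),
    class = "optics_moments"
  )
  zs <- seq(-300, 300, by = 10)
  if (any(sigma2_at(om, zs) <= 0)) {
    stop("moments give non-positive sigma^2 within +-300 mm", call. = FALSE)
  }
  om
}

#' @export
print.optics_moments <- function(x, ...) {
  cat(sprintf(
    "<optics_moments %s> A = %.3f mm^2, B = %.3f mm mrad, C = %.4f mrad^2\n",
    x$axis, x$A, x$B, x$C))
  invisible(x)
}

sigma2_at <- function(moments, z_mm) {
  zm <- z_mm / 1000   # metres; mm mrad * m = mm^2, mrad^2 * m^2 = mm^2
  moments$A + 2 * moments$B * zm + moments$C * zm^2
}

#' Spot sigma predicted by Fermi--Eyges moments
#'
#' @param moments An [optics_moments()].
#' @param z_mm Position(s) along the beam axis (mm from isocenter).
#' @return Sigma in mm.
#' @export
sigma_at <- function(moments, z_mm) {
  s2 <- sigma2_at(moments, z_mm)
  if (any(s2 <= 0)) stop("negative variance at requested z", call. = FALSE)
  sqrt(s2)
}

#' Fit Fermi--Eyges moments to spot sigmas across planes
#'
#' Ordinary least squares of \eqn{\sigma^2(z) = A + 2 B z + C z^2} (z in
#' metres) through the measured sigmas at the measurement planes,
#' returning the phase-space moments at the isocenter. With exact
#' quadratic data and >= 3 distinct planes the recovery is exact.
#'
#' @param sigmas Data frame with columns `z_mm` and `sigma_mm` (>= 3
#'   distinct planes, all sigma > 0).
#' @param axis `"x"` or `"y"` label carried into the result.
#' @return An [optics_moments()] with an `fit` attribute holding the
#'   underlying `lm` object.
#' @export
fit_fe_moments <- function(sigmas, axis = "x") {
  stopifnot(all(c("z_mm", "sigma_mm") %in% names(sigmas)))
  if (length(unique(sigmas$z_mm)) < 3) {
    stop("need >= 3 distinct planes", call. = FALSE)
  }
  if (any(sigmas$sigma_mm <= 0)) stop("all sigmas must be > 0", call. = FALSE)
  zm <- sigmas$z_mm / 1000
  s2 <- sigmas$sigma_mm^2
  fit <- stats::lm(s2 ~ zm + I(zm^2))
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design", call. = FALSE)
  cf <- stats::coef(fit)
  om <- optics_moments(A = unname(cf[1]), B = unname(cf[2]) / 2,
                       C = unname(cf[3]), axis = axis)
  attr(om, "fit") <- fit
  om
}

#' Relative difference in percent
#'
#' `100 * (a - b) / b`, with `b` the declared comparison baseline (e.g. the
#' measured value, or the first gantry of a cross-gantry pair).
#'
#' @param a,b Numeric; `b` must be nonzero.
#' @return Percent difference.
#' @export
relative_difference <- function(a, b) {
  if (any(b == 0)) stop("zero baseline", call. = FALSE)
  100 * (a - b) / b
}
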