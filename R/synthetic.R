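#' Gantry perturbation
#'
#' Small configurable deviations of one gantry from the nominal beamline,
#' emulating the residual differences between beam-matched delivery rooms:
#' a rigid range offset, an energy-spread scale, a per-axis spot-size
#' scale, random spot-position jitter and multiplicative dose noise.
#'
#' @param range_offset_mm Shift applied to every Bragg-peak range (mm);
#'   magnitudes up to ~0.3 mm reflect water-phantom positioning
#'   repeatability.
#' @param spectrum_sigma_scale Multiplier on the energy-spread sigma_E.
#' @param sigma_scale Multiplier on the spot sigma per axis (1.023 = +2.3%,
#'   the upper end of observed cross-gantry spot deviations).
#' @param spot_jitter_mm Standard deviation of random spot-position offsets
#'   (mm).
#' @param dose_noise Relative s.d. of multiplicative lognormal dose noise.
#' @param seed Optional integer seed recorded with the perturbation.
#' @return An object of class `gantry_perturbation`.
#' @export
gantry_perturbation <- function(range_offset_mm = 0, spectrum_sigma_scale = 1,
                                sigma_scale = 1, spot_jitter_mm = 0,
                                dose_noise = 0, seed = NULL) {
  stopifnot(spectrum_sigma_scale > 0, sigma_scale > 0,
            spot_jitter_mm >= 0, dose_noise >= 0)
  structure(
    list(range_offset_mm = range_offset_mm,
         spectrum_sigma_scale = spectrum_sigma_scale,
         sigma_scale = sigma_scale,
         spot_jitter_mm = spot_jitter_mm,
         dose_noise = dose_noise, seed = seed),
    class = "gantry_perturbation"
  )
}

#' Default perturbations of the two simulated gantries
#'
#' Gantry "GTR2" is the nominal beamline with measurement noise only;
#' "GTR4" adds a +0.3 mm range offset (phantom-positioning repeatability),
#' a 5% wider energy spread and a +2.3% spot-sigma scale — magnitudes at
#' the upper end of what beam-matched rooms exhibit, so cross-gantry
#' isocenter sigmas stay within the +-10% matching envelope.
#'
#' @param dose_noise Relative measurement noise s.d. for both gantries.
#' @return Named list of two [gantry_perturbation()] objects.
#' @export
default_gantry_perturbations <- function(dose_noise = 0.002) {
  list(
    GTR2 = gantry_perturbation(dose_noise = dose_noise,
                               spot_jitter_mm = 0.1),
    GTR4 = gantry_perturbation(range_offset_mm = 0.3,
                               spectrum_sigma_scale = 1.05,
                               sigma_scale = 1.023,
                               spot_jitter_mm = 0.1,
                               dose_noise = dose_noise)
  )
}

#' Default energy spread of the synthetic beamline
#'
#' Effective energy-spread sigma_E as a function of nominal energy:
#' 0.7% of E. A synthetic stand-in with a realistic magnitude for a
#' cyclotron + degrader line; not a reconstruction of any real machine.
#'
#' @param energy_mev Nominal energy (MeV).
#' @return sigma_E in MeV.
#' @export
default_sigma_e <- function(energy_mev) 0.007 * energy_mev

#' Default spot optics of the synthetic beamline
#'
#' Isocenter spot sigma falling log-linearly from 6 mm at 70 MeV to 3 mm
#' at 226.09 MeV, angular spread from 3 to 1.2 mrad, correlation -0.25
#' (slightly converging beam), with the y-axis sigma 5% below x. Synthetic
#' stand-ins with plausible magnitudes; the free-drift quadratic
#' \eqn{\sigma^2(z) = A + 2Bz + Cz^2} stays positive over +-300 mm by
#' construction (|B| < sqrt(AC)).
#'
#' @param energy_mev Nominal energy (MeV).
#' @return Named list of [optics_moments()] for axes `x` and `y`.
#' @export
default_moments <- function(energy_mev) {
  f <- log(energy_mev / 70) / log(226.09 / 70)
  sig_x <- exp(log(6) + f * (log(3) - log(6)))
  th <- exp(log(3) + f * (log(1.2) - log(3)))
  one <- function(sig) {
    A <- sig^2
    C <- th^2
    optics_moments(A = A, B = -0.25 * sqrt(A * C), C = C)
  }
  mx <- one(sig_x)
  my <- one(0.95 * sig_x)
  my$axis <- "y"
  list(x = mx, y = my)
}

#' Detector specifications
#'
#' `lynx_detector()`: scintillator spot-imaging detector, 300 mm x 300 mm
#' active area at 0.5 mm resolution. `matrixx_detector()`: QA
#' ionization-chamber array, 24.4 cm x 24.4 cm at 7.6 mm pixel spacing
#' (33 x 33 measurement points).
#'
#' @param size_mm Active area side length (mm).
#' @param pitch_mm Pixel pitch (mm).
#' @return List with `size_mm` and `pitch_mm`.
#' @export
lynx_detector <- function(size_mm = 300, pitch_mm = 0.5) {
  list(size_mm = size_mm, pitch_mm = pitch_mm)
}

#' @rdname lynx_detector
#' @export
matrixx_detector <- function(size_mm = 244, pitch_mm = 7.6) {
  list(size_mm = size_mm, pitch_mm = pitch_mm)
}

detector_axis <- function(detector) {
  n <- floor(detector$size_mm / detector$pitch_mm / 2)
  (-n:n) * detector$pitch_mm
}

# lognormal multiplicative noise with unit mean and relative s.d. `s`
rel_noise <- function(n, s) {
  if (s <= 0) return(rep(1, n))
  sl <- sqrt(log(1 + s^2))
  stats::rlnorm(n, meanlog = -sl^2 / 2, sdlog = sl)
}

#' Simulate a measured IDD curve
#'
#' Gaussian-weighted superposition of pristine Bragg peaks over an energy
#' grid E0 +- 4 sigma_E (0.25 MeV step), with every member range shifted
#' by the perturbation's range offset, multiplied by i.i.d. lognormal
#' noise, and renormalized to unit maximum. With sigma_E = 0 and zero
#' noise this reduces to the pristine peak at R(E0).
#'
#' @param energy_mev Nominal energy E0 (MeV).
#' @param sigma_e Energy spread (MeV); defaults to [default_sigma_e()]
#'   scaled by the perturbation.
#' @param perturbation A [gantry_perturbation()].
#' @param config A [beamline_config()].
#' @param seed Integer seed (noise reproducibility).
#' @return An [idd_curve] on the configuration depth grid.
#' @export
simulate_idd <- function(energy_mev,
                         sigma_e = default_sigma_e(energy_mev) *
                           perturbation$spectrum_sigma_scale,
                         perturbation = gantry_perturbation(),
                         config = beamline_config(), seed = 1) {
  stopifnot(sigma_e >= 0)
  grid <- depth_grid(config)
  shift_cm <- perturbation$range_offset_mm / 10
  if (sigma_e == 0) {
    dose <- mono_bragg(range_from_energy(energy_mev, config) + shift_cm,
                       grid, config)$dose
  } else {
    es <- seq(energy_mev - 4 * sigma_e, energy_mev + 4 * sigma_e, by = 0.25)
    wts <- stats::dnorm(es, energy_mev, sigma_e)
    wts <- wts / sum(wts)
    dose <- rep(0, length(grid))
    for (i in seq_along(es)) {
      dose <- dose + wts[i] *
        mono_bragg(range_from_energy(es[i], config) + shift_cm,
                   grid, config)$dose
    }
  }
  dose <- withr::with_seed(seed, dose * rel_noise(length(dose),
                                                  perturbation$dose_noise))
  normalize_unity(idd_curve(grid, dose, nominal_energy = energy_mev))
}

#' Simulate 5-spot planar images across measurement planes
#'
#' Renders the 5-spot test pattern at each plane z as cylindrical
#' Gaussians whose per-axis sigma follows the free-drift law
#' sigma(z) = sqrt(A + 2Bz + Cz^2) scaled by the perturbation, with equal
#' spot amplitudes, random position jitter, multiplicative dose noise and
#' an additive Gaussian detector floor at 0.1% of the image maximum.
#'
#' @param energy_mev Nominal energy (MeV).
#' @param moments Named list of x/y [optics_moments()]; defaults to
#'   [default_moments()].
#' @param pattern Spot positions, as [spot_pattern()].
#' @param detector A [lynx_detector()]-style spec.
#' @param perturbation A [gantry_perturbation()].
#' @param z_planes_mm Plane positions (mm from isocenter).
#' @param seed Integer seed.
#' @return List of [dose_plane()] objects, one per plane.
#' @export
simulate_spot_planes <- function(energy_mev,
                                 moments = default_moments(energy_mev),
                                 pattern = spot_pattern(),
                                 detector = lynx_detector(),
                                 perturbation = gantry_perturbation(),
                                 z_planes_mm = c(-300, -150, 0, 150, 300),
                                 seed = 1) {
  stopifnot(length(z_planes_mm) >= 1)
  sc <- perturbation$sigma_scale
  if (any(sigma2_at(moments$x, z_planes_mm) <= 0) ||
      any(sigma2_at(moments$y, z_planes_mm) <= 0)) {
    stop("moments give non-positive variance at a requested plane",
         call. = FALSE)
  }
  ax <- detector_axis(detector)
  withr::with_seed(seed, {
    lapply(z_planes_mm, function(z) {
      sx <- sc * sigma_at(moments$x, z)
      sy <- sc * sigma_at(moments$y, z)
      img <- matrix(0, nrow = length(ax), ncol = length(ax))
      for (k in seq_len(nrow(pattern))) {
        jx <- stats::rnorm(1, 0, perturbation$spot_jitter_mm)
        jy <- stats::rnorm(1, 0, perturbation$spot_jitter_mm)
        gx <- exp(-(ax - pattern$x_mm[k] - jx)^2 / (2 * sx^2))
        gy <- exp(-(ax - pattern$y_mm[k] - jy)^2 / (2 * sy^2))
        img <- img + outer(gy, gx) / (2 * pi * sx * sy)
      }
      img <- img * matrix(rel_noise(length(img), perturbation$dose_noise),
                          nrow = nrow(img))
      if (perturbation$dose_noise > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, 0.001 * max(img)),
                            nrow = nrow(img))
        img <- pmax(img, 0)
      }
      dose_plane(img, detector$pitch_mm, origin = c(0, 0), z_mm = z,
                 energy = energy_mev)
    })
  })
}

#' Simulate a full gantry commissioning dataset
#'
#' Generates one measured IDD curve per nominal energy and, optionally,
#' the 5-spot planar images at the five measurement planes, for one
#' simulated gantry under a fixed perturbation. Per-energy sub-seeds are
#' derived deterministically from `seed`, so equal seeds give identical
#' datasets.
#'
#' @param gantry_id Label, e.g. `"GTR2"`.
#' @param perturbation A [gantry_perturbation()].
#' @param config A [beamline_config()].
#' @param seed Integer seed.
#' @param energies Nominal energies (MeV); default the 33-point grid.
#' @param include_spots Generate spot planes too (memory-heavy at full
#'   detector resolution); default `TRUE`.
#' @param detector Spot-imaging detector spec.
#' @return A `gantry_dataset`: list with `gantry_id`, `energies`,
#'   `idd` (named list of [idd_curve]), `spots` (named list of plane
#'   lists), `perturbation`, `config`.
#' @export
simulate_gantry <- function(gantry_id = "GTR2",
                            perturbation = gantry_perturbation(),
                            config = beamline_config(), seed = 1,
                            energies = standard_energy_grid(),
                            include_spots = TRUE,
                            detector = lynx_detector(),
                            pattern = spot_pattern()) {
  nm <- sprintf("%.2f", energies)
  idd <- lapply(seq_along(energies), function(i) {
    simulate_idd(energies[i], perturbation = perturbation, config = config,
                 seed = (seed * 1009L + i) %% 2147483647L)
  })
  names(idd) <- nm
  spots <- NULL
  if (include_spots) {
    spots <- lapply(seq_along(energies), function(i) {
      simulate_spot_planes(energies[i], perturbation = perturbation,
                           pattern = pattern, detector = detector,
                           seed = (seed * 2003L + i) %% 2147483647L)
    })
    names(spots) <- nm
  }
  structure(
    list(gantry_id = gantry_id, energies = energies, idd = idd,
         spots = spots, pattern = pattern, perturbation = perturbation,
         config = config, seed = seed),
    class = "gantry_dataset"
  )
}

#' @export
print.gantry_dataset <- function(x, ...) {
  cat(sprintf("<gantry_dataset %s> %d energies, %s spot planes\n",
              x$gantry_id, length(x$energies),
              if (is.null(x$spots)) "no" else
                sprintf("%d x %d", length(x$spots),
                        length(x$spots[[1]]))))
  invisible(x)
}

#' QA field specification for a treatment-site cohort
#'
#' Builds a square single-layer spot field emulating the planar dose of an
#' IMPT verification plan at one measurement depth. Site templates are
#' synthetic stand-ins (field size and in-water spot sigma chosen as
#' typical for each site); per-plan variability is drawn around the
#' template.
#'
#' @param cohort One of `"prostate"`, `"lung"`, `"NPC"`.
#' @param seed Integer seed for the per-plan variation.
#' @return A `qa_field`: tibble of spots (`x_mm`, `y_mm`, `weight`,
#'   `sigma_mm`) with the cohort stored as an attribute.
#' @export
qa_field <- function(cohort = c("prostate", "lung", "NPC"), seed = 1) {
  cohort <- match.arg(cohort)
  tmpl <- switch(cohort,
    prostate = list(half = 40, sigma = 6.5),
    lung     = list(half = 30, sigma = 5.5),
    NPC      = list(half = 55, sigma = 5.0))
  withr::with_seed(seed, {
    half <- tmpl$half * stats::runif(1, 0.85, 1.15)
    sigma <- tmpl$sigma * stats::runif(1, 0.9, 1.1)
    pitch <- sigma                     # spot spacing = sigma: flat field
    pos <- seq(-half, half, by = pitch)
    spots <- tidyr::expand_grid(x_mm = pos, y_mm = pos)
    # mild edge enhancement, as optimized IMPT layers show
    edge <- (abs(spots$x_mm) > half - pitch) | (abs(spots$y_mm) > half - pitch)
    spots$weight <- ifelse(edge, 1.35, 1) * stats::runif(nrow(spots), 0.97, 1.03)
    spots$sigma_mm <- sigma
  })
  attr(spots, "cohort") <- cohort
  class(spots) <- c("qa_field", class(spots))
  spots
}

render_field <- function(field, ax, sigma_scale = 1, dx = 0, dy = 0,
                         jitter = NULL) {
  img <- matrix(0, nrow = length(ax), ncol = length(ax))
  for (k in seq_len(nrow(field))) {
    s <- field$sigma_mm[k] * sigma_scale
    jx <- if (is.null(jitter)) 0 else jitter$x[k]
    jy <- if (is.null(jitter)) 0 else jitter$y[k]
    gx <- exp(-(ax - field$x_mm[k] - dx - jx)^2 / (2 * s^2))
    gy <- exp(-(ax - field$y_mm[k] - dy - jy)^2 / (2 * s^2))
    img <- img + field$weight[k] * outer(gy, gx) / (2 * pi * s^2)
  }
  img
}

#' Simulate a patient-specific QA plane pair
#'
#' Returns the TPS-computed plane (sum of spot Gaussians on a 1 mm grid)
#' and the "delivered" plane measured on the QA array: the same field with
#' the perturbation applied (spot sigma scaled, a rigid position offset
#' drawn per plan from the jitter s.d. — measurement-position uncertainty
#' is dominated by water-phantom setup, so it displaces the whole plane —
#' and a range-driven global amplitude change of 2%/mm of range offset),
#' sampled at the array pitch with multiplicative noise.
#'
#' @param field A [qa_field()].
#' @param perturbation A [gantry_perturbation()] describing the
#'   model-to-delivery discrepancy.
#' @param detector QA array spec, default [matrixx_detector()].
#' @param seed Integer seed.
#' @param computed_pitch_mm Calculation grid resolution (mm).
#' @return List with `computed` and `measured` [dose_plane()] objects.
#' @export
simulate_qa_pair <- function(field, perturbation = gantry_perturbation(),
                             detector = matrixx_detector(), seed = 1,
                             computed_pitch_mm = 1) {
  ax_meas <- detector_axis(detector)
  margin <- 12   # mm beyond the array, so gamma search never runs off-grid
  nfine <- ceiling((max(ax_meas) + margin) / computed_pitch_mm)
  ax_comp <- (-nfine:nfine) * computed_pitch_mm
  computed <- render_field(field, ax_comp)
  withr::with_seed(seed, {
    setup <- stats::rnorm(2, 0, perturbation$spot_jitter_mm)
    delivered <- render_field(field, ax_meas,
                              sigma_scale = perturbation$sigma_scale,
                              dx = setup[1], dy = setup[2])
    amp <- 1 + 0.02 * perturbation$range_offset_mm
    delivered <- amp * delivered *
      matrix(rel_noise(length(delivered), perturbation$dose_noise),
             nrow = nrow(delivered))
  })
  list(
    computed = dose_plane(computed, computed_pitch_mm, z_mm = 0),
    measured = dose_plane(delivered, detector$pitch_mm, z_mm = 0)
  )
}
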