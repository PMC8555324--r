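# Spot extraction, averaging, Gaussian profile fits and Fermi-Eyges optics.

test_that("spots are extracted at generator positions and averaged cleanly", {
  planes <- simulate_small_planes(seed = 1)   # noiseless, jitter-free
  pl <- planes[[3]]                           # isocenter
  rois <- extract_spots(pl, small_pattern(), nominal_sigma_mm = 3)
  expect_length(rois, 5)
  for (k in 1:5) {
    cen <- attr(rois[[k]], "centroid")
    expect_lt(abs(cen[1] - small_pattern()$x_mm[k]), 0.1)
    expect_lt(abs(cen[2] - small_pattern()$y_mm[k]), 0.1)
  }
  dims <- vapply(rois, function(r) dim(r$dose), integer(2))
  expect_true(all(dims == dims[, 1]))
  # noiseless identical spots: average equals each ROI
  avg <- average_spot(rois)
  expect_equal(avg$dose, rois[[1]]$dose, tolerance = 1e-9)
  # permutation invariance
  avg2 <- average_spot(rev(rois))
  expect_equal(avg$dose, avg2$dose)

  empty <- dose_plane(matrix(0, 161, 161), 1)
  expect_error(extract_spots(empty, small_pattern(), nominal_sigma_mm = 3),
               "no spots")
  expect_error(extract_spots(pl, spot_pattern(spacing_mm = 10),
                             nominal_sigma_mm = 3), "overlap")
})

test_that("averaging five spots reduces i.i.d. noise s.d. by about sqrt(5)", {
  ratios <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      rois <- replicate(5, matrix(stats::rnorm(900), 30, 30), simplify = FALSE)
      stats::sd(rois[[1]]) / stats::sd(Reduce(`+`, rois) / 5)
    })
  }, numeric(1))
  expect_equal(mean(ratios), sqrt(5), tolerance = 0.05)
  expect_true(all(ratios > 1))   # averaging never increases noise
})

test_that("cross sections of an isotropic spot agree between axes", {
  spot <- direct_spot_image(4.0)
  prof <- cross_sections(spot)
  fx <- fit_gaussian(prof[prof$axis == "x", ])
  fy <- fit_gaussian(prof[prof$axis == "y", ])
  expect_equal(fx$sigma, fy$sigma, tolerance = 0.01)
  expect_equal(nrow(prof), 2 * ncol(spot$dose))
  # profile maximum at the centre pixel
  px <- prof[prof$axis == "x", ]
  expect_lt(abs(px$pos_mm[which.max(px$dose)]), spot$pitch_mm + 1e-9)
})

test_that("Gaussian profile fit recovers sigma exactly and is scale-free", {
  x <- seq(-30, 30, by = 0.5)
  prof <- tibble::tibble(pos_mm = x, dose = exp(-(x - 1.2)^2 / (2 * 4^2)))
  f <- fit_gaussian(prof)
  expect_lt(abs(f$sigma - 4), 0.01)
  expect_lt(abs(f$mu - 1.2), 0.01)
  f2 <- fit_gaussian(dplyr::mutate(prof, dose = 2 * dose))
  expect_equal(f2$sigma, f$sigma, tolerance = 1e-6)
  expect_equal(f2$mu, f$mu, tolerance = 1e-6)
  # baseline shift absorbed by the fit
  f3 <- fit_gaussian(dplyr::mutate(prof, dose = dose + 0.05))
  expect_equal(f3$sigma, f$sigma, tolerance = 1e-4)
})

test_that("sigma estimates stay unbiased to <0.5% under 1% profile noise", {
  x <- seq(-30, 30, by = 0.5)
  clean <- exp(-x^2 / (2 * 4^2))
  sig <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      fit_gaussian(tibble::tibble(
        pos_mm = x, dose = clean + 0.01 * stats::rnorm(length(x))))$sigma
    })
  }, numeric(1))
  expect_lt(abs(mean(sig) - 4) / 4, 0.005)
})

test_that("Fermi-Eyges fit recovers exact quadratics and degenerate cases", {
  z <- c(-300, -150, 0, 150, 300)
  A <- 9; B <- -2; C <- 1
  s <- sqrt(A + 2 * B * z / 1000 + C * (z / 1000)^2)
  om <- fit_fe_moments(tibble::tibble(z_mm = z, sigma_mm = s), axis = "x")
  expect_equal(om$A, A, tolerance = 1e-9)
  expect_equal(om$B, B, tolerance = 1e-9)
  expect_equal(om$C, C, tolerance = 1e-9)
  # constant sigma: pure spatial variance
  om2 <- fit_fe_moments(tibble::tibble(z_mm = z, sigma_mm = rep(3, 5)))
  expect_equal(om2$A, 9, tolerance = 1e-9)
  expect_equal(om2$B, 0, tolerance = 1e-9)
  expect_equal(om2$C, 0, tolerance = 1e-9)
  expect_error(fit_fe_moments(tibble::tibble(z_mm = c(0, 1), sigma_mm = c(1, 1))),
               "planes")
})

test_that("sigma_at round-trips with the moment fit and is symmetric", {
  om <- optics_moments(A = 9, B = 0, C = 1)
  expect_equal(sigma_at(om, 0), 3)
  expect_equal(sigma_at(om, 200), sigma_at(om, -200))
  om2 <- optics_moments(A = 12, B = -1.5, C = 1.2, axis = "y")
  z <- c(-300, -150, 0, 150, 300)
  refit <- fit_fe_moments(tibble::tibble(z_mm = z, sigma_mm = sigma_at(om2, z)),
                          axis = "y")
  expect_equal(refit$A, om2$A, tolerance = 1e-9)
  expect_equal(refit$B, om2$B, tolerance = 1e-9)
  expect_equal(refit$C, om2$C, tolerance = 1e-9)
  # strongly convergent moments rejected: sigma^2 crosses zero in range
  expect_error(optics_moments(A = 1, B = -8, C = 1), "sigma")
})

test_that("moment recovery under 0.5% sigma noise meets precision targets", {
  z <- c(-300, -150, 0, 150, 300)
  truth <- optics_moments(A = 16, B = -1.8, C = 2.2)
  s0 <- sigma_at(truth, z)
  fits <- purrr::map_dfr(1:100, function(s) {
    withr::with_seed(1000 + s, {
      sn <- s0 * (1 + 0.005 * stats::rnorm(5))
      om <- fit_fe_moments(tibble::tibble(z_mm = z, sigma_mm = sn))
      tibble::tibble(A = om$A, C = om$C)
    })
  })
  expect_lt(abs(mean(fits$A) - truth$A) / truth$A, 0.02)
  expect_lt(abs(mean(fits$C) - truth$C) / truth$C, 0.10)
})

test_that("relative difference uses the declared baseline", {
  expect_equal(relative_difference(10.23, 10.23), 0)
  expect_equal(relative_difference(11, 10), 10)
  expect_equal(relative_difference(10, 11), -100 / 11, tolerance = 1e-9)
  expect_error(relative_difference(1, 0), "baseline")
})
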