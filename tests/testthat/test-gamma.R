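# 1-D and 2-D gamma engine: identities, analytic cases, brute-force oracles.

smooth_curve <- function(n = 50, seed = 1, step = 1) {
  withr::with_seed(seed, {
    z <- seq(0, by = step, length.out = n)
    y <- exp(-(z - n * step * 0.6)^2 / (2 * (n * step / 8)^2)) +
      0.05 * stats::spline(seq(0, n * step, length.out = 8),
                           stats::rnorm(8), xout = z)$y
    idd_curve(z, pmax(y, 0) / max(pmax(y, 0)))
  })
}

test_that("gamma of a curve with itself is zero with 100% passing", {
  ref <- smooth_curve(seed = 2)
  g <- gamma_1d(ref, ref, gamma_criteria(1, 1))
  expect_equal(g$passing_rate, 100)
  expect_equal(g$mean_gamma, 0, tolerance = 1e-12)
})

test_that("a pure 1 mm shift passes 1 mm/1% at the DTA boundary", {
  pk <- mono_bragg(15)
  shifted <- idd_curve(pk$depth_mm, c(pk$dose[-(1:10)], rep(0, 10)))
  # shifted is pk moved 1.0 mm proximally on the same grid
  g <- gamma_1d(pk, shifted, gamma_criteria(1, 1))
  gg <- g$gamma_values[g$evaluated]
  expect_true(all(gg <= 1 + 1e-6))
  expect_equal(g$passing_rate, 100)
})

test_that("1-D gamma equals an exhaustive brute-force search", {
  crit <- gamma_criteria(1, 1)
  for (seed in 1:3) {
    ref <- smooth_curve(50, seed = seed, step = 0.5)
    ev <- smooth_curve(50, seed = seed + 10, step = 0.5)
    ev <- idd_curve(ev$depth_mm, 0.9 * ref$dose + 0.1 * ev$dose)
    g <- gamma_1d(ref, ev, crit)
    # oracle: exhaustive search over the full fine evaluated grid (dta/10
    # sampling, no search window); the pairs here put every true minimum
    # well inside the engine's 3*dta window, so the two must agree
    zf <- seq(0, 24.5, by = 0.1)
    df <- stats::splinefun(ev$depth_mm, ev$dose, method = "fmm")(zf)
    oracle <- vapply(seq_len(nrow(ref)), function(i) {
      min(sqrt((zf - ref$depth_mm[i])^2 / crit$dta_mm^2 +
                 (100 * (df - ref$dose[i]) / max(ref$dose))^2 /
                   crit$dose_diff_pct^2))
    }, numeric(1))
    expect_equal(g$gamma_values, oracle, tolerance = 1e-6)
  }
})

test_that("2-D gamma identities and the uniform-offset analytic case", {
  img <- matrix(1, 21, 21)
  ref <- dose_plane(img, pitch_mm = 2)
  expect_equal(gamma_2d(ref, ref, gamma_criteria(3, 3))$passing_rate, 100)
  # additive offset of 3% of the global maximum on a flat plane: gamma = 1
  ev <- dose_plane(img + 0.03, pitch_mm = 2)
  g <- gamma_2d(ref, ev, gamma_criteria(3, 3))
  expect_equal(max(abs(g$gamma_values[g$evaluated] - 1)), 0, tolerance = 1e-6)
  expect_equal(g$passing_rate, 100)
})

test_that("2-D gamma matches a brute-force fine-grid oracle", {
  crit <- gamma_criteria(2, 2)
  for (seed in 1:4) {
    withr::with_seed(seed, {
      base <- matrix(stats::rnorm(25), 5, 5)
      sm <- function(m) {
        k <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3)
        out <- m
        for (i in 2:4) for (j in 2:4) {
          out[i, j] <- sum(m[(i - 1):(i + 1), (j - 1):(j + 1)] * k)
        }
        out
      }
      rimg <- abs(sm(base)) + 1
      eimg <- rimg * (1 + 0.01 * matrix(stats::rnorm(25), 5, 5))
    })
    ref <- dose_plane(rimg, pitch_mm = 2)
    ev <- dose_plane(eimg, pitch_mm = 2)
    g <- gamma_2d(ref, ev, crit)
    # oracle: exhaustive search over a square fine-offset grid wider than
    # the engine's search disk, with its own scalar bilinear interpolation
    h <- crit$dta_mm / 10
    axr <- plane_axes(ref)
    axe <- plane_axes(ev)
    bilin <- function(x, y) {
      fx <- (x - axe$x[1]) / ev$pitch_mm
      fy <- (y - axe$y[1]) / ev$pitch_mm
      if (fx < 0 || fx > 4 || fy < 0 || fy > 4) return(NA_real_)
      i0 <- min(floor(fy), 3); j0 <- min(floor(fx), 3)
      tx <- fx - j0; ty <- fy - i0
      eimg[i0 + 1, j0 + 1] * (1 - tx) * (1 - ty) +
        eimg[i0 + 1, j0 + 2] * tx * (1 - ty) +
        eimg[i0 + 2, j0 + 1] * (1 - tx) * ty +
        eimg[i0 + 2, j0 + 2] * tx * ty
    }
    fine <- expand.grid(x = seq(-6, 6, by = h), y = seq(-6, 6, by = h))
    oracle <- matrix(NA_real_, 5, 5)
    for (i in 1:5) for (j in 1:5) {
      gbest <- Inf
      for (k in seq_len(nrow(fine))) {
        de <- bilin(axr$x[j] + fine$x[k], axr$y[i] + fine$y[k])
        if (is.na(de)) next
        gbest <- min(gbest, sqrt(
          (fine$x[k]^2 + fine$y[k]^2) / crit$dta_mm^2 +
            (100 * (de - rimg[i, j]) / max(rimg))^2 / crit$dose_diff_pct^2))
      }
      oracle[i, j] <- gbest
    }
    expect_equal(g$gamma_values, oracle, tolerance = 1e-4)
  }
})

test_that("gamma summaries, thresholds and criteria behave monotonically", {
  r <- pbsmatch:::new_gamma_result(c(0.5, 1.0, 1.5), rep(TRUE, 3),
                                   gamma_criteria(1, 1))
  s <- gamma_summary(r)
  expect_equal(s$passing_rate, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(s$mean_gamma, 1.0)

  pk <- mono_bragg(15)
  ev <- idd_curve(pk$depth_mm, pmin(pk$dose * 1.02, 1))
  tight <- gamma_1d(pk, ev, gamma_criteria(1, 1))
  loose_dd <- gamma_1d(pk, ev, gamma_criteria(1, 2))
  loose_dta <- gamma_1d(pk, ev, gamma_criteria(2, 1))
  expect_gte(loose_dd$passing_rate, tight$passing_rate)
  expect_gte(loose_dta$passing_rate, tight$passing_rate)

  # threshold excludes low-dose points, never adds any
  th <- gamma_1d(pk, ev, gamma_criteria(1, 1, 10))
  expect_lte(th$n_evaluated, tight$n_evaluated)

  # global normalization: invariant under joint rescaling
  g1 <- gamma_1d(pk, ev, gamma_criteria(1, 1))
  g2 <- gamma_1d(idd_curve(pk$depth_mm, 2 * pk$dose),
                 idd_curve(ev$depth_mm, 2 * ev$dose), gamma_criteria(1, 1))
  expect_equal(g1$gamma_values, g2$gamma_values, tolerance = 1e-12)
})
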