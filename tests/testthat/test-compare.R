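# Orchestrated comparisons, QA study table and paired statistics.

make_pair <- function(energies = c(100, 180), seed = 5, spots = FALSE) {
  perts <- default_gantry_perturbations()
  list(
    a = simulate_gantry("GTR2", perts$GTR2, seed = seed, energies = energies,
                        include_spots = spots, detector = small_detector(),
                        pattern = small_pattern()),
    b = simulate_gantry("GTR4", perts$GTR4, seed = seed + 1,
                        energies = energies, include_spots = spots,
                        detector = small_detector(), pattern = small_pattern())
  )
}

test_that("IDD comparison emits all kinds and is zero for identical gantries", {
  g <- make_pair()
  rows <- run_idd_comparison(g$a, g$a)
  expect_setequal(unique(rows$kind),
                  c("measured-vs-computed", "measured-vs-measured",
                    "computed-vs-computed"))
  expect_equal(nrow(rows), 2 * 4)   # 2 energies x (2 intra + 2 cross)
  cross <- rows[rows$kind != "measured-vs-computed", ]
  expect_true(all(cross$mean_gamma < 1e-9))
  expect_true(all(cross$passing_rate == 100))
})

test_that("intra-gantry reconstruction passes 1 mm/1% on a default gantry", {
  g <- make_pair()
  rows <- run_idd_comparison(g$a, g$b)
  intra <- rows[rows$kind == "measured-vs-computed", ]
  expect_true(all(intra$passing_rate == 100))
  expect_true(all(intra$mean_gamma < 0.5))
  # R80 increases with energy and R80 energy tracks the nominal energy
  for (gid in c("GTR2", "GTR4")) {
    sub <- intra[intra$gantry == gid, ]
    expect_true(all(diff(sub$r80_mm) > 0))
    expect_lt(max(abs(sub$r80_energy_mev - sub$energy_mev)), 2)
  }
})

test_that("inflated model residuals degrade model-model agreement most", {
  # fitting with a deliberately coarse spectrum basis inflates the model
  # residual; the error propagates to the computed curves, so the
  # computed-vs-computed deviation grows past measured-vs-measured
  g <- make_pair()
  coarse <- run_idd_comparison(g$a, g$b, basis_step = 4)
  mvm <- mean(coarse$mean_gamma[coarse$kind == "measured-vs-measured"])
  cvc <- mean(coarse$mean_gamma[coarse$kind == "computed-vs-computed"])
  expect_gt(cvc, mvm)
})

test_that("optics comparison vanishes for identical gantries and summarizes exactly", {
  g <- make_pair(energies = 150, spots = TRUE)
  out <- run_optics_comparison(g$a, g$a)
  expect_true(all(abs(out$sigmas$cross_measured_pct) < 1e-9))
  expect_true(all(abs(out$moments$spatial_var_diff_pct) < 1e-9))
  s <- out$summary
  expect_equal(s$mean[s$metric == "cross_iso_sigma_measured_pct"], 0)
  # aggregation identity
  expect_equal(s$mean[s$metric == "intra_sigma_rel_diff_pct_a"],
               mean(out$sigmas$intra_rel_diff_pct_a))
  expect_equal(s$max[s$metric == "intra_sigma_rel_diff_pct_a"],
               max(out$sigmas$intra_rel_diff_pct_a))
})

test_that("cross-gantry isocenter sigma differences respect the envelope", {
  g <- make_pair(energies = 150, spots = TRUE)
  out <- run_optics_comparison(g$a, g$b)
  iso <- out$sigmas[out$sigmas$z_mm == 0, ]
  expect_true(all(abs(iso$cross_measured_pct) < 10))
  expect_true(all(abs(iso$cross_computed_pct) < 10))
})

test_that("QA study produces the four arms with monotone criteria", {
  rec <- run_qa_study(n_per_cohort = 2, seed = 3, cohorts = "lung")
  expect_setequal(unique(rec$arm), c("M2G2", "M2G4", "M4G2", "M4G4"))
  expect_equal(nrow(rec), 2 * 4 * 2)
  wide <- tidyr::pivot_wider(rec, id_cols = c("plan_id", "arm"),
                             names_from = "criteria",
                             values_from = "passing_rate")
  expect_true(all(wide$`3 mm/3% (10% threshold)` >=
                    wide$`2 mm/3% (10% threshold)`))
  expect_true(all(rec$passing_rate >= 0 & rec$passing_rate <= 100))
})

test_that("zero machine differences give 100% QA passing in every arm", {
  flat <- qa_machine_defaults()
  flat$sigma_scale <- 1
  flat$range_offset_mm <- 0
  rec <- run_qa_study(n_per_cohort = 2, seed = 5, cohorts = "prostate",
                      machine = flat, jitter_mm = 0, dose_noise = 0)
  expect_true(all(rec$passing_rate == 100))
})

test_that("paired statistics match textbook formulas and self-comparison", {
  # constructed QA records with per-plan variation (12 plans, one cohort)
  rec <- withr::with_seed(31, {
    base <- 97 + stats::rnorm(12, 0, 1.5)
    dplyr::bind_rows(
      tibble::tibble(plan_id = sprintf("p%02d", 1:12), cohort = "lung",
                     model = "GTR2", delivered = "GTR2", arm = "M2G2",
                     criteria = "2 mm/3%",
                     passing_rate = pmin(base + stats::rnorm(12, 0.2, 0.4), 100)),
      tibble::tibble(plan_id = sprintf("p%02d", 1:12), cohort = "lung",
                     model = "GTR4", delivered = "GTR2", arm = "M4G2",
                     criteria = "2 mm/3%",
                     passing_rate = pmin(base + stats::rnorm(12, 0, 0.4), 100))
    )
  })
  st <- paired_model_stats(rec, c("M2G2", "M4G2"))
  expect_equal(nrow(st), 1)
  # oracle: direct formula evaluation of paired t and Pearson r
  w <- tidyr::pivot_wider(rec, id_cols = "plan_id", names_from = "arm",
                          values_from = "passing_rate")
  dif <- w$M2G2 - w$M4G2
  t_oracle <- mean(dif) / (stats::sd(dif) / sqrt(length(dif)))
  x <- w$M2G2 - mean(w$M2G2); y <- w$M4G2 - mean(w$M4G2)
  r_oracle <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  expect_equal(st$mean_diff, mean(dif), tolerance = 1e-12)
  expect_equal(st$t, t_oracle, tolerance = 1e-9)
  expect_equal(st$pearson_r, r_oracle, tolerance = 1e-9)
  # an arm against itself: zero difference, perfect correlation
  self <- paired_model_stats(rec, c("M2G2", "M2G2"))
  expect_true(all(self$mean_diff == 0))
  expect_true(all(self$pearson_r == 1))
  # unpaired input rejected
  expect_error(paired_model_stats(rec[-1, ], c("M2G2", "M4G2")), "paired")
})

test_that("paired t-test is calibrated under the null", {
  # two arms differing only by independent measurement noise
  p_vals <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      base <- 97 + stats::rnorm(12, 0, 1.5)
      a <- pmin(base + stats::rnorm(12, 0, 0.5), 100)
      b <- pmin(base + stats::rnorm(12, 0, 0.5), 100)
      stats::t.test(a, b, paired = TRUE)$p.value
    })
  }, numeric(1))
  expect_gte(mean(p_vals > 0.05), 0.90)
})

test_that("report rendering is deterministic and round-trips the manifest", {
  g <- make_pair()
  rows <- run_idd_comparison(g$a, g$b)
  rec <- run_qa_study(n_per_cohort = 2, seed = 3, cohorts = "lung")
  man <- list(seed = 3, config = list(alpha = 0.0022, p = 1.77))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  render_report(rows, NULL, rec, NULL, out_dir = d1, manifest = man)
  render_report(rows, NULL, rec, NULL, out_dir = d2, manifest = man)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  got <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(got$seed, man$seed)
  expect_equal(got$config$alpha, man$config$alpha)
  # empty inputs still produce tables with headers
  d3 <- withr::local_tempdir()
  render_report(out_dir = d3)
  qa <- utils::read.csv(file.path(d3, "qa_records.csv"))
  expect_equal(nrow(qa), 0)
  expect_true("passing_rate" %in% names(qa))
})
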