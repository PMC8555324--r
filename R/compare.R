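#' Intra- and cross-gantry IDD comparison
#'
#' For each gantry the measured curve at each nominal energy is fitted to
#' an effective energy spectrum (NNLS against the pristine-peak basis) and
#' reconstructed into the model-computed curve. Gamma analysis is then run
#' for the three comparison kinds: each gantry's measured vs computed
#' curve (intra-gantry), the two gantries' measured curves, and the two
#' gantries' computed curves (cross-gantry; gantry A is the reference).
#'
#' @param gantry_a,gantry_b [simulate_gantry()] datasets on the same
#'   energy grid (or a single gantry with `gantry_b = NULL` for
#'   intra-gantry rows only).
#' @param criteria A [gamma_criteria()]; default 1 mm/1%.
#' @param basis_half_width,basis_step Spectrum basis span and spacing
#'   (MeV).
#' @return Tibble with one row per (energy, comparison kind): `energy_mev`,
#'   `kind`, `gantry`, `passing_rate`, `mean_gamma`, `r80_mm`,
#'   `r80_energy_mev` (the latter two for measured curves).
#' @export
run_idd_comparison <- function(gantry_a, gantry_b = NULL,
                               criteria = gamma_criteria(1, 1),
                               basis_half_width = 10, basis_step = 0.5) {
  stopifnot(inherits(gantry_a, "gantry_dataset"))
  if (!is.null(gantry_b)) {
    stopifnot(inherits(gantry_b, "gantry_dataset"))
    if (!isTRUE(all.equal(gantry_a$energies, gantry_b$energies))) {
      stop("gantries must share the nominal energy grid", call. = FALSE)
    }
  }
  cfg <- gantry_a$config
  one_gantry <- function(g) {
    purrr::map(seq_along(g$energies), function(i) {
      e <- g$energies[i]
      basis <- build_basis(e, basis_half_width, basis_step,
                           grid_mm = g$idd[[i]]$depth_mm, config = cfg)
      spec <- fit_spectrum(g$idd[[i]], basis)
      list(energy = e, measured = g$idd[[i]], spectrum = spec,
           computed = reconstruct_idd(spec, basis),
           r80 = r80(g$idd[[i]]), r80_e = r80_energy(spec, basis))
    })
  }
  fa <- one_gantry(gantry_a)
  fb <- if (!is.null(gantry_b)) one_gantry(gantry_b)
  row <- function(e, kind, gantry, ref, ev, r80_mm = NA, r80_e = NA) {
    gs <- gamma_summary(gamma_1d(ref, ev, criteria))
    tibble::tibble(energy_mev = e, kind = kind, gantry = gantry,
                   passing_rate = gs$passing_rate,
                   mean_gamma = gs$mean_gamma,
                   r80_mm = r80_mm, r80_energy_mev = r80_e)
  }
  rows <- purrr::map(seq_along(fa), function(i) {
    a <- fa[[i]]
    out <- list(row(a$energy, "measured-vs-computed", gantry_a$gantry_id,
                    a$measured, a$computed, a$r80, a$r80_e))
    if (!is.null(fb)) {
      b <- fb[[i]]
      out <- c(out, list(
        row(b$energy, "measured-vs-computed", gantry_b$gantry_id,
            b$measured, b$computed, b$r80, b$r80_e),
        row(a$energy, "measured-vs-measured",
            paste(gantry_a$gantry_id, gantry_b$gantry_id, sep = "-"),
            a$measured, b$measured),
        row(a$energy, "computed-vs-computed",
            paste(gantry_a$gantry_id, gantry_b$gantry_id, sep = "-"),
            a$computed, b$computed)))
    }
    dplyr::bind_rows(out)
  })
  dplyr::bind_rows(rows)
}

#' Spot sigma table of a gantry dataset
#'
#' Runs the full spot pipeline for every energy and plane: extract the
#' five spots, average them, take X/Y cross sections and fit single
#' Gaussians.
#'
#' @param gantry A [simulate_gantry()] dataset with spot planes.
#' @return Tibble with `energy_mev`, `z_mm`, `axis`, `sigma_mm`, `mu_mm`.
#' @export
spot_sigma_table <- function(gantry) {
  stopifnot(inherits(gantry, "gantry_dataset"))
  if (is.null(gantry$spots)) stop("dataset has no spot planes", call. = FALSE)
  pattern <- gantry$pattern %||% spot_pattern()
  purrr::map2_dfr(gantry$energies, gantry$spots, function(e, planes) {
    nom_sigma <- sigma_at(default_moments(e)$x, 0)
    purrr::map_dfr(planes, function(pl) {
      rois <- extract_spots(pl, pattern, nominal_sigma_mm = nom_sigma)
      avg <- average_spot(rois)
      prof <- cross_sections(avg)
      purrr::map_dfr(c("x", "y"), function(a) {
        fit <- fit_gaussian(prof[prof$axis == a, ])
        tibble::tibble(energy_mev = e, z_mm = pl$z_mm, axis = a,
                       sigma_mm = fit$sigma, mu_mm = fit$mu)
      })
    })
  })
}

#' Fit Fermi--Eyges moments for every energy and axis
#'
#' @param sigma_table Output of [spot_sigma_table()].
#' @return Tibble with `energy_mev`, `axis`, `A_mm2`, `B_mm_mrad`,
#'   `C_mrad2`, `sigma_iso_mm`.
#' @export
fit_gantry_optics <- function(sigma_table) {
  sigma_table |>
    dplyr::group_by(.data$energy_mev, .data$axis) |>
    dplyr::group_modify(function(d, key) {
      om <- fit_fe_moments(d, axis = key$axis)
      tibble::tibble(A_mm2 = om$A, B_mm_mrad = om$B, C_mrad2 = om$C,
                     sigma_iso_mm = sigma_at(om, 0))
    }) |>
    dplyr::ungroup()
}

#' Intra- and cross-gantry spot-optics comparison
#'
#' Per energy and axis: Gaussian sigmas at the five planes, fitted
#' Fermi--Eyges moments, model sigmas from the moments, intra-gantry
#' computed-vs-measured sigma relative differences, and cross-gantry
#' relative differences of measured sigma, computed sigma (at isocenter)
#' and each moment. Gantry A is the baseline of every relative difference.
#'
#' @inheritParams run_idd_comparison
#' @return List of tibbles: `sigmas` (per energy/plane/axis with measured
#'   and computed sigma and intra-gantry differences), `moments` (per
#'   energy/axis with cross-gantry moment differences), `summary` (per
#'   metric mean and range).
#' @export
run_optics_comparison <- function(gantry_a, gantry_b) {
  tab <- function(g) {
    st <- spot_sigma_table(g)
    op <- fit_gantry_optics(st)
    st <- dplyr::left_join(st, op, by = c("energy_mev", "axis"))
    st$sigma_computed_mm <- sqrt(st$A_mm2 + 2 * st$B_mm_mrad * st$z_mm / 1000 +
                                   st$C_mrad2 * (st$z_mm / 1000)^2)
    st$intra_rel_diff_pct <- relative_difference(st$sigma_computed_mm,
                                                 st$sigma_mm)
    list(sigmas = st, optics = op)
  }
  ta <- tab(gantry_a)
  tb <- tab(gantry_b)
  key <- c("energy_mev", "z_mm", "axis")
  sig <- dplyr::left_join(ta$sigmas, tb$sigmas, by = key,
                          suffix = c("_a", "_b"))
  sig$cross_measured_pct <- relative_difference(sig$sigma_mm_b,
                                                sig$sigma_mm_a)
  sig$cross_computed_pct <- relative_difference(sig$sigma_computed_mm_b,
                                                sig$sigma_computed_mm_a)
  mom <- dplyr::left_join(ta$optics, tb$optics, by = c("energy_mev", "axis"),
                          suffix = c("_a", "_b"))
  mom$spatial_var_diff_pct <- relative_difference(mom$A_mm2_b, mom$A_mm2_a)
  mom$covariance_diff_pct <- relative_difference(mom$B_mm_mrad_b,
                                                 mom$B_mm_mrad_a)
  mom$angular_var_diff_pct <- relative_difference(mom$C_mrad2_b, mom$C_mrad2_a)
  iso <- sig[sig$z_mm == 0, ]
  summarise_metric <- function(name, v) {
    tibble::tibble(metric = name, mean = mean(v), min = min(v), max = max(v))
  }
  summary <- dplyr::bind_rows(
    summarise_metric("intra_sigma_rel_diff_pct_a",
                     ta$sigmas$intra_rel_diff_pct),
    summarise_metric("intra_sigma_rel_diff_pct_b",
                     tb$sigmas$intra_rel_diff_pct),
    summarise_metric("cross_iso_sigma_measured_pct", iso$cross_measured_pct),
    summarise_metric("cross_iso_sigma_computed_pct", iso$cross_computed_pct),
    summarise_metric("spatial_var_diff_pct", mom$spatial_var_diff_pct),
    summarise_metric("covariance_diff_pct", mom$covariance_diff_pct),
    summarise_metric("angular_var_diff_pct", mom$angular_var_diff_pct)
  )
  list(sigmas = sig, moments = mom, summary = summary)
}

#' Model-sharing patient-specific QA study
#'
#' Simulates `n_per_cohort` verification plans for each treatment-site
#' cohort and evaluates all four model/delivery arms (M2G2, M2G4, M4G2,
#' M4G4: plan computed with the GTR2 or GTR4 beam model, delivered on
#' either gantry) at each gamma criterion. The model-to-delivery
#' discrepancy of an arm combines the modelling residual of the chosen
#' model with the true state of the delivering gantry.
#'
#' @param n_per_cohort Plans per cohort (>= 2).
#' @param criteria_list List of [gamma_criteria()]; default 2 mm/3% and
#'   3 mm/3%, both with a 10% low-dose threshold.
#' @param seed Integer seed.
#' @param cohorts Character vector of cohort names.
#' @param machine Machine state table: per gantry/model sigma-scale and
#'   range factors (see [qa_machine_defaults()]).
#' @param jitter_mm,dose_noise Delivery jitter s.d. and measurement noise.
#' @return Tibble of QA records: `plan_id`, `cohort`, `model`,
#'   `delivered`, `arm`, `criteria`, `passing_rate`, `mean_gamma`.
#' @export
run_qa_study <- function(n_per_cohort = 12,
                         criteria_list = list(gamma_criteria(2, 3, 10),
                                              gamma_criteria(3, 3, 10)),
                         seed = 3,
                         cohorts = c("prostate", "lung", "NPC"),
                         machine = qa_machine_defaults(),
                         jitter_mm = 0.3, dose_noise = 0.005) {
  stopifnot(n_per_cohort >= 2)
  arms <- tidyr::expand_grid(model = c("GTR2", "GTR4"),
                             delivered = c("GTR2", "GTR4"))
  arms$arm <- paste0("M", substr(arms$model, 4, 4),
                     "G", substr(arms$delivered, 4, 4))
  rows <- list()
  for (ci in seq_along(cohorts)) {
    for (p in seq_len(n_per_cohort)) {
      plan_seed <- (seed * 7919L + ci * 613L + p) %% 2147483647L
      field <- qa_field(cohorts[ci], seed = plan_seed)
      for (a in seq_len(nrow(arms))) {
        mod <- machine[machine$role == "model" &
                         machine$gantry == arms$model[a], ]
        del <- machine[machine$role == "gantry" &
                         machine$gantry == arms$delivered[a], ]
        pert <- gantry_perturbation(
          range_offset_mm = del$range_offset_mm - mod$range_offset_mm,
          sigma_scale = del$sigma_scale / mod$sigma_scale,
          spot_jitter_mm = jitter_mm, dose_noise = dose_noise)
        pair <- simulate_qa_pair(field, pert,
                                 seed = (plan_seed + a * 101L) %% 2147483647L)
        for (cr in criteria_list) {
          gs <- gamma_summary(gamma_2d(pair$measured, pair$computed, cr))
          rows[[length(rows) + 1]] <- tibble::tibble(
            plan_id = sprintf("%s-%02d", cohorts[ci], p),
            cohort = cohorts[ci], model = arms$model[a],
            delivered = arms$delivered[a], arm = arms$arm[a],
            criteria = format(cr), passing_rate = gs$passing_rate,
            mean_gamma = gs$mean_gamma)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Default machine states for the QA study
#'
#' True delivery state and fitted beam-model state of each gantry, as
#' spot-sigma scale factors and range offsets relative to the nominal
#' beamline. GTR4 delivers 2.3% wider spots with +0.3 mm range; each
#' model reproduces its own gantry to within a small modelling residual,
#' so every model/delivery arm sees an effective sigma mismatch of at
#' most ~2.3% and a range mismatch of at most 0.3 mm.
#'
#' @return Tibble with columns `role` ("gantry" = true state, "model" =
#'   fitted model), `gantry`, `sigma_scale`, `range_offset_mm`.
#' @export
qa_machine_defaults <- function() {
  tibble::tribble(
    ~role,    ~gantry, ~sigma_scale, ~range_offset_mm,
    "gantry", "GTR2",  1.005,        0.1,
    "gantry", "GTR4",  1.023,        0.3,
    "model",  "GTR2",  1.000,        0.0,
    "model",  "GTR4",  1.018,        0.2
  )
}

#' Paired statistics between two QA arms
#'
#' Two-sided paired t-test on per-plan passing-rate differences and
#' Pearson correlation across plans, per cohort and criterion — the
#' model-sharing comparison (e.g. M2G2 vs M4G2: same delivery gantry,
#' different beam model).
#'
#' @param records [run_qa_study()] output.
#' @param arm_pair Character vector of two arm labels.
#' @return Tibble per (cohort, criteria): `mean_diff` (arm1 - arm2, %),
#'   `t`, `p`, `pearson_r`, `r_p`, `n`.
#' @export
paired_model_stats <- function(records, arm_pair = c("M2G2", "M4G2")) {
  stopifnot(length(arm_pair) == 2)
  a <- records[records$arm == arm_pair[1], ]
  b <- records[records$arm == arm_pair[2], ]
  key <- c("plan_id", "cohort", "criteria")
  m <- dplyr::inner_join(a, b, by = key, suffix = c("_1", "_2"))
  if (nrow(m) != nrow(a) || nrow(m) != nrow(b)) {
    stop("records are not paired over identical plans", call. = FALSE)
  }
  m |>
    dplyr::group_by(.data$cohort, .data$criteria) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) stop("need >= 3 paired plans", call. = FALSE)
      dif <- d$passing_rate_1 - d$passing_rate_2
      identical_arms <- all(abs(dif) < 1e-12)
      tt <- if (identical_arms) list(statistic = NA_real_, p.value = NA_real_)
            else stats::t.test(d$passing_rate_1, d$passing_rate_2,
                               paired = TRUE)
      ct <- if (stats::sd(d$passing_rate_1) == 0 ||
                stats::sd(d$passing_rate_2) == 0)
              list(estimate = NA_real_, p.value = NA_real_)
            else stats::cor.test(d$passing_rate_1, d$passing_rate_2)
      tibble::tibble(mean_diff = mean(dif),
                     t = unname(tt$statistic), p = tt$p.value,
                     pearson_r = unname(ct$estimate), r_p = ct$p.value,
                     n = nrow(d))
    }) |>
    dplyr::ungroup()
}

#' Write comparison tables and a reproducibility manifest
#'
#' Writes the IDD comparison rows, optics comparison tables, QA records
#' and paired statistics as CSV files, plus a JSON manifest carrying the
#' run configuration, seeds and package version. Empty or `NULL` inputs
#' produce empty tables with headers.
#'
#' @param idd_rows,optics,qa_records,qa_stats Outputs of the respective
#'   `run_*` functions (any may be `NULL`).
#' @param out_dir Output directory (created if needed).
#' @param manifest Named list of run metadata to embed in the manifest.
#' @return Character vector of written file paths, invisibly.
#' @export
render_report <- function(idd_rows = NULL, optics = NULL, qa_records = NULL,
                          qa_stats = NULL, out_dir, manifest = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory",
                                 call. = FALSE)
  empty <- function(cols) {
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  }
  files <- character()
  put <- function(df, name, cols) {
    if (is.null(df)) df <- empty(cols)
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  put(idd_rows, "idd_comparison.csv",
      c("energy_mev", "kind", "gantry", "passing_rate", "mean_gamma",
        "r80_mm", "r80_energy_mev"))
  put(optics$sigmas, "optics_sigmas.csv", c("energy_mev", "z_mm", "axis"))
  put(optics$moments, "optics_moments.csv", c("energy_mev", "axis"))
  put(optics$summary, "optics_summary.csv", c("metric", "mean", "min", "max"))
  put(qa_records, "qa_records.csv",
      c("plan_id", "cohort", "model", "delivered", "arm", "criteria",
        "passing_rate", "mean_gamma"))
  put(qa_stats, "qa_stats.csv",
      c("cohort", "criteria", "mean_diff", "t", "p", "pearson_r", "r_p", "n"))
  man <- c(list(package = "pbsmatch",
                version = as.character(utils::packageVersion("pbsmatch"))),
           manifest)
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, man_path)
  invisible(files)
}
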