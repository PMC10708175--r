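#' Run the full synthetic analysis pipeline
#'
#' End-to-end orchestration on synthetic data: simulate the concentration
#' field, birth records and newborn population grid; assign peak-season
#' exposures; fit the weighted stratified fixed-effects model (and
#' optionally the low-birthweight logit); estimate the marginal-effect curve
#' and integrate it into the ERF with Monte Carlo uncertainty; reduce the
#' monthly field to annual peak-season concentrations; and compute
#' country-level and overall attributable birthweight reductions.
#'
#' When `out_dir` is given, every stage artifact is written (CSV/JSON) along
#' with the resolved configuration and a manifest of MD5 checksums; two runs
#' with identical configs and seeds produce identical checksums.
#'
#' @param config A [sim_config()].
#' @param covariates Covariates for the regression stages (see
#'   [fit_birthweight_fe()]).
#' @param vc_df Degrees of freedom of the marginal-effect curve.
#' @param tmrel_ppb TMREL (ppb) for ERF integration and burden.
#' @param n_draws Monte Carlo draws for ERF/burden CIs.
#' @param burden_years Years for the burden stage; default all complete
#'   calendar years.
#' @param fit_lbw Also fit the low-birthweight logit (default `TRUE`).
#' @param out_dir Optional output directory.
#' @return List of class `o3_run`: `config`, `field`, `births`, `exposures`,
#'   `fe_fit`, `lbw_fit`, `curve`, `erf`, `exposure_by_country`, `burden`,
#'   `overall`, and (if written) `manifest`.
#' @export
run_pipeline <- function(config = sim_config(),
                         covariates = c("sex", "season"),
                         vc_df = 3,
                         tmrel_ppb = config$tmrel_ppb,
                         n_draws = 500,
                         burden_years = NULL,
                         fit_lbw = TRUE,
                         out_dir = NULL) {
  config <- validate_sim_config(config)
  field <- simulate_concentration_field(config)
  births <- simulate_births(config, field)
  exposures <- assign_exposures(births, field, metric = "peak_season")
  dat <- births |>
    left_join(exposures |> select(record_id, value_ppb), by = "record_id") |>
    rename(exposure_ppb = value_ppb)

  fe_fit <- fit_birthweight_fe(dat, exposure = "exposure_ppb",
                               covariates = covariates)
  lbw_fit <- if (fit_lbw) {
    tryCatch(
      fit_lbw_logit(dat, exposure = "exposure_ppb", covariates = setdiff(covariates, "season")),
      error = function(e) {
        warn(sprintf("low-birthweight logit skipped: %s", conditionMessage(e)))
        NULL
      }
    )
  }

  curve <- fit_varying_coefficient(dat, exposure = "exposure_ppb",
                                   covariates = covariates, df = vc_df)
  erf <- erf_uncertainty(curve, tmrel_ppb = tmrel_ppb,
                         n_draws = n_draws, seed = config$seed)

  annual <- annual_peak_season(field, years = burden_years,
                               epoch_year = config$epoch_year)
  pop <- simulate_population_grid(config, field)
  expo <- population_weighted_exposure(annual, pop)
  burden <- attributable_reduction(expo, erf)
  baseline <- expo |>
    distinct(country_id, year) |>
    mutate(baseline_bw_g = config$baseline_bw_g)
  burden <- relative_reduction(burden, baseline)
  overall <- aggregate_burden(burden)

  run <- structure(list(
    config = config, field = field, births = births, exposures = exposures,
    fe_fit = fe_fit, lbw_fit = lbw_fit, curve = curve, erf = erf,
    exposure_by_country = expo, burden = burden, overall = overall
  ), class = "o3_run")

  if (!is.null(out_dir)) {
    run$manifest <- write_run(run, out_dir)
  }
  run
}

#' @export
print.o3_run <- function(x, ...) {
  cat("<o3_run> synthetic pipeline\n")
  print(x$fe_fit)
  if (!is.null(x$lbw_fit)) print(x$lbw_fit)
  ov <- x$overall |> arrange(year) |> slice(dplyr::n())
  cat(sprintf("  overall attributable reduction, %d: %.1f g (95%% CI %.1f to %.1f)\n",
              ov$year, ov$estimate, ov$lo, ov$hi))
  invisible(x)
}

# write every stage artifact + resolved config + MD5 manifest
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_births(run$births, p("births.csv"))
  readr::write_csv(run$field, p("concentration_field.csv"))
  readr::write_csv(run$exposures, p("exposures.csv"))
  readr::write_csv(tidy(run$fe_fit, all_terms = TRUE), p("fe_coefficients.csv"))
  readr::write_csv(tidy(run$curve), p("marginal_effect_curve.csv"))
  readr::write_csv(tidy(run$erf), p("erf.csv"))
  readr::write_csv(run$burden |> select(-dplyr::any_of("draws")),
                   p("burden_by_country.csv"))
  readr::write_csv(run$overall, p("burden_overall.csv"))
  cfg <- run$config
  cfg$true_erf <- unclass(cfg$true_erf)
  jsonlite::write_json(unclass(cfg), p("resolved_config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    basis_df = run$curve$df, tmrel_ppb = run$erf$tmrel_ppb,
    n_draws = nrow(run$erf$draws), seed = run$config$seed,
    stratum_mean_range_ppb = run$curve$cbar_range
  ), p("erf_metadata.json"), auto_unbox = TRUE, digits = NA)

  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  manifest
}

#' Read and write birth-record tables
#'
#' Births round-trip through CSV (always) or Parquet (when the arrow package
#' is installed). The column dictionary is the one produced by
#' [simulate_births()].
#'
#' @param births Birth-record tibble.
#' @param path File path ending in `.csv` or `.parquet`.
#' @return `read_births()` returns a tibble; `write_births()` the path,
#'   invisibly.
#' @export
write_births <- function(births, path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("the arrow package is required for Parquet output.",
            class = "ozonebw_value_error")
    }
    arrow::write_parquet(births, path)
  } else {
    readr::write_csv(births, path)
  }
  invisible(path)
}

#' @rdname write_births
#' @export
read_births <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("the arrow package is required for Parquet input.",
            class = "ozonebw_value_error")
    }
    as_tibble(arrow::read_parquet(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
}
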