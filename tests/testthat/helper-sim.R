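# shared fixtures: small synthetic worlds built in code

suppressPackageStartupMessages(library(dplyr))

# quick small world for structural tests
cfg_small <- function(..., seed = 11) {
  sim_config(
    n_countries = 3, strata_per_country = 12, births_per_stratum = 15,
    grid_cells_per_country = 3, n_months = 48,
    noise_sd_g = 50, within_stratum_sd_ppb = 8,
    covariate_effects = c(sex_male = 100), stratum_effect_sd_g = 100,
    seed = seed, ...
  )
}

# deterministic world: no noise anywhere except exposure structure
cfg_exact <- function(..., seed = 21) {
  sim_config(
    n_countries = 2, strata_per_country = 8, births_per_stratum = 12,
    grid_cells_per_country = 2, n_months = 48,
    true_erf = erf_linear(-2), noise_sd_g = 0,
    covariate_effects = numeric(0), stratum_effect_sd_g = 120,
    within_stratum_sd_ppb = 8, seed = seed, ...
  )
}

# estimator-recovery world: residual noise kept low so Monte Carlo error is
# negligible against the bias tolerances being tested
cfg_recovery <- function(..., n_countries = 10, strata_per_country = 100,
                         births_per_stratum = 50, noise_sd_g = 10,
                         seed = 31) {
  sim_config(
    n_countries = n_countries, strata_per_country = strata_per_country,
    births_per_stratum = births_per_stratum,
    grid_cells_per_country = 4, n_months = 48,
    noise_sd_g = noise_sd_g, within_stratum_sd_ppb = 12,
    covariate_effects = c(sex_male = 100), stratum_effect_sd_g = 100,
    seed = seed, ...
  )
}

# births joined with module-computed peak-season exposure
make_dataset <- function(cfg) {
  fld <- simulate_concentration_field(cfg)
  b <- simulate_births(cfg, fld)
  b |>
    left_join(assign_exposures(b, fld) |> select(record_id, value_ppb),
              by = "record_id") |>
    rename(exposure_ppb = value_ppb)
}

# independent brute-force oracle for the peak-season metric
brute_peak_season <- function(series) {
  stopifnot(length(series) == 12)
  max(vapply(1:7, function(i) mean(series[i:(i + 5)]), numeric(1)))
}
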