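#' Simulate a monthly concentration field on a toy grid
#'
#' Generates a complete cell x month table of monthly mean MDA8-style
#' concentrations. Each cell's series is
#' country mean + cell offset + sinusoidal seasonal cycle + white noise,
#' floored at zero. Country means are spread uniformly over
#' `stratum_mean_range_ppb`; cell offsets are Normal with SD one eighth of
#' that range; the seasonal phase differs by country.
#'
#' @param config A [sim_config()].
#' @return Tibble `cell_id`, `country_id`, `month_index`, `conc_ppb`, with an
#'   attribute `cell_means` (tibble of long-run cell means used downstream
#'   for stratum-level confounding).
#' @export
simulate_concentration_field <- function(config) {
  config <- validate_sim_config(config)
  withr_seed(config$seed, "field", {
    n_cells <- config$n_countries * config$grid_cells_per_country
    rng <- config$stratum_mean_range_ppb
    country_id <- sprintf("C%02d", seq_len(config$n_countries))
    country_mean <- runif(config$n_countries, rng[1], rng[2])
    phase <- runif(config$n_countries, 0, 12)
    cell <- tibble(
      cell_id = sprintf("cell%03d", seq_len(n_cells)),
      country_id = rep(country_id, each = config$grid_cells_per_country),
      cell_offset = rnorm(n_cells, 0, config$cell_offset_sd_ppb)
    )
    cell$long_run_mean <- country_mean[match(cell$country_id, country_id)] +
      cell$cell_offset

    grid <- tidyr::expand_grid(cell, month_index = seq_len(config$n_months))
    ph <- phase[match(grid$country_id, country_id)]
    seasonal <- config$seasonal_amplitude_ppb *
      sin(2 * pi * (grid$month_index + ph) / 12)
    noise <- rnorm(nrow(grid), 0, config$within_stratum_sd_ppb)
    out <- grid |>
      mutate(conc_ppb = pmax(0, long_run_mean + seasonal + noise)) |>
      select(cell_id, country_id, month_index, conc_ppb)
    attr(out, "cell_means") <- cell |>
      select(cell_id, country_id, long_run_mean)
    out
  })
}

# evaluate an expression under a seed derived from (seed, tag) without
# disturbing the caller's RNG state
withr_seed <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  offs <- c(field = 11L, births = 29L, pop = 47L, miss = 83L,
            impute = 97L, draws = 131L)
  tag_off <- unname(offs[tag])
  if (is.na(tag_off)) tag_off <- 7L
  set.seed((as.integer(seed) * 1000L + tag_off) %% .Machine$integer.max)
  force(expr)
}

#' Simulate DHS-like stratified birth records
#'
#' Generates singleton live-birth records under a two-stage stratified
#' design: strata nested in countries, each stratum tied to one grid cell,
#' births spread over calendar months. Birthweight is generated as
#'
#' `baseline + f(exposure) - f(TMREL) + covariate effects + stratum effect + noise`
#'
#' where `f` is the configured ground-truth ERF and the exposure is the
#' record's true peak-season concentration computed from the field. Stratum
#' effects are Normal(0, `stratum_effect_sd_g`) plus
#' `confounding_g_per_ppb * (cell long-run mean - mid-range)`, so switching
#' the confounding knob on creates stratum-level confounding that stratum
#' fixed effects must absorb. Sampling weights are Gamma(shape 4) draws
#' normalised to mean 1 within stratum (positive and right-skewed, like
#' survey design weights).
#'
#' The generated truth (`true_exposure_ppb`, `stratum_effect_g`) is kept in
#' the table so recovery tests never re-derive it through the code paths
#' being tested.
#'
#' @param config A [sim_config()].
#' @param field Output of [simulate_concentration_field()] for `config`.
#' @return Tibble of birth records with design columns (`stratum_id`,
#'   `country_id`, `cell_id`, `sampling_weight`), outcome (`birthweight_g`),
#'   timing (`birth_month_index`, `birth_month`, `birth_year`), covariates,
#'   `latitude_deg`, and ground-truth columns.
#' @export
simulate_births <- function(config, field) {
  config <- validate_sim_config(config)
  check_field(field)
  if (config$n_months < 22) {
    abort("field too short: at least 21 months of record before the earliest birth are required.",
          class = "ozonebw_value_error")
  }
  cell_means <- attr(field, "cell_means")
  if (is.null(cell_means)) {
    cell_means <- field |>
      group_by(cell_id, country_id) |>
      summarise(long_run_mean = mean(conc_ppb), .groups = "drop")
  }
  withr_seed(config$seed, "births", {
    n_strata <- config$n_countries * config$strata_per_country
    countries <- sprintf("C%02d", seq_len(config$n_countries))
    country_lat <- runif(config$n_countries, -30, 45)

    strata <- tibble(
      stratum_id = sprintf("S%05d", seq_len(n_strata)),
      country_id = rep(countries, each = config$strata_per_country)
    )
    # each stratum sits in one of its country's grid cells (grid lookup)
    strata <- strata |>
      group_by(country_id) |>
      mutate(cell_id = {
        cl <- cell_means$cell_id[cell_means$country_id == country_id[1]]
        sample(cl, n(), replace = TRUE)
      }) |>
      ungroup() |>
      left_join(cell_means |> select(cell_id, long_run_mean), by = "cell_id")
    mid <- mean(config$stratum_mean_range_ppb)
    strata$stratum_effect_g <-
      rnorm(n_strata, 0, config$stratum_effect_sd_g) +
      config$confounding_g_per_ppb * (strata$long_run_mean - mid)
    strata$latitude_deg <-
      country_lat[match(strata$country_id, countries)] + runif(n_strata, -2, 2)

    n <- n_strata * config$births_per_stratum
    rec <- strata[rep(seq_len(n_strata), each = config$births_per_stratum), ] |>
      mutate(record_id = sprintf("R%07d", row_number()))

    # birth dates leave a full 21-month pre-birth record
    rec$birth_month_index <- sample(22:config$n_months, n, replace = TRUE)
    rec$birth_month <- (rec$birth_month_index - 1L) %% 12L + 1L
    rec$birth_year <- config$epoch_year + (rec$birth_month_index - 1L) %/% 12L

    # true peak-season exposure straight from the generative definition
    m <- field_matrix(field)
    combos <- rec |> distinct(cell_id, birth_month_index)
    combos$true_exposure_ppb <- vapply(seq_len(nrow(combos)), function(i) {
      e <- combos$birth_month_index[i] - 1L
      max(running_mean6(m[combos$cell_id[i], as.character((e - 11L):e)]))
    }, numeric(1))
    rec <- rec |> left_join(combos, by = c("cell_id", "birth_month_index"))

    rec <- bind_cols(rec, simulate_covariates(n))

    eff <- config$covariate_effects
    cov_g <- rep(0, n)
    if ("sex_male" %in% names(eff)) {
      cov_g <- cov_g + eff[["sex_male"]] * (rec$sex == "male")
    }
    if ("cesarean" %in% names(eff)) {
      cov_g <- cov_g + eff[["cesarean"]] * (rec$cesarean == "yes")
    }
    if ("maternal_age_per_y" %in% names(eff)) {
      cov_g <- cov_g + eff[["maternal_age_per_y"]] * (rec$maternal_age_y - 26)
    }
    if ("parity_per_child" %in% names(eff)) {
      cov_g <- cov_g + eff[["parity_per_child"]] * (rec$parity - 2)
    }
    rec$covariate_effect_g <- cov_g

    f <- function(cc) true_erf(config$true_erf, cc)
    rec$birthweight_g <- config$baseline_bw_g +
      f(rec$true_exposure_ppb) - f(config$tmrel_ppb) +
      cov_g + rec$stratum_effect_g +
      rnorm(n, 0, config$noise_sd_g)

    w <- rgamma(n, shape = 4, rate = 4)
    rec <- rec |>
      group_by(stratum_id) |>
      mutate(sampling_weight = w[dplyr::cur_group_rows()] /
               mean(w[dplyr::cur_group_rows()])) |>
      ungroup()

    out <- rec |>
      select(record_id, stratum_id, country_id, cell_id, birth_month_index,
             birth_month, birth_year, birthweight_g, sampling_weight,
             latitude_deg, sex, cesarean, place_of_delivery, antenatal_care,
             parity, maternal_age_y, interpregnancy_interval_mo,
             maternal_bmi_class, maternal_employed, head_sex, head_age_y,
             water_source, toilet_type, cooking_fuel, temperature_c,
             pm25_ugm3,
             true_exposure_ppb, stratum_effect_g, covariate_effect_g)
    attr(out, "ground_truth") <- list(
      true_erf = config$true_erf, tmrel_ppb = config$tmrel_ppb,
      baseline_bw_g = config$baseline_bw_g,
      covariate_effects = config$covariate_effects,
      confounding_g_per_ppb = config$confounding_g_per_ppb,
      seed = config$seed
    )
    out
  })
}

# categorical + continuous maternal/household covariates, DHS-style domains
simulate_covariates <- function(n) {
  samp <- function(lv, p) factor(sample(lv, n, TRUE, p), levels = lv)
  tibble(
    sex = samp(c("male", "female"), c(0.516, 0.484)),
    cesarean = samp(c("no", "yes"), c(0.88, 0.12)),
    place_of_delivery = samp(c("home", "facility"), c(0.45, 0.55)),
    antenatal_care = samp(c("none", "1-3", "4+"), c(0.2, 0.35, 0.45)),
    parity = pmin(rgeom_plus1(n), 8L),
    maternal_age_y = pmin(pmax(round(rnorm(n, 26, 6)), 15), 49),
    interpregnancy_interval_mo = pmin(round(rgamma(n, 2, 1 / 18)), 120),
    maternal_bmi_class = samp(c("under", "normal", "over", "obese"),
                              c(0.15, 0.55, 0.2, 0.1)),
    maternal_employed = samp(c("no", "yes"), c(0.5, 0.5)),
    head_sex = samp(c("male", "female"), c(0.8, 0.2)),
    head_age_y = pmin(pmax(round(rnorm(n, 42, 12)), 18), 90),
    water_source = samp(c("improved", "unimproved"), c(0.7, 0.3)),
    toilet_type = samp(c("improved", "unimproved", "none"),
                       c(0.5, 0.3, 0.2)),
    cooking_fuel = samp(c("clean", "solid"), c(0.35, 0.65)),
    # environmental co-exposures (pre-birth aggregates, generated directly)
    temperature_c = round(rnorm(n, 24, 4), 1),
    pm25_ugm3 = round(stats::rlnorm(n, log(35), 0.5), 1)
  )
}

rgeom_plus1 <- function(n) stats::rgeom(n, 0.4) + 1L

#' Simulate a gridded newborn population
#'
#' Draws annual sex-specific counts of 0-to-1-year-olds per grid cell, the
#' `P_{s,y,k}` input of population-weighted exposure. Counts are lognormal
#' (median 500 per cell and sex) or uniform (`uniform = TRUE`: 500
#' everywhere), constant-seeded so a fixed config reproduces the grid.
#'
#' @param config A [sim_config()].
#' @param field Concentration field (defines the cells and years covered).
#' @param uniform If `TRUE`, every (cell, sex) count is equal.
#' @return Tibble `cell_id`, `country_id`, `year`, `sex`, `count`.
#' @export
simulate_population_grid <- function(config, field, uniform = FALSE) {
  config <- validate_sim_config(config)
  check_field(field)
  cells <- field |> distinct(cell_id, country_id)
  idx <- sort(unique(field$month_index))
  yrs <- config$epoch_year + (idx - 1L) %/% 12L
  years <- as.integer(names(which(table(yrs) == 12L)))
  withr_seed(config$seed, "pop", {
    grid <- tidyr::expand_grid(cells, year = years,
                               sex = c("male", "female"))
    grid$count <- if (uniform) {
      500
    } else {
      round(stats::rlnorm(nrow(grid), log(500), 0.6))
    }
    grid
  })
}

#' Inject missingness into covariate columns
#'
#' Sets each value of the targeted covariate columns to `NA` independently
#' with probability `rate`, emulating item nonresponse before imputation.
#'
#' @param records Birth-record tibble.
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param vars Covariate columns to target; defaults to the categorical
#'   household/pregnancy covariates.
#' @return `records` with `NA`s injected.
#' @export
inject_missingness <- function(records, rate, seed = 1L,
                               vars = c("cesarean", "place_of_delivery",
                                        "antenatal_care", "maternal_bmi_class",
                                        "water_source", "toilet_type",
                                        "cooking_fuel")) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    abort("`rate` must lie in [0, 1).", class = "ozonebw_value_error")
  }
  if (rate == 0) return(records)
  withr_seed(seed, "miss", {
    for (v in vars) {
      hit <- runif(nrow(records)) < rate
      records[[v]][hit] <- NA
    }
    records
  })
}

#' Single random hot-deck imputation within country
#'
#' Fills every missing covariate value with a sampling-weighted random draw
#' from the observed values of the same variable within the same country — a
#' single random (chained-equation-style) imputation pass. Errors if a
#' variable is entirely missing within a country.
#'
#' @param records Birth-record tibble (possibly with `NA` covariates).
#' @param seed Integer seed.
#' @param vars Columns to impute; defaults to every covariate column with
#'   missing values.
#' @return `records` with no missing values in `vars`.
#' @export
impute_hot_deck <- function(records, seed = 1L, vars = NULL) {
  cand <- setdiff(names(records),
                  c("record_id", "stratum_id", "country_id", "cell_id",
                    "birthweight_g", "sampling_weight"))
  vars <- vars %||% cand[vapply(records[cand], anyNA, logical(1))]
  if (!length(vars)) return(records)
  withr_seed(seed, "impute", {
    for (v in vars) {
      for (ct in unique(records$country_id)) {
        in_ct <- records$country_id == ct
        obs <- in_ct & !is.na(records[[v]])
        mis <- in_ct & is.na(records[[v]])
        if (!any(mis)) next
        if (!any(obs)) {
          abort(sprintf("variable `%s` is entirely missing in country %s; cannot impute.",
                        v, ct), class = "ozonebw_value_error")
        }
        pool <- which(obs)
        w <- records$sampling_weight[pool]
        records[[v]][mis] <- records[[v]][sample(pool, sum(mis),
                                                 replace = TRUE,
                                                 prob = w / sum(w))]
      }
    }
    records
  })
}
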