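#' Simulation configuration for the synthetic DHS-like world
#'
#' Builds and validates the configuration driving every synthetic-data
#' generator: the survey design (countries, strata, births per stratum), the
#' toy concentration grid, the ground-truth exposure-response function (ERF),
#' and the noise structure. Defaults describe a world scaled like the
#' multicountry survey setting the package targets: mean birthweight near
#' 3061 g, peak-season ozone means spanning roughly 35-70 ppb, and 25 births
#' per sampling stratum (DHS clusters enrol 25-30 households).
#'
#' @param n_countries Number of countries.
#' @param strata_per_country Sampling strata (region x urban/rural units) per
#'   country. Stratum fixed effects are taken at this level.
#' @param births_per_stratum Singleton live births generated per stratum.
#' @param grid_cells_per_country Concentration grid cells per country; each
#'   stratum is assigned to one cell (grid-lookup exposure, no interpolation).
#' @param n_months Length of the monthly concentration record (>= 24). Month
#'   index 1 is January of `epoch_year`.
#' @param true_erf Ground-truth ERF specification from [erf_linear()],
#'   [erf_piecewise()] or [erf_sublinear()].
#' @param baseline_bw_g Baseline birthweight (g) at the TMREL for a reference
#'   covariate profile.
#' @param noise_sd_g SD (g) of the residual birthweight noise.
#' @param stratum_mean_range_ppb Length-2 numeric `(low, high)`: range of
#'   country-level mean concentrations (ppb).
#' @param within_stratum_sd_ppb SD (ppb) of the month-to-month white noise in
#'   each cell's series; this is what creates within-stratum exposure
#'   variation across birth dates.
#' @param seasonal_amplitude_ppb Amplitude (ppb) of the sinusoidal seasonal
#'   cycle in each cell's series.
#' @param cell_offset_sd_ppb SD (ppb) of the time-constant cell-level offset
#'   from the country mean; default one eighth of the stratum-mean range.
#' @param covariate_effects Named numeric vector of generative covariate
#'   effects (g). Supported names: `sex_male`, `cesarean`,
#'   `maternal_age_per_y` (per year, centred at 26), `parity_per_child`
#'   (per child, centred at 2).
#' @param stratum_effect_sd_g SD (g) of i.i.d. stratum-level intercept shifts.
#' @param confounding_g_per_ppb Slope (g per ppb) linking each stratum's
#'   long-run mean concentration to its intercept shift. Non-zero values
#'   create exactly the stratum-level confounding that the fixed effects must
#'   absorb.
#' @param tmrel_ppb Theoretical minimum risk exposure level (ppb) used to
#'   anchor the generative ERF; defaults to the WHO AQG (60 ug/m3).
#' @param epoch_year Calendar year of month index 1.
#' @param seed Integer seed; a fixed seed reproduces every generated dataset
#'   byte for byte.
#'
#' @return A validated `sim_config` list.
#' @examples
#' cfg <- sim_config(n_countries = 2, strata_per_country = 5,
#'                   births_per_stratum = 10, n_months = 36, seed = 1)
#' cfg$true_erf
#' @export
sim_config <- function(n_countries = 10,
                       strata_per_country = 40,
                       births_per_stratum = 25,
                       grid_cells_per_country = 4,
                       n_months = 60,
                       true_erf = erf_sublinear(),
                       baseline_bw_g = 3061,
                       noise_sd_g = 450,
                       stratum_mean_range_ppb = c(35, 70),
                       within_stratum_sd_ppb = 3,
                       seasonal_amplitude_ppb = 8,
                       cell_offset_sd_ppb = NULL,
                       covariate_effects = c(sex_male = 100),
                       stratum_effect_sd_g = 150,
                       confounding_g_per_ppb = 0,
                       tmrel_ppb = tmrel_preset("aqg"),
                       epoch_year = 2003,
                       seed = 1L) {
  cfg <- list(
    n_countries = n_countries, strata_per_country = strata_per_country,
    births_per_stratum = births_per_stratum,
    grid_cells_per_country = grid_cells_per_country, n_months = n_months,
    true_erf = true_erf, baseline_bw_g = baseline_bw_g,
    noise_sd_g = noise_sd_g, stratum_mean_range_ppb = stratum_mean_range_ppb,
    within_stratum_sd_ppb = within_stratum_sd_ppb,
    seasonal_amplitude_ppb = seasonal_amplitude_ppb,
    cell_offset_sd_ppb = cell_offset_sd_ppb %||%
      diff(range(stratum_mean_range_ppb)) / 8,
    covariate_effects = covariate_effects,
    stratum_effect_sd_g = stratum_effect_sd_g,
    confounding_g_per_ppb = confounding_g_per_ppb,
    tmrel_ppb = tmrel_ppb, epoch_year = epoch_year, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x)) {
      abort(sprintf("`%s` must be a positive integer count.", nm),
            class = "ozonebw_config_error")
    }
  }
  for (nm in c("n_countries", "strata_per_country", "births_per_stratum",
               "grid_cells_per_country", "n_months")) {
    chk_count(cfg[[nm]], nm)
  }
  if (cfg$n_months < 24) {
    abort("`n_months` must be at least 24.", class = "ozonebw_config_error")
  }
  r <- cfg$stratum_mean_range_ppb
  if (!is.numeric(r) || length(r) != 2 || !(r[1] < r[2])) {
    abort("`stratum_mean_range_ppb` must be (low, high) with low < high.",
          class = "ozonebw_config_error")
  }
  for (nm in c("noise_sd_g", "within_stratum_sd_ppb", "seasonal_amplitude_ppb",
               "stratum_effect_sd_g", "cell_offset_sd_ppb")) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] < 0) {
      abort(sprintf("`%s` must be a nonnegative number.", nm),
            class = "ozonebw_config_error")
    }
  }
  if (cfg$baseline_bw_g <= 0) {
    abort("`baseline_bw_g` must be positive.", class = "ozonebw_config_error")
  }
  if (!inherits(cfg$true_erf, "erf_spec")) {
    abort("`true_erf` must be built with erf_linear(), erf_piecewise() or erf_sublinear().",
          class = "ozonebw_config_error")
  }
  if (length(cfg$covariate_effects) &&
      (is.null(names(cfg$covariate_effects)) ||
       !all(names(cfg$covariate_effects) %in%
            c("sex_male", "cesarean", "maternal_age_per_y", "parity_per_child")))) {
    abort(paste("`covariate_effects` names must be among sex_male, cesarean,",
                "maternal_age_per_y, parity_per_child."),
          class = "ozonebw_config_error")
  }
  cfg
}

#' Ground-truth exposure-response specifications
#'
#' Tagged specifications of the true concentration -> birthweight-change
#' function used by the synthetic-data generator. All are expressed as a
#' function `f(c)` in grams; birthweight is generated as
#' `baseline + f(exposure) - f(TMREL) + ...`, so only differences of `f`
#' matter.
#'
#' * `erf_linear()`: `f(c) = slope * c`.
#' * `erf_piecewise()`: continuous piecewise-linear `f` with breakpoints
#'   `knots` and one slope per interval (length `length(knots) + 1`),
#'   anchored at `f(0) = 0`.
#' * `erf_sublinear()`: `f(c) = -scale * c^shape`, `0 < shape < 1` — a
#'   monotone-decreasing curve whose marginal effect attenuates at high
#'   concentrations (sublinear decreasing curvature). The default scale is
#'   calibrated so the marginal effect near 53 ppb is about -2 g per ppb.
#'
#' @param slope_g_per_ppb Slope in g per ppb.
#' @param knots Increasing breakpoints (ppb).
#' @param slopes Slopes (g per ppb), one per interval.
#' @param scale,shape Parameters of the sublinear power law.
#' @return An `erf_spec` object; evaluate it with [true_erf()].
#' @examples
#' f <- erf_sublinear()
#' true_erf(f, c(30, 50, 70))
#' @export
erf_linear <- function(slope_g_per_ppb = -2) {
  structure(list(type = "linear", slope = slope_g_per_ppb),
            class = "erf_spec")
}

#' @rdname erf_linear
#' @export
erf_piecewise <- function(knots, slopes) {
  if (length(slopes) != length(knots) + 1) {
    abort("`slopes` must have one more element than `knots`.",
          class = "ozonebw_config_error")
  }
  if (is.unsorted(knots, strictly = TRUE)) {
    abort("`knots` must be strictly increasing.",
          class = "ozonebw_config_error")
  }
  structure(list(type = "piecewise_linear", knots = knots, slopes = slopes),
            class = "erf_spec")
}

#' @rdname erf_linear
#' @export
erf_sublinear <- function(scale = 29, shape = 0.5) {
  if (shape <= 0 || shape >= 1) {
    abort("`shape` must lie in (0, 1).", class = "ozonebw_config_error")
  }
  structure(list(type = "sublinear", scale = scale, shape = shape),
            class = "erf_spec")
}

#' Evaluate a ground-truth ERF specification
#'
#' @param spec An `erf_spec` from [erf_linear()], [erf_piecewise()] or
#'   [erf_sublinear()].
#' @param c_ppb Concentrations (ppb).
#' @return Birthweight change `f(c)` in grams (same length as `c_ppb`).
#' @export
true_erf <- function(spec, c_ppb) {
  stopifnot(inherits(spec, "erf_spec"))
  switch(spec$type,
    linear = spec$slope * c_ppb,
    sublinear = -spec$scale * c_ppb^spec$shape,
    piecewise_linear = {
      brk <- c(0, spec$knots, Inf)
      vapply(c_ppb, function(cc) {
        tot <- 0
        for (j in seq_along(spec$slopes)) {
          lo <- brk[j]; hi <- min(cc, brk[j + 1])
          if (hi > lo) tot <- tot + spec$slopes[j] * (hi - lo)
          if (cc <= brk[j + 1]) break
        }
        tot
      }, numeric(1))
    },
    abort("Unknown erf_spec type.")
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d countries x %d strata x %d births (n = %d)\n",
              x$n_countries, x$strata_per_country, x$births_per_stratum,
              x$n_countries * x$strata_per_country * x$births_per_stratum))
  cat(sprintf("  grid: %d cells/country, %d months from Jan %d\n",
              x$grid_cells_per_country, x$n_months, x$epoch_year))
  cat(sprintf("  true ERF: %s; TMREL %.2f ppb; seed %d\n",
              x$true_erf$type, x$tmrel_ppb, x$seed))
  invisible(x)
}
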