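#' Newborn-population-weighted country exposure
#'
#' Computes, per country and year, the weighted average annual peak-season
#' concentration
#' `E_{i,y} = sum_{s in i} C_{s,y} * sum_k P_{s,y,k} / sum_{s in i} sum_k P_{s,y,k}`
#' where `s` indexes grid cells, `k` sex, `C` the annual peak-season
#' concentration field and `P` the gridded annual sex-specific population of
#' 0-to-1-year-olds standing in for newborn counts. Cells with zero
#' population contribute nothing.
#'
#' @param conc Annual peak-season field: tibble `cell_id`, `country_id`,
#'   `year`, `conc_ppb` (see [annual_peak_season()]).
#' @param pop Population grid: tibble `cell_id`, `year`, `sex`, `count`.
#' @return Tibble `country_id`, `year`, `E_ppb`, `newborns`.
#' @examples
#' conc <- tibble::tibble(cell_id = c("a", "b", "c"), country_id = "X",
#'                        year = 2019, conc_ppb = c(40, 50, 60))
#' pop <- tibble::tibble(cell_id = c("a", "b", "c"), year = 2019,
#'                       sex = "female", count = c(1, 2, 1))
#' population_weighted_exposure(conc, pop)  # E = 50 ppb
#' @export
population_weighted_exposure <- function(conc, pop) {
  check_cols(conc, c("cell_id", "country_id", "year", "conc_ppb"))
  check_cols(pop, c("cell_id", "year", "sex", "count"))
  if (any(pop$count < 0)) {
    abort("population counts must be nonnegative.",
          class = "ozonebw_value_error")
  }
  align <- check_grid_alignment(conc, pop)
  if (!all(align$ok)) {
    abort(paste("concentration and population grids are misaligned:",
                paste(align$issue[!align$ok], collapse = "; ")),
          class = "ozonebw_value_error")
  }
  ptot <- pop |>
    group_by(cell_id, year) |>
    summarise(.num = sum(count), .groups = "drop")
  joined <- conc |>
    inner_join(ptot, by = c("cell_id", "year"))
  out <- joined |>
    group_by(country_id, year) |>
    summarise(E_ppb = sum(conc_ppb * .num) / sum(.num),
              newborns = sum(.num), .groups = "drop")
  zero <- joined |>
    group_by(country_id, year) |>
    summarise(tot = sum(.num), .groups = "drop") |>
    filter(tot <= 0)
  if (nrow(zero)) {
    abort(sprintf("country-year(s) with zero total population: %s.",
                  paste(paste(zero$country_id, zero$year), collapse = ", ")),
          class = "ozonebw_value_error")
  }
  out
}

#' Check that concentration and population grids share cells and years
#'
#' @param conc,pop As in [population_weighted_exposure()].
#' @return Tibble report with columns `check`, `ok`, `issue`.
#' @export
check_grid_alignment <- function(conc, pop) {
  yrs <- intersect(unique(conc$year), unique(pop$year))
  miss_in_pop <- setdiff(unique(conc$cell_id), unique(pop$cell_id))
  miss_in_conc <- setdiff(unique(pop$cell_id), unique(conc$cell_id))
  tibble(
    check = c("shared_years", "cells_covered_by_population",
              "cells_covered_by_concentration"),
    ok = c(length(yrs) > 0, length(miss_in_pop) == 0,
           length(miss_in_conc) == 0),
    issue = c(
      if (length(yrs) > 0) "" else "no common years",
      if (length(miss_in_pop) == 0) "" else
        sprintf("%d concentration cell(s) missing from the population grid",
                length(miss_in_pop)),
      if (length(miss_in_conc) == 0) "" else
        sprintf("%d population cell(s) missing from the concentration grid",
                length(miss_in_conc))
    )
  )
}

#' Country-level attributable birthweight reduction
#'
#' Evaluates the ERF at each country-year exposure `E_{i,y}`: the
#' attributable absolute reduction is `-ERF(E)` for exposures above the
#' TMREL and zero at or below it (burdens are floored at zero; attributable
#' risk is not credited below the reference level). Evaluation outside the
#' ERF grid clamps to the boundary value by default. When the ERF carries
#' Monte Carlo draws, each draw is evaluated the same way and kept for
#' percentile CIs.
#'
#' @param exposure Tibble from [population_weighted_exposure()].
#' @param erf An `o3_erf` object.
#' @param floor Floor burdens at zero (default `TRUE`).
#' @param extrapolation `"clamp"` (default) or `"linear"` beyond the ERF
#'   grid.
#' @return Tibble `country_id`, `year`, `E_ppb`, `newborns`, `abs_g`,
#'   `abs_lo`, `abs_hi`, with the per-draw matrix in attribute `draws`
#'   (rows = countries-years, cols = draws) when the ERF has draws.
#' @export
attributable_reduction <- function(exposure, erf, floor = TRUE,
                                   extrapolation = c("clamp", "linear")) {
  extrapolation <- match.arg(extrapolation)
  stopifnot(inherits(erf, "o3_erf"))
  check_cols(exposure, c("country_id", "year", "E_ppb", "newborns"))
  out_of_grid <- exposure$E_ppb < min(erf$grid) | exposure$E_ppb > max(erf$grid)
  if (any(out_of_grid) && extrapolation == "clamp") {
    inform(sprintf("%d exposure value(s) outside the ERF grid clamped to the boundary.",
                   sum(out_of_grid)))
  }
  red <- function(vals) {
    r <- -vals
    r[exposure$E_ppb <= erf$tmrel_ppb] <- 0
    if (floor) r <- pmax(r, 0)
    r
  }
  abs_g <- red(erf_eval(erf, exposure$E_ppb, "mean", extrapolation))
  out <- exposure |> mutate(abs_g = abs_g, abs_lo = NA_real_, abs_hi = NA_real_)
  if (!is.null(erf$draws)) {
    dm <- erf_eval(erf, exposure$E_ppb, "draws", extrapolation)
    dm <- apply(dm, 1, red)               # units x draws
    if (is.null(dim(dm))) dm <- matrix(dm, nrow = nrow(exposure))
    ci <- monte_carlo_ci(dm)
    out$abs_lo <- ci$lo
    out$abs_hi <- ci$hi
    attr(out, "draws") <- dm
  }
  out
}

#' Relative attributable birthweight reduction
#'
#' Divides the absolute reduction by a country-year baseline mean
#' birthweight: `rel = 100 * abs / baseline`. Baselines missing for a year
#' are carried forward from the most recent available year (mirroring the
#' use of the latest available estimates for trailing years), with a
#' message.
#'
#' @param burden Output of [attributable_reduction()].
#' @param baseline Tibble `country_id`, `year`, `baseline_bw_g`.
#' @return `burden` with `baseline_bw_g`, `rel_pct`, `rel_lo`, `rel_hi`
#'   added; the relative per-draw matrix is stored in attribute
#'   `rel_draws`.
#' @export
relative_reduction <- function(burden, baseline) {
  check_cols(burden, c("country_id", "year", "abs_g"))
  check_cols(baseline, c("country_id", "year", "baseline_bw_g"))
  if (any(baseline$baseline_bw_g <= 0)) {
    abort("baseline birthweights must be positive.",
          class = "ozonebw_value_error")
  }
  draws <- attr(burden, "draws")
  out <- burden |>
    left_join(baseline, by = c("country_id", "year"))
  if (anyNA(out$baseline_bw_g)) {
    n_cf <- sum(is.na(out$baseline_bw_g))
    out <- out |>
      group_by(country_id) |>
      arrange(year, .by_group = TRUE) |>
      mutate(baseline_bw_g = carry_forward(baseline_bw_g, year, baseline,
                                           country_id[1])) |>
      ungroup()
    if (anyNA(out$baseline_bw_g)) {
      abort("no baseline birthweight available (in any year) for some country.",
            class = "ozonebw_value_error")
    }
    inform(sprintf("baseline birthweight carried forward from the most recent available year for %d country-year(s).",
                   n_cf))
  }
  out$rel_pct <- 100 * out$abs_g / out$baseline_bw_g
  out$rel_lo <- NA_real_
  out$rel_hi <- NA_real_
  if (!is.null(draws)) {
    rel_draws <- 100 * draws / out$baseline_bw_g
    ci <- monte_carlo_ci(rel_draws)
    out$rel_lo <- ci$lo
    out$rel_hi <- ci$hi
    attr(out, "draws") <- draws
    attr(out, "rel_draws") <- rel_draws
  }
  out
}

carry_forward <- function(base_g, yrs, baseline, ctry) {
  avail <- baseline |> filter(country_id == ctry) |> arrange(year)
  vapply(seq_along(base_g), function(i) {
    if (!is.na(base_g[i])) return(base_g[i])
    prior <- avail |> filter(year <= yrs[i])
    if (nrow(prior)) prior$baseline_bw_g[nrow(prior)] else
      if (nrow(avail)) avail$baseline_bw_g[1] else NA_real_
  }, numeric(1))
}

#' Newborn-weighted aggregation of country burdens
#'
#' Averages country-level burdens with weights equal to newborn counts,
#' overall or within groups (e.g. regions), per Monte Carlo draw, then
#' summarises draws to percentile CIs. Aggregation is associative: the
#' overall burden equals the newborn-weighted mean of group burdens.
#'
#' @param burden Output of [attributable_reduction()] or
#'   [relative_reduction()] (draw attributes are used when present).
#' @param by Optional grouping column name (e.g. a region column joined onto
#'   `burden`); `NULL` aggregates everything.
#' @param value Column to aggregate: `"abs_g"` (default) or `"rel_pct"`.
#' @return Tibble with the group column (or `group = "overall"`), `year`,
#'   `estimate`, `lo`, `hi`, `newborns`.
#' @export
aggregate_burden <- function(burden, by = NULL, value = c("abs_g", "rel_pct")) {
  value <- match.arg(value)
  check_cols(burden, c("year", "newborns", value))
  draws <- if (value == "abs_g") attr(burden, "draws") else attr(burden, "rel_draws")
  gvar <- by %||% ".overall"
  if (is.null(by)) burden$.overall <- "overall"
  if (nrow(burden) == 0) {
    abort("empty burden table: nothing to aggregate.",
          class = "ozonebw_value_error")
  }
  if (!is.null(draws) && nrow(draws) != nrow(burden)) {
    abort("draw matrix rows do not match burden rows (draw-count mismatch).",
          class = "ozonebw_value_error")
  }
  idx <- split(seq_len(nrow(burden)),
               list(burden[[gvar]], burden$year), drop = TRUE)
  purrr::imap(idx, function(ii, key) {
    w <- burden$newborns[ii]
    est <- weighted.mean(burden[[value]][ii], w)
    lo <- hi <- NA_real_
    if (!is.null(draws)) {
      agg <- as.vector(w %*% draws[ii, , drop = FALSE]) / sum(w)
      qs <- quantile(agg, c(0.025, 0.975), names = FALSE)
      lo <- qs[1]; hi <- qs[2]
    }
    tibble(group = burden[[gvar]][ii[1]], year = burden$year[ii[1]],
           estimate = est, lo = lo, hi = hi, newborns = sum(w))
  }) |>
    list_rbind() |>
    arrange(group, year)
}

#' Percentile 95% confidence intervals from Monte Carlo draws
#'
#' Pointwise 2.5th and 97.5th percentiles across draws; constant draws give
#' a zero-width interval.
#'
#' @param draws Matrix (units x draws) or vector of draws.
#' @return Tibble `lo`, `hi` (one row per unit).
#' @export
monte_carlo_ci <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1)
  qs <- t(apply(draws, 1, quantile, probs = c(0.025, 0.975), names = FALSE))
  tibble(lo = qs[, 1], hi = qs[, 2])
}
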