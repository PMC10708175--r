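#' Convert ozone concentrations between ug/m3 and ppb
#'
#' Standard-conditions conversion for ozone (25 degrees C, 1013 hPa):
#' 1 ppb = 1.96 ug/m3. The WHO peak-season guideline values are quoted in
#' ug/m3 (AQG 60, IT2 70, IT1 100) while exposure work is done in ppb, so
#' both directions are provided. The factor is configurable for other
#' reference conditions.
#'
#' @param x Nonnegative concentration values.
#' @param factor ug/m3 per ppb; default 1.96.
#' @return Converted values.
#' @examples
#' ugm3_to_ppb(60)  # WHO AQG -> 30.61 ppb
#' @export
ugm3_to_ppb <- function(x, factor = 1.96) {
  check_nonneg(x, "x")
  x / factor
}

#' @rdname ugm3_to_ppb
#' @export
ppb_to_ugm3 <- function(x, factor = 1.96) {
  check_nonneg(x, "x")
  x * factor
}

check_nonneg <- function(x, nm) {
  if (any(!is.na(x) & x < 0)) {
    abort(sprintf("`%s` must be nonnegative.", nm),
          class = "ozonebw_value_error")
  }
  invisible(x)
}

#' WHO peak-season ozone reference levels in ppb
#'
#' The Air Quality Guideline (60 ug/m3) and interim targets 2 (70 ug/m3) and
#' 1 (100 ug/m3), converted to ppb with [ugm3_to_ppb()]. The AQG is the
#' default TMREL for ERF integration and burden assessment.
#'
#' @param which One of `"aqg"`, `"it2"`, `"it1"`.
#' @return Concentration in ppb.
#' @examples
#' tmrel_preset("aqg")
#' @export
tmrel_preset <- function(which = c("aqg", "it2", "it1")) {
  which <- match.arg(which)
  ugm3_to_ppb(c(aqg = 60, it2 = 70, it1 = 100)[[which]])
}

check_series <- function(series, len, what) {
  if (length(series) != len) {
    abort(sprintf("%s requires exactly %d consecutive monthly values, got %d.",
                  what, len, length(series)),
          class = "ozonebw_value_error")
  }
  if (anyNA(series)) {
    abort(sprintf("%s: missing value at month position(s) %s of the window.",
                  what, paste(which(is.na(series)), collapse = ", ")),
          class = "ozonebw_value_error")
  }
  invisible(series)
}

#' Peak-season exposure: maximum 6-month running mean
#'
#' The WHO long-term ozone metric: over the 12 months preceding birth, the
#' maximum over the 7 windows of 6 consecutive months of the window mean of
#' monthly MDA8 concentrations. The birth month itself is excluded (the
#' window is months -12..-1 relative to birth).
#'
#' @param series Numeric vector of exactly 12 consecutive monthly means
#'   (ppb), ordered oldest to newest, none missing.
#' @return Peak-season concentration (ppb).
#' @examples
#' peak_season(c(30, 35, 40, 45, 50, 55, 60, 55, 50, 45, 40, 35))  # 52.5
#' @export
peak_season <- function(series) {
  check_series(series, 12L, "peak_season")
  max(running_mean6(series))
}

# means of the 7 windows of 6 consecutive months within a 12-month series
running_mean6 <- function(series) {
  cs <- cumsum(c(0, series))
  (cs[7:13] - cs[1:7]) / 6
}

#' Gestational exposure: 9-month pre-birth mean
#'
#' Arithmetic mean of the monthly MDA8 concentrations over the 9 months
#' preceding birth (the dominant gestational duration where gestational age
#' is unrecorded).
#'
#' @param series Numeric vector of exactly 9 consecutive monthly means (ppb).
#' @return Mean concentration (ppb).
#' @export
gestational_mean <- function(series) {
  check_series(series, 9L, "gestational_mean")
  mean(series)
}

#' Gestation-weighted exposure from annual concentrations
#'
#' For annual-resolution products, gestational exposure is the weighted mean
#' of the birth-year and prior-year concentrations with weights
#' `min(m, 9)/9` and `1 - min(m, 9)/9`, where `m` is the birth month. A May
#' birth therefore weights the birth year 5/9 and the prior year 4/9; births
#' in month 9 or later fall entirely within the birth year.
#'
#' @param annual_conc Named numeric vector of annual concentrations (ppb);
#'   names are calendar years.
#' @param birth_month Birth month 1-12.
#' @param birth_year Birth year; `annual_conc` must contain `birth_year` and
#'   `birth_year - 1`.
#' @return Gestation-weighted concentration (ppb).
#' @examples
#' gestation_weighted(c(`2009` = 45, `2010` = 54), birth_month = 5,
#'                    birth_year = 2010)  # 5/9 * 54 + 4/9 * 45
#' @export
gestation_weighted <- function(annual_conc, birth_month, birth_year) {
  if (!is.numeric(birth_month) || birth_month < 1 || birth_month > 12) {
    abort("`birth_month` must be in 1..12.", class = "ozonebw_value_error")
  }
  yrs <- as.character(c(birth_year, birth_year - 1))
  missing_y <- yrs[!yrs %in% names(annual_conc)]
  if (length(missing_y)) {
    abort(sprintf("annual concentration missing for year(s) %s.",
                  paste(missing_y, collapse = ", ")),
          class = "ozonebw_value_error")
  }
  w <- min(birth_month, 9) / 9
  w * annual_conc[[yrs[1]]] + (1 - w) * annual_conc[[yrs[2]]]
}

# ---- field-level operations --------------------------------------------

check_field <- function(field) {
  need <- c("cell_id", "country_id", "month_index", "conc_ppb")
  miss <- setdiff(need, names(field))
  if (length(miss)) {
    abort(sprintf("concentration field is missing column(s): %s.",
                  paste(miss, collapse = ", ")),
          class = "ozonebw_value_error")
  }
  invisible(field)
}

# cell x month matrix from a long field table; errors on gaps
field_matrix <- function(field) {
  check_field(field)
  months <- sort(unique(field$month_index))
  if (!identical(months, seq(min(months), max(months)))) {
    abort("field month indices are not consecutive.",
          class = "ozonebw_value_error")
  }
  cells <- sort(unique(field$cell_id))
  m <- matrix(NA_real_, nrow = length(cells), ncol = length(months),
              dimnames = list(cells, months))
  m[cbind(match(field$cell_id, cells), match(field$month_index, months))] <-
    field$conc_ppb
  if (anyNA(m)) {
    abort("field has missing (cell, month) combinations.",
          class = "ozonebw_value_error")
  }
  m
}

#' Annual peak-season concentration field from monthly data
#'
#' Reduces a monthly concentration field to the gridded annual peak-season
#' concentration: per cell, the maximum 6-month running mean within the
#' calendar year (7 windows of 6 consecutive months). This is the `C_{s,y}`
#' input of the burden equation.
#'
#' @param field Long-format monthly field: columns `cell_id`, `country_id`,
#'   `month_index`, `conc_ppb`. Month index 1 is January of `epoch_year`.
#' @param years Calendar years to reduce; default every complete year in the
#'   field.
#' @param epoch_year Calendar year of month index 1.
#' @return Tibble with columns `cell_id`, `country_id`, `year`, `conc_ppb`.
#' @export
annual_peak_season <- function(field, years = NULL, epoch_year = 2003) {
  m <- field_matrix(field)
  idx <- as.integer(colnames(m))
  all_years <- epoch_year + (idx - 1L) %/% 12L
  complete <- as.integer(names(which(table(all_years) == 12L)))
  years <- years %||% complete
  bad <- setdiff(years, complete)
  if (length(bad)) {
    abort(sprintf("calendar year(s) %s not fully covered by the field.",
                  paste(bad, collapse = ", ")),
          class = "ozonebw_value_error")
  }
  cell_country <- field |> distinct(cell_id, country_id)
  purrr::map(years, function(y) {
    cols <- which(all_years == y)
    vals <- apply(m[, cols, drop = FALSE], 1, function(s) max(running_mean6(s)))
    tibble(cell_id = rownames(m), year = y, conc_ppb = unname(vals))
  }) |>
    list_rbind() |>
    left_join(cell_country, by = "cell_id") |>
    select(cell_id, country_id, year, conc_ppb)
}

#' Yearly peak-season exposure lookup
#'
#' Assigns each record the peak-season concentration of its grid cell for its
#' calendar year of birth (the "yearly exposure" used with annual-resolution
#' products).
#'
#' @param annual_field Output of [annual_peak_season()] (or any table with
#'   `cell_id`, `year`, `conc_ppb`).
#' @param records Tibble with `record_id`, `cell_id`, `birth_year`.
#' @return Tibble `record_id`, `value_ppb`.
#' @export
yearly_peak_season <- function(annual_field, records) {
  out <- records |>
    select(record_id, cell_id, birth_year) |>
    left_join(annual_field |> select(cell_id, year, conc_ppb),
              by = c("cell_id" = "cell_id", "birth_year" = "year"))
  if (anyNA(out$conc_ppb)) {
    miss <- out |> filter(is.na(conc_ppb)) |> head(3)
    abort(sprintf(
      "no annual peak-season value for %d record(s), e.g. cell %s year %d.",
      sum(is.na(out$conc_ppb)), miss$cell_id[1], miss$birth_year[1]),
      class = "ozonebw_value_error")
  }
  out |> select(record_id, value_ppb = conc_ppb)
}

#' Assign monthly-field exposure metrics to birth records
#'
#' Computes, per record, the peak-season (maximum 6-month running mean over
#' the 12 pre-birth months) or gestational (9-month pre-birth mean) exposure
#' from its grid cell's monthly series. Pre-birth windows end at the month
#' before birth. Temperature and fine-particle confounders on monthly grids
#' are prepared with the same call.
#'
#' @param records Tibble with `record_id`, `cell_id`, `birth_month_index`.
#' @param field Long-format monthly concentration field.
#' @param metric `"peak_season"` or `"gestational"`.
#' @param include_birth_month If `TRUE` the window ends at the birth month
#'   itself instead of the month before (alternative convention).
#' @return Tibble `record_id`, `metric`, `value_ppb`, `window_start`,
#'   `window_end` (month indices).
#' @export
assign_exposures <- function(records, field,
                             metric = c("peak_season", "gestational"),
                             include_birth_month = FALSE) {
  metric <- match.arg(metric)
  len <- if (metric == "peak_season") 12L else 9L
  m <- field_matrix(field)
  first_idx <- as.integer(colnames(m)[1])
  last_idx <- as.integer(colnames(m)[ncol(m)])
  offset <- if (include_birth_month) 0L else 1L

  combos <- records |> distinct(cell_id, birth_month_index)
  ends <- combos$birth_month_index - offset
  starts <- ends - len + 1L
  if (any(starts < first_idx) || any(ends > last_idx)) {
    abort(sprintf(
      "field does not cover the %d-month pre-birth window for all records (field spans month %d..%d).",
      len, first_idx, last_idx), class = "ozonebw_value_error")
  }
  combos$value_ppb <- vapply(seq_len(nrow(combos)), function(i) {
    s <- m[as.character(combos$cell_id[i]),
           as.character(seq(starts[i], ends[i]))]
    if (metric == "peak_season") max(running_mean6(s)) else mean(s)
  }, numeric(1))
  combos$window_start <- starts
  combos$window_end <- ends

  records |>
    select(record_id, cell_id, birth_month_index) |>
    left_join(combos, by = c("cell_id", "birth_month_index")) |>
    mutate(metric = metric) |>
    select(record_id, metric, value_ppb, window_start, window_end)
}
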