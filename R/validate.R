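#' Record-level validation filters for birth tables
#'
#' Applies the study-design exclusions to a raw birth table and reports
#' counts dropped per rule:
#'
#' 1. potential stillbirths — records whose birth and death dates are equal;
#' 2. records lacking birthweight;
#' 3. non-singleton births.
#'
#' The rules are independent predicates, so their order does not change the
#' retained set. A rule whose columns are absent drops nothing and is noted
#' in the report.
#'
#' @param records Tibble. Recognised columns: `birth_date`, `death_date`
#'   (stillbirth rule), `birthweight_g` (missing-birthweight rule),
#'   `singleton` (logical; non-singleton rule).
#' @return List with `records` (the retained rows) and `report` (tibble
#'   `rule`, `dropped`, `note`).
#' @examples
#' tb <- tibble::tibble(
#'   birthweight_g = c(3000, NA, 2800, NA, 3100, 2900, 3300, 2600, 3050, 2950),
#'   birth_date = c("2010-01-02", rep("2010-03-01", 9)),
#'   death_date = c("2010-01-02", rep(NA, 9)),
#'   singleton = c(rep(TRUE, 9), FALSE)
#' )
#' validate_births(tb)$report
#' @export
validate_births <- function(records) {
  n0 <- nrow(records)
  rules <- list()

  if (all(c("birth_date", "death_date") %in% names(records))) {
    still <- !is.na(records$birth_date) & !is.na(records$death_date) &
      records$birth_date == records$death_date
    note <- ""
  } else {
    still <- rep(FALSE, n0)
    note <- "birth_date/death_date columns absent; rule skipped"
  }
  rules$stillbirth <- list(drop = still, note = note)

  if ("birthweight_g" %in% names(records)) {
    rules$missing_birthweight <- list(drop = is.na(records$birthweight_g),
                                      note = "")
  } else {
    rules$missing_birthweight <- list(
      drop = rep(FALSE, n0), note = "birthweight_g column absent; rule skipped")
  }

  if ("singleton" %in% names(records)) {
    rules$non_singleton <- list(
      drop = !is.na(records$singleton) & !records$singleton, note = "")
  } else {
    rules$non_singleton <- list(
      drop = rep(FALSE, n0), note = "singleton column absent; rule skipped")
  }

  drop_any <- Reduce(`|`, lapply(rules, `[[`, "drop"))
  report <- tibble(
    rule = names(rules),
    dropped = vapply(rules, function(r) sum(r$drop), integer(1)),
    note = vapply(rules, `[[`, character(1), "note")
  ) |>
    bind_rows(tibble(rule = "retained", dropped = n0 - sum(drop_any),
                     note = ""))
  list(records = records[!drop_any, , drop = FALSE], report = report)
}
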