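#' Latitude zones for seasonality control
#'
#' Partitions latitudes into south (< 0 deg), tropical (0 to 23.5 deg) and
#' north (> 23.5 deg). Month of birth crossed with this zone is the
#' categorical seasonality control in all models.
#'
#' @param latitude_deg Latitudes in degrees (south negative).
#' @return Factor with levels `south`, `tropical`, `north`.
#' @export
lat_zone <- function(latitude_deg) {
  z <- ifelse(latitude_deg < 0, "south",
              ifelse(latitude_deg <= 23.5, "tropical", "north"))
  factor(z, levels = c("south", "tropical", "north"))
}

#' Covariate adjustment blocks
#'
#' The six ordered adjustment blocks used in the specification ladder from
#' unadjusted to fully adjusted: (i) environmental (fine particles and
#' temperature), (ii) birth characteristics (sex; month of birth x latitude
#' zone), (iii) pregnancy (cesarean, place of delivery, antenatal care,
#' nulliparity), (iv) reproductive history (maternal age, inter-pregnancy
#' interval), (v) maternal (BMI class, employment), and (vi) household (head
#' sex and age, water source, toilet type, cooking fuel).
#'
#' @return Named list mapping block name to covariate column names.
#' @export
covariate_blocks <- function() {
  list(
    environment = c("pm25_ugm3", "temperature_c"),
    birth = c("sex", "season"),
    pregnancy = c("cesarean", "place_of_delivery", "antenatal_care",
                  "nulliparous"),
    reproductive = c("maternal_age_y", "interpregnancy_interval_mo"),
    maternal = c("maternal_bmi_class", "maternal_employed"),
    household = c("head_sex", "head_age_y", "water_source", "toilet_type",
                  "cooking_fuel")
  )
}

# continuous confounders entered as natural cubic splines with 3 df
spline_covariates <- function() {
  c("temperature_c", "maternal_age_y", "interpregnancy_interval_mo",
    "head_age_y")
}

# natural cubic spline basis, 3 df, boundary knots at the 1st/99th pctiles
ns3 <- function(x, df = 3) {
  bk <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
  if (bk[1] >= bk[2]) bk <- range(x)
  splines::ns(x, df = df, Boundary.knots = bk)
}

# Build the (non-fixed-effect) regressor matrix for a model.
# exposure_cols: named list of numeric columns entered as-is (already scaled).
build_design <- function(data, exposure_cols, covariates) {
  n <- nrow(data)
  mats <- list()
  for (nm in names(exposure_cols)) {
    mats[[nm]] <- matrix(exposure_cols[[nm]], ncol = 1,
                         dimnames = list(NULL, nm))
  }
  for (v in covariates) {
    if (v == "season") {
      z <- interaction(factor(data$birth_month, levels = 1:12),
                       lat_zone(data$latitude_deg), drop = TRUE)
      mm <- model.matrix(~ z)[, -1, drop = FALSE]
      colnames(mm) <- sub("^z", "season", colnames(mm))
      mats[[v]] <- mm
    } else if (v == "nulliparous") {
      mats[[v]] <- matrix(as.numeric(data$parity == 1), ncol = 1,
                          dimnames = list(NULL, "nulliparous"))
    } else {
      if (!v %in% names(data)) {
        abort(sprintf("covariate `%s` not found in the data.", v),
              class = "ozonebw_value_error")
      }
      x <- data[[v]]
      if (is.numeric(x) && v %in% spline_covariates() &&
          length(unique(x)) > 4) {
        b <- ns3(x)
        colnames(b) <- paste0(v, "_ns", seq_len(ncol(b)))
        mats[[v]] <- b
      } else if (is.numeric(x)) {
        mats[[v]] <- matrix(x, ncol = 1, dimnames = list(NULL, v))
      } else {
        xf <- droplevels(factor(x))
        if (nlevels(xf) < 2) next  # constant; absorbed by the intercept/FE
        mm <- model.matrix(~ xf)[, -1, drop = FALSE]
        colnames(mm) <- sub("^xf", paste0(v, "_"), colnames(mm))
        mats[[v]] <- mm
      }
    }
  }
  X <- do.call(cbind, mats)
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0)
  # columns from multi-column expansions (factor/season/spline dummies) may
  # be aliased with the fixed effects or each other without that signalling
  # a user error; they are droppable during collinearity screening
  expanded <- unlist(lapply(mats[setdiff(names(mats), names(exposure_cols))],
                            function(m) if (ncol(m) > 1) colnames(m)),
                     use.names = FALSE)
  attr(X, "droppable") <- expanded %||% character(0)
  X
}

# weighted within-group demeaning of a matrix (and vector) by stratum
wdemean <- function(X, w, g) {
  gw <- rowsum(w, g)
  gm <- rowsum(X * w, g) / as.vector(gw)
  X - gm[match(g, rownames(gm)), , drop = FALSE]
}

# drop singleton strata (absorbed entirely by their fixed effect)
drop_singletons <- function(data, stratum) {
  sizes <- table(data[[stratum]])
  singles <- names(sizes)[sizes < 2]
  if (length(singles)) {
    warn(sprintf("%d stratum/strata with a single record drop out of the fixed-effects fit.",
                 length(singles)))
    data <- data[!data[[stratum]] %in% singles, , drop = FALSE]
  }
  data
}

# identify regressors absorbed by the fixed effects or aliased with other
# regressors after absorption; aliased columns listed in `droppable`
# (factor-expansion dummies) are removed silently, others raise an error
screen_columns <- function(X, w, g, droppable = character(0)) {
  Xd <- wdemean(X, w, g)
  ss_orig <- colSums(w * X^2)
  ss_dem <- colSums(w * Xd^2)
  absorbed <- ss_dem <= 1e-10 * (ss_orig + 1)
  keep <- which(!absorbed)
  if (!length(keep)) {
    abort("every regressor is stratum-constant (absorbed by the fixed effects).",
          class = "ozonebw_value_error")
  }
  qrd <- qr(sqrt(w) * Xd[, keep, drop = FALSE])
  indep <- sort(qrd$pivot[seq_len(qrd$rank)])
  aliased <- colnames(X)[keep[-indep]]
  if (qrd$rank < length(keep)) {
    bad <- setdiff(aliased, droppable)
    if (length(bad)) {
      abort(sprintf("collinear regressor(s) after fixed-effect absorption: %s.",
                    paste(bad, collapse = ", ")),
            class = "ozonebw_value_error")
    }
    keep <- keep[indep]
  }
  list(keep = keep,
       dropped = c(colnames(X)[absorbed], aliased))
}

# core absorbed weighted least squares with cluster-robust vcov
fe_wls <- function(y, X, w, g, se_type = "cluster") {
  scr <- screen_columns(X, w, g, attr(X, "droppable") %||% character(0))
  dropped <- scr$dropped
  Xd <- wdemean(X[, scr$keep, drop = FALSE], w, g)
  yd <- as.vector(wdemean(matrix(y, ncol = 1), w, g))
  fit <- lm(yd ~ 0 + Xd, weights = w)
  cf <- coef(fit)
  if (anyNA(cf)) {
    bad <- colnames(Xd)[is.na(cf)]
    abort(sprintf("collinear regressor(s) after fixed-effect absorption: %s.",
                  paste(bad, collapse = ", ")),
          class = "ozonebw_value_error")
  }
  V <- switch(se_type,
    cluster = sandwich::vcovCL(fit, cluster = factor(g)),
    HC1 = sandwich::vcovHC(fit, type = "HC1"),
    iid = vcov(fit),
    abort("`se_type` must be one of cluster, HC1, iid.")
  )
  names(cf) <- colnames(Xd)
  dimnames(V) <- list(colnames(Xd), colnames(Xd))
  list(coef = cf, vcov = V, dropped = dropped, fit = fit,
       n = length(y), n_strata = length(unique(g)))
}

#' Survey-weighted stratified fixed-effects birthweight model
#'
#' Fits the linear association between an exposure and birthweight with
#' sampling-stratum fixed effects absorbed, per-record sampling weights, and
#' heteroskedasticity-robust standard errors clustered by stratum. Continuous
#' confounders among temperature, maternal age, inter-pregnancy interval and
#' household-head age enter as natural cubic splines with three degrees of
#' freedom; seasonality enters as month of birth crossed with latitude zone
#' (`"season"` in `covariates`). The effect is reported per 10-ppb increment.
#'
#' Two algebraically equivalent fitting paths are available: weighted
#' within-stratum demeaning (default, Frisch-Waugh-Lovell absorption) and
#' explicit stratum dummy variables. They agree to numerical precision and
#' the dummy path is retained as a cross-check.
#'
#' @param data Tibble of birth records joined with an exposure column.
#' @param exposure Name of the exposure column (ppb).
#' @param covariates Character vector of covariate names (columns of `data`,
#'   plus the special terms `"season"` and `"nulliparous"`), or a subset of
#'   block names from [covariate_blocks()] via `blocks`.
#' @param blocks Optional character vector of adjustment-block names; their
#'   covariates are appended to `covariates`.
#' @param outcome,stratum,weight Column names for the outcome (g), stratum ID
#'   and sampling weight.
#' @param method `"demean"` (absorption) or `"dummies"` (explicit stratum
#'   indicators).
#' @param se_type `"cluster"` (default; clustered by stratum), `"HC1"`, or
#'   `"iid"`.
#' @param effect_scale_ppb Increment the coefficient is reported for
#'   (default 10 ppb).
#' @return An object of class `o3_fe_fit` with elements `estimate` (tibble:
#'   term, estimate, se, conf.low, conf.high), `beta_g_per_10ppb`, `se`,
#'   `ci95`, full `coef`/`vcov`, `n`, `n_strata`, `dropped_terms`.
#' @examples
#' cfg <- sim_config(n_countries = 2, strata_per_country = 10,
#'                   births_per_stratum = 20, true_erf = erf_linear(-2),
#'                   seed = 7)
#' fld <- simulate_concentration_field(cfg)
#' b <- simulate_births(cfg, fld)
#' b$exposure_ppb <- b$true_exposure_ppb
#' fit <- fit_birthweight_fe(b, exposure = "exposure_ppb",
#'                           covariates = c("sex", "season"))
#' tidy(fit)
#' @export
fit_birthweight_fe <- function(data, exposure,
                               covariates = character(),
                               blocks = NULL,
                               outcome = "birthweight_g",
                               stratum = "stratum_id",
                               weight = "sampling_weight",
                               method = c("demean", "dummies"),
                               se_type = c("cluster", "HC1", "iid"),
                               effect_scale_ppb = 10) {
  method <- match.arg(method)
  se_type <- match.arg(se_type)
  covariates <- resolve_blocks(covariates, blocks)
  check_cols(data, c(exposure, outcome, stratum, weight))
  data <- drop_singletons(data, stratum)

  xname <- sprintf("exposure_per%g", effect_scale_ppb)
  xcols <- setNames(list(data[[exposure]] / effect_scale_ppb), xname)
  X <- build_design(data, xcols, covariates)
  y <- data[[outcome]]
  w <- data[[weight]]
  g <- data[[stratum]]

  if (method == "demean") {
    res <- fe_wls(y, X, w, g, se_type)
  } else {
    res <- fe_dummies(y, X, w, g, se_type)
  }
  b <- res$coef[[xname]]
  se <- sqrt(res$vcov[xname, xname])
  est <- tibble(
    term = names(res$coef),
    estimate = unname(res$coef),
    std.error = sqrt(diag(res$vcov)),
    conf.low = unname(res$coef) - 1.96 * sqrt(diag(res$vcov)),
    conf.high = unname(res$coef) + 1.96 * sqrt(diag(res$vcov))
  )
  structure(list(
    estimate = est, exposure_term = xname,
    beta_g_per_10ppb = b, se = se, ci95 = c(b - 1.96 * se, b + 1.96 * se),
    coef = res$coef, vcov = res$vcov, dropped_terms = res$dropped,
    n = res$n, n_strata = res$n_strata, method = method, se_type = se_type,
    covariates = covariates, effect_scale_ppb = effect_scale_ppb
  ), class = "o3_fe_fit")
}

resolve_blocks <- function(covariates, blocks) {
  if (!is.null(blocks)) {
    defs <- covariate_blocks()
    bad <- setdiff(blocks, names(defs))
    if (length(bad)) {
      abort(sprintf("unknown covariate block(s): %s.",
                    paste(bad, collapse = ", ")),
            class = "ozonebw_value_error")
    }
    covariates <- unique(c(covariates, unlist(defs[blocks], use.names = FALSE)))
  }
  covariates
}

check_cols <- function(data, cols) {
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    abort(sprintf("data is missing column(s): %s.",
                  paste(miss, collapse = ", ")),
          class = "ozonebw_value_error")
  }
  invisible(data)
}

# explicit stratum-dummy path (cross-check for the absorption path)
fe_dummies <- function(y, X, w, g, se_type = "cluster") {
  # remove absorbed/aliased regressors first so both paths share a basis
  scr <- screen_columns(X, w, g, attr(X, "droppable") %||% character(0))
  dropped <- scr$dropped
  X <- X[, scr$keep, drop = FALSE]
  gf <- factor(g)
  D <- model.matrix(~ 0 + gf)
  fit <- lm(y ~ 0 + cbind(X, D), weights = w)
  cf <- coef(fit)
  names(cf) <- sub("^cbind\\(X, D\\)", "", names(cf))
  keep <- colnames(X)
  if (anyNA(cf[keep])) {
    abort(sprintf("collinear regressor(s): %s.",
                  paste(keep[is.na(cf[keep])], collapse = ", ")),
          class = "ozonebw_value_error")
  }
  V <- switch(se_type,
    cluster = sandwich::vcovCL(fit, cluster = gf),
    HC1 = sandwich::vcovHC(fit, type = "HC1"),
    iid = vcov(fit)
  )
  dimnames(V) <- list(names(cf), names(cf))
  list(coef = cf[keep], vcov = V[keep, keep, drop = FALSE],
       dropped = dropped, fit = fit,
       n = length(y), n_strata = nlevels(gf))
}

#' @export
print.o3_fe_fit <- function(x, ...) {
  cat("<o3_fe_fit> weighted stratified fixed-effects model\n")
  cat(sprintf("  n = %d records in %d strata (%s path, %s SEs)\n",
              x$n, x$n_strata, x$method, x$se_type))
  cat(sprintf("  birthweight change per %g ppb: %.1f g (95%% CI %.1f to %.1f)\n",
              x$effect_scale_ppb, x$beta_g_per_10ppb, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @export
tidy.o3_fe_fit <- function(x, all_terms = FALSE, ...) {
  out <- x$estimate
  if (!all_terms) out <- out |> filter(.data$term == x$exposure_term)
  out
}

#' @export
glance.o3_fe_fit <- function(x, ...) {
  tibble(n = x$n, n_strata = x$n_strata,
         beta_g_per_10ppb = x$beta_g_per_10ppb, se = x$se,
         conf.low = x$ci95[1], conf.high = x$ci95[2],
         method = x$method, se_type = x$se_type)
}

#' Weighted stratified logit model for low birthweight
#'
#' Replaces birthweight with the low-birthweight indicator (birthweight
#' below 2500 g; exactly 2500 g is not LBW) and fits a sampling-weighted
#' logit with explicit stratum indicators. Strata without outcome variation
#' carry no information under stratum fixed effects and are excluded with a
#' message. Reports the odds ratio per 10-ppb increment with a
#' cluster-robust 95% CI. Note the usual incidental-parameter caveat for
#' dummy-variable logit with small strata.
#'
#' @inheritParams fit_birthweight_fe
#' @param lbw_threshold_g Threshold in grams (default 2500).
#' @return Object of class `o3_lbw_fit` with `or_per_10ppb`, `ci95`,
#'   `log_or`, `se`, `n`, `n_strata`, `n_strata_excluded`.
#' @export
fit_lbw_logit <- function(data, exposure,
                          covariates = character(),
                          blocks = NULL,
                          outcome = "birthweight_g",
                          stratum = "stratum_id",
                          weight = "sampling_weight",
                          lbw_threshold_g = 2500,
                          effect_scale_ppb = 10) {
  covariates <- resolve_blocks(covariates, blocks)
  check_cols(data, c(exposure, outcome, stratum, weight))
  data$.lbw <- as.numeric(data[[outcome]] < lbw_threshold_g)
  keep <- data |>
    group_by(.data[[stratum]]) |>
    summarise(var_ok = dplyr::n_distinct(.lbw) > 1) |>
    filter(var_ok)
  n_excl <- dplyr::n_distinct(data[[stratum]]) - nrow(keep)
  if (n_excl > 0) {
    inform(sprintf("%d stratum/strata without outcome variation excluded from the logit fit.",
                   n_excl))
  }
  data <- data |> filter(.data[[stratum]] %in% keep[[stratum]])
  data <- drop_singletons(data, stratum)

  xname <- sprintf("exposure_per%g", effect_scale_ppb)
  X <- build_design(data,
                    setNames(list(data[[exposure]] / effect_scale_ppb), xname),
                    covariates)
  scr <- screen_columns(X, data[[weight]], data[[stratum]],
                        attr(X, "droppable") %||% character(0))
  X <- X[, scr$keep, drop = FALSE]
  gf <- factor(data[[stratum]])
  D <- model.matrix(~ 0 + gf)
  XX <- cbind(X, D)
  fit <- suppressWarnings(
    glm.fit2(XX, data$.lbw, data[[weight]])
  )
  cf <- fit$coef
  if (is.na(cf[xname]) || abs(cf[xname]) > 20) {
    abort(paste("logit fit appears separated (exposure coefficient not",
                "identifiable); consider a penalized refit on a reduced",
                "covariate set."), class = "ozonebw_fit_error")
  }
  V <- sandwich::vcovCL(fit$glm, cluster = gf)
  rownames(V) <- colnames(V) <- names(cf)
  lo <- cf[[xname]]
  se <- sqrt(V[xname, xname])
  structure(list(
    or_per_10ppb = exp(lo), ci95 = exp(c(lo - 1.96 * se, lo + 1.96 * se)),
    log_or = lo, se = se, n = nrow(data), n_strata = nlevels(gf),
    n_strata_excluded = n_excl, lbw_threshold_g = lbw_threshold_g,
    prevalence = weighted.mean(data$.lbw, data[[weight]])
  ), class = "o3_lbw_fit")
}

# quasibinomial WLS-IRLS wrapper returning both coefficients and glm object
glm.fit2 <- function(X, y, w) {
  df <- data.frame(y = y)
  g <- glm(y ~ 0 + X, family = quasibinomial(), weights = w, data = df)
  cf <- coef(g)
  names(cf) <- sub("^X", "", names(cf))
  list(coef = cf, glm = g)
}

#' @export
print.o3_lbw_fit <- function(x, ...) {
  cat("<o3_lbw_fit> weighted stratified logit for low birthweight\n")
  cat(sprintf("  n = %d in %d strata (%d excluded, no outcome variation)\n",
              x$n, x$n_strata, x$n_strata_excluded))
  cat(sprintf("  OR per 10 ppb: %.3f (95%% CI %.3f to %.3f)\n",
              x$or_per_10ppb, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @export
tidy.o3_lbw_fit <- function(x, ...) {
  tibble(term = "exposure_per10", estimate = x$or_per_10ppb,
         std.error = x$se, conf.low = x$ci95[1], conf.high = x$ci95[2])
}

#' Effect-modification (interaction) analysis
#'
#' Fits a single stratified fixed-effects model in which the exposure slope
#' is allowed to differ by level of a categorical modifier (exposure x level
#' terms plus the modifier main effect), and tests slope homogeneity with a
#' joint Wald test on the interaction contrasts. Modifier levels observed in
#' fewer than two strata are flagged and excluded.
#'
#' @inheritParams fit_birthweight_fe
#' @param modifier Name of a categorical column of `data`.
#' @return Object of class `o3_interaction` with `effects` (tibble: level,
#'   estimate, se, conf.low, conf.high, n), `wald_chisq`, `wald_df`,
#'   `wald_p` (NA with a note when fewer than two levels are estimable),
#'   `excluded_levels`.
#' @export
interaction_analysis <- function(data, exposure, modifier,
                                 covariates = character(),
                                 blocks = NULL,
                                 outcome = "birthweight_g",
                                 stratum = "stratum_id",
                                 weight = "sampling_weight",
                                 se_type = c("cluster", "HC1", "iid"),
                                 effect_scale_ppb = 10) {
  se_type <- match.arg(se_type)
  covariates <- resolve_blocks(covariates, blocks)
  check_cols(data, c(exposure, modifier, outcome, stratum, weight))
  data <- drop_singletons(data, stratum)

  mod <- droplevels(factor(data[[modifier]]))
  lev_strata <- table(distinct(tibble(l = mod, s = data[[stratum]])))
  n_strata_per_level <- rowSums(lev_strata > 0)
  excluded <- names(n_strata_per_level)[n_strata_per_level < 2]
  if (length(excluded)) {
    warn(sprintf("modifier level(s) observed in <2 strata excluded: %s.",
                 paste(excluded, collapse = ", ")))
    keep <- !(mod %in% excluded)
    data <- data[keep, , drop = FALSE]
    mod <- droplevels(mod[keep])
  }
  levs <- levels(mod)
  x10 <- data[[exposure]] / effect_scale_ppb
  xcols <- setNames(
    lapply(levs, function(l) x10 * (mod == l)),
    paste0("exposure_per10:", levs)
  )
  data$.modifier <- mod
  covs <- unique(c(".modifier", setdiff(covariates, modifier)))
  X <- build_design(data, xcols, covs)
  res <- fe_wls(data[[outcome]], X, data[[weight]], data[[stratum]], se_type)

  terms <- paste0("exposure_per10:", levs)
  est_levs <- levs[terms %in% names(res$coef)]
  terms <- terms[terms %in% names(res$coef)]
  b <- res$coef[terms]
  se <- sqrt(diag(res$vcov)[terms])
  effects <- tibble(
    level = est_levs, estimate = unname(b), std.error = unname(se),
    conf.low = unname(b - 1.96 * se), conf.high = unname(b + 1.96 * se),
    n = as.integer(table(mod)[est_levs])
  )
  if (length(terms) >= 2) {
    L <- length(terms)
    R <- cbind(-1, diag(L - 1))
    colnames(R) <- terms
    Rb <- as.vector(R %*% b)
    RVR <- R %*% res$vcov[terms, terms] %*% t(R)
    wald <- as.numeric(t(Rb) %*% solve(RVR, Rb))
    wald_df <- L - 1L
    wald_p <- pchisq(wald, wald_df, lower.tail = FALSE)
  } else {
    wald <- NA_real_; wald_df <- NA_integer_; wald_p <- NA_real_
    inform("interaction not estimable: modifier has a single usable level; result equals the main fit.")
  }
  structure(list(
    modifier = modifier, effects = effects,
    wald_chisq = wald, wald_df = wald_df, wald_p = wald_p,
    excluded_levels = excluded, n = res$n, n_strata = res$n_strata
  ), class = "o3_interaction")
}

#' @export
print.o3_interaction <- function(x, ...) {
  cat(sprintf("<o3_interaction> modifier `%s` (n = %d, %d strata)\n",
              x$modifier, x$n, x$n_strata))
  print(x$effects)
  if (is.na(x$wald_p)) {
    cat("  joint Wald test: not estimable (single level)\n")
  } else {
    cat(sprintf("  joint Wald test of slope homogeneity: chi2(%d) = %.2f, p = %.3g\n",
                x$wald_df, x$wald_chisq, x$wald_p))
  }
  invisible(x)
}

#' @export
tidy.o3_interaction <- function(x, ...) x$effects
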