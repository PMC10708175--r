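#' Varying-coefficient model for the marginal exposure effect
#'
#' Estimates how the marginal effect of within-stratum exposure variation on
#' birthweight changes with the stratum-level average exposure — the first
#' derivative of the exposure-response function. The fixed-effects model of
#' [fit_birthweight_fe()] is refitted with the exposure term replaced by
#' `(within-stratum deviation / 10) x B(stratum mean)`, where `B` is a
#' natural cubic spline basis (intercept plus `df - 1` spline columns, knots
#' at stratum-mean quantiles). Covariates, weights, fixed-effect absorption
#' and cluster-robust covariance are inherited unchanged. With `df = 1` the
#' basis is the intercept alone and the fit reproduces the linear model
#' exactly.
#'
#' Within-stratum deviations are taken about the sampling-weighted stratum
#' mean, so the interaction columns are orthogonal to the stratum fixed
#' effects by construction.
#'
#' @inheritParams fit_birthweight_fe
#' @param df Degrees of freedom of the marginal-effect curve (total basis
#'   columns, including the intercept). Default 3.
#' @param grid_step Evaluation-grid step in ppb (default 0.25).
#' @return Object of class `marginal_effect_curve`: evaluation `grid` (ppb),
#'   `beta` (g per 10 ppb at each grid point), basis coefficient vector
#'   `coef` and covariance `vcov`, a `basis` closure, the observed
#'   stratum-mean range `cbar_range`, `n`, `n_strata`.
#' @export
fit_varying_coefficient <- function(data, exposure,
                                    covariates = character(),
                                    blocks = NULL,
                                    df = 3,
                                    outcome = "birthweight_g",
                                    stratum = "stratum_id",
                                    weight = "sampling_weight",
                                    se_type = c("cluster", "HC1", "iid"),
                                    effect_scale_ppb = 10,
                                    grid_step = 0.25) {
  se_type <- match.arg(se_type)
  covariates <- resolve_blocks(covariates, blocks)
  check_cols(data, c(exposure, outcome, stratum, weight))
  if (df < 1 || df != floor(df)) {
    abort("`df` must be a positive integer.", class = "ozonebw_value_error")
  }
  data <- drop_singletons(data, stratum)

  x <- data[[exposure]]
  w <- data[[weight]]
  g <- data[[stratum]]
  cbar_map <- tibble(g = g, x = x, w = w) |>
    group_by(g) |>
    summarise(cbar = weighted.mean(x, w), .groups = "drop")
  cbar_s <- cbar_map$cbar
  if (length(cbar_s) < 10) {
    abort("at least 10 strata are required to estimate a marginal-effect curve.",
          class = "ozonebw_value_error")
  }
  if (diff(range(cbar_s)) < 5) {
    abort("stratum-mean exposure range below 5 ppb: the curve is not identifiable.",
          class = "ozonebw_value_error")
  }
  cbar <- cbar_map$cbar[match(g, cbar_map$g)]
  dev10 <- (x - cbar) / effect_scale_ppb

  basis <- make_vc_basis(cbar_s, df)
  B <- basis(cbar)
  xcols <- setNames(
    lapply(seq_len(ncol(B)), function(k) dev10 * B[, k]),
    colnames(B)
  )
  X <- build_design(data, xcols, covariates)
  res <- tryCatch(
    fe_wls(data[[outcome]], X, w, g, se_type),
    error = function(e) {
      if (grepl("collinear", conditionMessage(e)) &&
          grepl("vc_b", conditionMessage(e))) {
        abort("varying-coefficient basis is rank deficient; refit with fewer df.",
              class = "ozonebw_value_error")
      }
      stop(e)
    }
  )
  vc_terms <- colnames(B)
  if (!all(vc_terms %in% names(res$coef))) {
    abort("varying-coefficient basis is rank deficient (columns absorbed); refit with fewer df.",
          class = "ozonebw_value_error")
  }
  gam <- res$coef[vc_terms]
  V <- res$vcov[vc_terms, vc_terms, drop = FALSE]
  V <- (V + t(V)) / 2

  grid <- seq(min(cbar_s), max(cbar_s), by = grid_step)
  beta <- as.vector(basis(grid) %*% gam)
  structure(list(
    grid = grid, beta = beta, coef = gam, vcov = V, basis = basis,
    df = df, cbar_range = range(cbar_s), n = res$n, n_strata = res$n_strata,
    se_type = se_type, covariates = covariates
  ), class = "marginal_effect_curve")
}

# natural-cubic-spline basis closure for the stratum-mean axis:
# column 1 is the intercept; df - 1 ns columns with knots at stratum-mean
# quantiles and boundary knots at the observed stratum-mean range
make_vc_basis <- function(cbar_s, df) {
  if (df == 1) {
    return(function(cc) matrix(1, length(cc), 1, dimnames = list(NULL, "vc_b1")))
  }
  bk <- range(cbar_s)
  inner_df <- df - 1
  proto <- splines::ns(cbar_s, df = inner_df, Boundary.knots = bk)
  knots <- attr(proto, "knots")
  function(cc) {
    m <- cbind(1, splines::ns(cc, knots = knots, Boundary.knots = bk))
    colnames(m) <- paste0("vc_b", seq_len(ncol(m)))
    m
  }
}

#' @export
print.marginal_effect_curve <- function(x, ...) {
  cat(sprintf("<marginal_effect_curve> df = %d, %d strata (means %.1f-%.1f ppb)\n",
              x$df, x$n_strata, x$cbar_range[1], x$cbar_range[2]))
  cat(sprintf("  marginal effect at the stratum-mean midpoint: %.1f g per 10 ppb\n",
              marginal_effect_at(x, mean(x$cbar_range))$estimate))
  invisible(x)
}

#' @export
tidy.marginal_effect_curve <- function(x, ...) {
  B <- x$basis(x$grid)
  se <- sqrt(pmax(0, rowSums((B %*% x$vcov) * B)))
  tibble(grid_ppb = x$grid, estimate = x$beta, std.error = se,
         conf.low = x$beta - 1.96 * se, conf.high = x$beta + 1.96 * se)
}

#' Marginal effect at a given stratum-mean concentration
#'
#' Pointwise readout of the marginal-effect curve: birthweight change
#' (g per 10 ppb) at concentration `c_ppb`, with a delta-method 95% CI from
#' the basis-coefficient covariance.
#'
#' @param curve A [fit_varying_coefficient()] result.
#' @param c_ppb Concentration(s) in ppb.
#' @param allow_extrapolation Evaluate outside the observed stratum-mean
#'   range (natural splines extrapolate linearly). Default errors instead.
#' @return Tibble `c_ppb`, `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @export
marginal_effect_at <- function(curve, c_ppb, allow_extrapolation = FALSE) {
  stopifnot(inherits(curve, "marginal_effect_curve"))
  out <- c_ppb < curve$cbar_range[1] - 1e-9 |
    c_ppb > curve$cbar_range[2] + 1e-9
  if (any(out) && !allow_extrapolation) {
    abort(sprintf("c_ppb outside the observed stratum-mean range [%.2f, %.2f]; set allow_extrapolation = TRUE to extrapolate.",
                  curve$cbar_range[1], curve$cbar_range[2]),
          class = "ozonebw_value_error")
  }
  B <- curve$basis(c_ppb)
  est <- as.vector(B %*% curve$coef)
  se <- sqrt(pmax(0, rowSums((B %*% curve$vcov) * B)))
  tibble(c_ppb = c_ppb, estimate = est, std.error = se,
         conf.low = est - 1.96 * se, conf.high = est + 1.96 * se)
}

# cumulative trapezoid of y over x, anchored to zero at x = anchor
cumtrapz_from <- function(x, y, anchor) {
  if (is.unsorted(x, strictly = TRUE)) {
    abort("integration grid must be strictly increasing with no duplicates.",
          class = "ozonebw_value_error")
  }
  i0 <- which(abs(x - anchor) < 1e-9)
  if (!length(i0)) {
    abort("integration grid must contain the TMREL as a grid point.",
          class = "ozonebw_value_error")
  }
  ct <- c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
  ct - ct[i0[1]]
}

# default integration grid: step-spaced, spans the curve support and the
# TMREL, and contains the TMREL exactly
erf_grid <- function(curve, tmrel_ppb, step = 0.25) {
  lo <- min(curve$cbar_range[1], tmrel_ppb)
  hi <- max(curve$cbar_range[2], tmrel_ppb)
  sort(unique(c(rev(seq(tmrel_ppb, lo, by = -step)),
                seq(tmrel_ppb, hi, by = step))))
}

#' Integrate the marginal-effect curve into the nonlinear ERF
#'
#' Integrates the per-ppb marginal effect (`beta(u)/10`) from the TMREL by
#' cumulative trapezoid, giving the exposure-response function
#' `ERF(c) = integral from TMREL to c of beta(u)/10 du`: the birthweight
#' change (g) for an increase from the TMREL to concentration `c`. Negative
#' values are birthweight reductions; concentrations below the TMREL yield
#' the signed (positive) integral. `ERF(TMREL) = 0` by construction.
#'
#' @param curve A [fit_varying_coefficient()] result.
#' @param tmrel_ppb Theoretical minimum risk exposure level (ppb); default
#'   the WHO AQG. See [tmrel_preset()].
#' @param grid Optional strictly increasing integration grid containing
#'   `tmrel_ppb`; default a 0.25-ppb grid spanning the curve support and the
#'   TMREL.
#' @param step Grid step (ppb) for the default grid.
#' @return Object of class `o3_erf`: `grid`, `mean_g`, `tmrel_ppb`; no
#'   uncertainty until [erf_uncertainty()] is applied.
#' @export
integrate_erf <- function(curve, tmrel_ppb = tmrel_preset("aqg"),
                          grid = NULL, step = 0.25) {
  stopifnot(inherits(curve, "marginal_effect_curve"))
  grid <- grid %||% erf_grid(curve, tmrel_ppb, step)
  beta <- as.vector(curve$basis(grid) %*% curve$coef)
  mean_g <- cumtrapz_from(grid, beta / 10, tmrel_ppb)
  structure(list(
    grid = grid, mean_g = mean_g, tmrel_ppb = tmrel_ppb,
    draws = NULL, lo = NULL, hi = NULL,
    meta = list(df = curve$df, cbar_range = curve$cbar_range,
                n = curve$n, n_strata = curve$n_strata)
  ), class = "o3_erf")
}

#' Monte Carlo uncertainty for the ERF
#'
#' Propagates the cluster-robust coefficient covariance of the
#' marginal-effect curve into pointwise ERF confidence bands: coefficient
#' vectors are drawn from a multivariate normal centred at the estimate,
#' each draw's marginal curve is integrated from the TMREL
#' (integrate-then-summarise, preserving dependence across grid points), and
#' the pointwise 2.5th/97.5th percentiles form the 95% CI. The draw matrix is
#' retained so downstream burden CIs use the same ERF uncertainty.
#'
#' @inheritParams integrate_erf
#' @param n_draws Number of Monte Carlo draws (>= 200).
#' @param seed Integer seed (draws are reproducible).
#' @return Object of class `o3_erf` with `draws` (`n_draws` x grid matrix),
#'   `lo`, `hi`.
#' @export
erf_uncertainty <- function(curve, tmrel_ppb = tmrel_preset("aqg"),
                            grid = NULL, n_draws = 1000, seed = 1L,
                            step = 0.25) {
  stopifnot(inherits(curve, "marginal_effect_curve"))
  if (n_draws < 200) {
    abort("`n_draws` must be at least 200.", class = "ozonebw_value_error")
  }
  ev <- eigen(curve$vcov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    abort("coefficient covariance is not positive semidefinite; repair it (nearest-PSD) before drawing.",
          class = "ozonebw_value_error")
  }
  grid <- grid %||% erf_grid(curve, tmrel_ppb, step)
  B <- curve$basis(grid)
  point <- cumtrapz_from(grid, as.vector(B %*% curve$coef) / 10, tmrel_ppb)
  withr_seed(seed, "draws", {
    G <- MASS::mvrnorm(n_draws, mu = curve$coef,
                       Sigma = fix_psd(curve$vcov))
    beta_draws <- G %*% t(B)  # n_draws x n_grid
    draws <- t(apply(beta_draws, 1, function(bb)
      cumtrapz_from(grid, bb / 10, tmrel_ppb)))
    ci <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    structure(list(
      grid = grid, mean_g = point, tmrel_ppb = tmrel_ppb,
      draws = draws, lo = ci[1, ], hi = ci[2, ],
      meta = list(df = curve$df, cbar_range = curve$cbar_range,
                  n = curve$n, n_strata = curve$n_strata,
                  n_draws = n_draws, seed = seed)
    ), class = "o3_erf")
  })
}

# clip tiny negative eigenvalues arising from floating-point asymmetry
fix_psd <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  e$vectors %*% diag(pmax(e$values, 0), nrow(V)) %*% t(e$vectors)
}

#' Build an exact ERF from a ground-truth specification
#'
#' Closed-form counterpart of [integrate_erf()] for a known generative ERF:
#' `ERF(c) = f(c) - f(TMREL)` on a grid, with zero uncertainty. Used to
#' drive the burden pipeline with the truth (bypassing estimation) in
#' validation studies.
#'
#' @param spec An `erf_spec` ([erf_linear()], [erf_piecewise()],
#'   [erf_sublinear()]).
#' @param tmrel_ppb Reference level (ppb).
#' @param grid Evaluation grid (ppb) containing `tmrel_ppb`.
#' @param n_draws If positive, replicates the exact curve as identical draws
#'   so Monte Carlo plumbing downstream still works (zero-width CIs).
#' @return Object of class `o3_erf`.
#' @export
erf_exact <- function(spec, tmrel_ppb = tmrel_preset("aqg"),
                      grid = seq(20, 80, by = 0.25), n_draws = 0) {
  stopifnot(inherits(spec, "erf_spec"))
  if (!any(abs(grid - tmrel_ppb) < 1e-9)) {
    grid <- sort(unique(c(grid, tmrel_ppb)))
  }
  mean_g <- true_erf(spec, grid) - true_erf(spec, tmrel_ppb)
  draws <- NULL; lo <- NULL; hi <- NULL
  if (n_draws > 0) {
    draws <- matrix(mean_g, nrow = n_draws, ncol = length(grid), byrow = TRUE)
    lo <- hi <- mean_g
  }
  structure(list(grid = grid, mean_g = mean_g, tmrel_ppb = tmrel_ppb,
                 draws = draws, lo = lo, hi = hi,
                 meta = list(exact = TRUE, type = spec$type)),
            class = "o3_erf")
}

#' @export
print.o3_erf <- function(x, ...) {
  cat(sprintf("<o3_erf> TMREL %.2f ppb, grid %.2f-%.2f ppb (%d points)\n",
              x$tmrel_ppb, min(x$grid), max(x$grid), length(x$grid)))
  if (!is.null(x$draws)) {
    cat(sprintf("  %d Monte Carlo draws; ", nrow(x$draws)))
  }
  i <- which.max(x$grid)
  cat(sprintf("ERF at %.1f ppb: %.1f g\n", x$grid[i], x$mean_g[i]))
  invisible(x)
}

#' @export
tidy.o3_erf <- function(x, ...) {
  tibble(grid_ppb = x$grid, estimate = x$mean_g,
         conf.low = x$lo %||% NA_real_, conf.high = x$hi %||% NA_real_)
}

# evaluate an ERF (mean or draws) at arbitrary concentrations
erf_eval <- function(erf, c_ppb, what = c("mean", "draws"),
                     extrapolation = c("clamp", "linear")) {
  what <- match.arg(what)
  extrapolation <- match.arg(extrapolation)
  ev1 <- function(yv) {
    out <- approx(erf$grid, yv, xout = pmin(pmax(c_ppb, min(erf$grid)),
                                            max(erf$grid)))$y
    if (extrapolation == "linear") {
      ng <- length(erf$grid)
      sl_hi <- (yv[ng] - yv[ng - 1]) / (erf$grid[ng] - erf$grid[ng - 1])
      sl_lo <- (yv[2] - yv[1]) / (erf$grid[2] - erf$grid[1])
      hi_i <- c_ppb > max(erf$grid)
      lo_i <- c_ppb < min(erf$grid)
      out[hi_i] <- yv[ng] + sl_hi * (c_ppb[hi_i] - erf$grid[ng])
      out[lo_i] <- yv[1] + sl_lo * (c_ppb[lo_i] - erf$grid[1])
    }
    out
  }
  if (what == "mean") return(ev1(erf$mean_g))
  if (is.null(erf$draws)) {
    abort("this ERF has no Monte Carlo draws; run erf_uncertainty() first.",
          class = "ozonebw_value_error")
  }
  t(apply(erf$draws, 1, ev1))  # n_draws x length(c_ppb)
}
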