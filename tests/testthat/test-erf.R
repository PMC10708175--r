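# hand-built marginal-effect curve with a known closed form
fake_curve <- function(basis, coef, vcov, cbar_range) {
  grid <- seq(cbar_range[1], cbar_range[2], by = 0.25)
  structure(list(
    grid = grid, beta = as.vector(basis(grid) %*% coef),
    coef = coef, vcov = vcov, basis = basis, df = length(coef),
    cbar_range = cbar_range, n = NA_integer_, n_strata = NA_integer_
  ), class = "marginal_effect_curve")
}
const_basis <- function(cc) matrix(1, length(cc), 1,
                                   dimnames = list(NULL, "vc_b1"))
lin_basis <- function(cc) cbind(vc_b1 = 1, vc_b2 = cc)

test_that("a one-df varying coefficient reproduces the linear fixed-effects fit", {
  d <- make_dataset(cfg_small())
  lin <- fit_birthweight_fe(d, "exposure_ppb", covariates = "sex")
  vc <- fit_varying_coefficient(d, "exposure_ppb", covariates = "sex", df = 1)
  expect_equal(unname(vc$coef), lin$beta_g_per_10ppb, tolerance = 1e-8)
  expect_true(all(abs(vc$beta - lin$beta_g_per_10ppb) < 1e-8))
})

test_that("identifiability preconditions are enforced", {
  d <- make_dataset(cfg_small())
  few <- d |> filter(stratum_id %in% unique(stratum_id)[1:5])
  expect_error(fit_varying_coefficient(few, "exposure_ppb"),
               "10 strata", class = "ozonebw_value_error")
  d_flat <- d |> mutate(exposure_ppb = 50 + (exposure_ppb - mean(exposure_ppb)) / 50)
  expect_error(fit_varying_coefficient(d_flat, "exposure_ppb"),
               "5 ppb", class = "ozonebw_value_error")
})

test_that("constant integrand integrates to an exactly linear ERF", {
  cur <- fake_curve(const_basis, coef = c(vc_b1 = -20),
                    vcov = matrix(0, 1, 1), cbar_range = c(25, 60))
  erf <- integrate_erf(cur, tmrel_ppb = 30)
  expect_equal(approx(erf$grid, erf$mean_g, 50)$y, -40, tolerance = 1e-10)
  i0 <- which(abs(erf$grid - 30) < 1e-9)
  expect_equal(erf$mean_g[i0], 0)
  # below the TMREL the signed integral is positive
  expect_true(all(erf$mean_g[erf$grid < 30] > 0))
})

test_that("a linear integrand matches the closed-form quadratic ERF", {
  a <- -35; b <- 0.3   # beta(u) = a + b u  (g per 10 ppb)
  cur <- fake_curve(lin_basis, coef = c(vc_b1 = a, vc_b2 = b),
                    vcov = matrix(0, 2, 2), cbar_range = c(25, 70))
  tm <- 30
  erf <- integrate_erf(cur, tmrel_ppb = tm, step = 0.05)
  closed <- function(cc) (a * (cc - tm) + b / 2 * (cc^2 - tm^2)) / 10
  expect_equal(erf$mean_g, closed(erf$grid), tolerance = 1e-6)
})

test_that("finite differences of the ERF recover the marginal curve", {
  d <- make_dataset(cfg_recovery(strata_per_country = 30,
                                 births_per_stratum = 20))
  vc <- fit_varying_coefficient(d, "exposure_ppb", covariates = "sex", df = 3)
  erf <- integrate_erf(vc, tmrel_ppb = mean(vc$cbar_range), step = 0.05)
  g <- erf$grid
  inner <- 3:(length(g) - 2)
  fd <- (erf$mean_g[inner + 1] - erf$mean_g[inner - 1]) / (g[inner + 1] - g[inner - 1])
  beta_inner <- as.vector(vc$basis(g[inner]) %*% vc$coef) / 10
  expect_lt(max(abs(fd - beta_inner) / max(abs(beta_inner))), 0.001)
})

test_that("marginal_effect_at is consistent, symmetric, and guards extrapolation", {
  d <- make_dataset(cfg_small())
  vc <- fit_varying_coefficient(d, "exposure_ppb", covariates = "sex", df = 3)
  cc <- mean(vc$cbar_range)
  me <- marginal_effect_at(vc, cc)
  expect_equal(me$conf.high - me$estimate, me$estimate - me$conf.low,
               tolerance = 1e-10)
  # equals the numerical derivative of the integrated ERF times 10
  erf <- integrate_erf(vc, tmrel_ppb = cc, step = 0.01)
  d1 <- approx(erf$grid, erf$mean_g, cc + 0.01)$y
  d0 <- approx(erf$grid, erf$mean_g, cc - 0.01)$y
  expect_equal((d1 - d0) / 0.02 * 10, me$estimate, tolerance = 1e-3)
  expect_error(marginal_effect_at(vc, vc$cbar_range[2] + 5),
               "extrapolat", class = "ozonebw_value_error")
  expect_silent(marginal_effect_at(vc, vc$cbar_range[2] + 5,
                                   allow_extrapolation = TRUE))
})

test_that("zero covariance collapses the Monte Carlo band to the mean curve", {
  cur <- fake_curve(const_basis, coef = c(vc_b1 = -20),
                    vcov = matrix(0, 1, 1), cbar_range = c(25, 60))
  erf <- erf_uncertainty(cur, tmrel_ppb = 30, n_draws = 250, seed = 2)
  expect_equal(erf$lo, erf$mean_g, tolerance = 1e-10)
  expect_equal(erf$hi, erf$mean_g, tolerance = 1e-10)
  expect_true(all(apply(erf$draws, 2, sd) < 1e-12))
})

test_that("Monte Carlo bands are seed-reproducible and mean-consistent", {
  d <- make_dataset(cfg_small())
  vc <- fit_varying_coefficient(d, "exposure_ppb", covariates = "sex", df = 2)
  e1 <- erf_uncertainty(vc, n_draws = 400, seed = 9)
  e2 <- erf_uncertainty(vc, n_draws = 400, seed = 9)
  expect_identical(e1$lo, e2$lo)
  expect_identical(e1$draws, e2$draws)
  expect_true(all(e1$lo <= e1$mean_g + 1e-9 & e1$mean_g <= e1$hi + 1e-9))
  # pointwise mean of draws approaches the mean curve
  mc_se <- apply(e1$draws, 2, sd) / sqrt(nrow(e1$draws))
  gap <- abs(colMeans(e1$draws) - e1$mean_g)
  expect_true(mean(gap <= 4 * mc_se + 1e-9) > 0.95)
})

test_that("scalar-coefficient percentile CI matches the analytic normal interval", {
  sigma <- 4
  cur <- fake_curve(const_basis, coef = c(vc_b1 = -20),
                    vcov = matrix(sigma^2, 1, 1), cbar_range = c(25, 60))
  tm <- 30
  erf <- erf_uncertainty(cur, tmrel_ppb = tm, n_draws = 10000, seed = 3)
  at <- 55
  i <- which(abs(erf$grid - at) < 1e-9)
  span <- (at - tm) / 10
  an_lo <- (-20 - 1.96 * sigma) * span
  an_hi <- (-20 + 1.96 * sigma) * span
  expect_equal(erf$lo[i], an_lo, tolerance = 0.05 * abs(an_lo - an_hi))
  expect_equal(erf$hi[i], an_hi, tolerance = 0.05 * abs(an_lo - an_hi))
})

test_that("changing the TMREL shifts the ERF by a constant", {
  d <- make_dataset(cfg_small())
  vc <- fit_varying_coefficient(d, "exposure_ppb", covariates = "sex", df = 3)
  t1 <- tmrel_preset("aqg"); t2 <- tmrel_preset("it2")
  grid <- sort(unique(c(seq(30, 70, by = 0.25), t1, t2)))
  e1 <- integrate_erf(vc, tmrel_ppb = t1, grid = grid)
  e2 <- integrate_erf(vc, tmrel_ppb = t2, grid = grid)
  shift <- e1$mean_g - e2$mean_g
  expect_lt(diff(range(shift)), 1e-10)
  expect_equal(shift[1], approx(grid, e1$mean_g, t2)$y, tolerance = 1e-10)
})

test_that("degenerate integration grids are rejected", {
  cur <- fake_curve(const_basis, c(vc_b1 = -20), matrix(0, 1, 1), c(25, 60))
  expect_error(integrate_erf(cur, tmrel_ppb = 30, grid = c(30, 29, 31)),
               class = "ozonebw_value_error")
  expect_error(integrate_erf(cur, tmrel_ppb = 30, grid = c(25, 40, 55)),
               "TMREL", class = "ozonebw_value_error")
  expect_error(erf_uncertainty(cur, n_draws = 50),
               class = "ozonebw_value_error")
})

test_that("exact ERFs reproduce the generative truth", {
  spec <- erf_sublinear()
  tm <- tmrel_preset("aqg")
  ee <- erf_exact(spec, tmrel_ppb = tm, grid = seq(25, 75, 0.25), n_draws = 200)
  expect_equal(approx(ee$grid, ee$mean_g, 60)$y,
               true_erf(spec, 60) - true_erf(spec, tm), tolerance = 1e-10)
  expect_equal(ee$lo, ee$mean_g)
})
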