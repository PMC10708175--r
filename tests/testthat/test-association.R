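test_that("noise-free linear world is recovered exactly", {
  d <- make_dataset(cfg_exact())
  fit <- fit_birthweight_fe(d, "exposure_ppb")
  expect_equal(fit$beta_g_per_10ppb, -20, tolerance = 1e-8)
  expect_equal(fit$ci95, c(fit$beta_g_per_10ppb - 1.96 * fit$se,
                           fit$beta_g_per_10ppb + 1.96 * fit$se))
  expect_gte(fit$n_strata, 2)
})

test_that("equal weights reproduce the unweighted fit", {
  d <- make_dataset(cfg_small())
  d1 <- d |> mutate(sampling_weight = 1)
  d2 <- d |> mutate(sampling_weight = 2.5)
  f1 <- fit_birthweight_fe(d1, "exposure_ppb", covariates = "sex")
  f2 <- fit_birthweight_fe(d2, "exposure_ppb", covariates = "sex")
  expect_equal(f1$beta_g_per_10ppb, f2$beta_g_per_10ppb, tolerance = 1e-10)
  # and equals a plain dummy-variable OLS
  ols <- lm(birthweight_g ~ I(exposure_ppb / 10) + sex + factor(stratum_id),
            data = d1)
  expect_equal(f1$beta_g_per_10ppb,
               unname(coef(ols)[["I(exposure_ppb/10)"]]), tolerance = 1e-8)
})

test_that("demeaning and dummy-absorption paths agree", {
  # small instance per the Frisch-Waugh-Lovell identity
  cfg <- sim_config(n_countries = 1, strata_per_country = 3,
                    births_per_stratum = 10, n_months = 36,
                    noise_sd_g = 80, seed = 23)
  d <- make_dataset(cfg)
  f_dem <- fit_birthweight_fe(d, "exposure_ppb", covariates = "sex")
  f_dum <- fit_birthweight_fe(d, "exposure_ppb", covariates = "sex",
                              method = "dummies")
  expect_equal(f_dem$beta_g_per_10ppb, f_dum$beta_g_per_10ppb,
               tolerance = 1e-8)
  # and on a larger heterogeneous instance with splines and seasonality
  d2 <- make_dataset(cfg_small())
  f2a <- fit_birthweight_fe(d2, "exposure_ppb",
                            covariates = c("sex", "season", "maternal_age_y"))
  f2b <- fit_birthweight_fe(d2, "exposure_ppb",
                            covariates = c("sex", "season", "maternal_age_y"),
                            method = "dummies")
  expect_equal(f2a$coef, f2b$coef, tolerance = 1e-8)
})

test_that("stratum-constant confounding is absorbed by the fixed effects", {
  d <- make_dataset(cfg_exact(confounding_g_per_ppb = 30))
  fit0 <- fit_birthweight_fe(d, "exposure_ppb")
  # adding any stratum-constant shift leaves the estimate unchanged
  shift <- setNames(rnorm(dplyr::n_distinct(d$stratum_id), 0, 500),
                    unique(d$stratum_id))
  d2 <- d |> mutate(birthweight_g = birthweight_g + shift[stratum_id])
  fit2 <- fit_birthweight_fe(d2, "exposure_ppb")
  expect_equal(fit0$beta_g_per_10ppb, fit2$beta_g_per_10ppb, tolerance = 1e-8)
  expect_equal(fit0$beta_g_per_10ppb, -20, tolerance = 1e-8)
})

test_that("confidence interval coverage is near nominal under the linear model", {
  hits <- 0L
  reps <- 30L
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_countries = 4, strata_per_country = 25,
                      births_per_stratum = 20, n_months = 36,
                      true_erf = erf_linear(-2), noise_sd_g = 150,
                      within_stratum_sd_ppb = 10,
                      confounding_g_per_ppb = 20, seed = 100 + r)
    fit <- fit_birthweight_fe(make_dataset(cfg), "exposure_ppb",
                              covariates = "sex")
    if (fit$ci95[1] <= -20 && -20 <= fit$ci95[2]) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.80)   # 3-sigma band around 95% at 30 reps
})

test_that("the covariate-block ladder returns one estimate per rung", {
  d <- make_dataset(cfg_small())
  rungs <- names(covariate_blocks())
  betas <- vapply(seq_along(rungs), function(k) {
    fit_birthweight_fe(d, "exposure_ppb",
                       blocks = rungs[seq_len(k)])$beta_g_per_10ppb
  }, numeric(1))
  expect_length(betas, 6)
  expect_true(all(is.finite(betas)))
})

test_that("singleton strata are dropped with a warning and collinear inputs error", {
  d <- make_dataset(cfg_small())
  d1 <- bind_rows(d, d[1, ] |> mutate(stratum_id = "LONE", record_id = "RX"))
  expect_warning(fit_birthweight_fe(d1, "exposure_ppb"), "single record")
  d$dup <- d$exposure_ppb * 2
  expect_error(fit_birthweight_fe(d, "exposure_ppb", covariates = "dup"),
               "collinear", class = "ozonebw_value_error")
})

test_that("LBW logit: threshold boundary, direction, and null coverage", {
  # a record at exactly 2500 g is not LBW
  cfg <- cfg_small(seed = 41)
  d <- make_dataset(cfg)
  d$birthweight_g <- ifelse(seq_len(nrow(d)) %% 2 == 0, 2500, 2400)
  suppressMessages(fit <- fit_lbw_logit(d, "exposure_ppb"))
  expect_equal(fit$prevalence,
               weighted.mean(d$birthweight_g == 2400, d$sampling_weight),
               tolerance = 1e-10)
  # strongly negative birthweight effect raises the odds of LBW
  cfgn <- sim_config(n_countries = 3, strata_per_country = 20,
                     births_per_stratum = 30, n_months = 36,
                     true_erf = erf_linear(-40), noise_sd_g = 400,
                     within_stratum_sd_ppb = 10, baseline_bw_g = 3800,
                     seed = 43)
  dn <- make_dataset(cfgn)
  suppressMessages(fitn <- fit_lbw_logit(dn, "exposure_ppb"))
  expect_gt(fitn$or_per_10ppb, 1)
})

test_that("LBW logit null CIs cover OR = 1 in most replicates", {
  hits <- 0L
  reps <- 20L
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_countries = 3, strata_per_country = 25,
                      births_per_stratum = 50, n_months = 36,
                      true_erf = erf_linear(0), noise_sd_g = 500,
                      within_stratum_sd_ppb = 10, baseline_bw_g = 3000,
                      seed = 300 + r)
    d <- make_dataset(cfg)
    suppressMessages(fit <- fit_lbw_logit(d, "exposure_ppb"))
    if (fit$ci95[1] <= 1 && 1 <= fit$ci95[2]) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.90)
})

test_that("interaction analysis recovers level-specific slopes exactly at zero noise", {
  cfg <- cfg_exact(seed = 51)
  d <- make_dataset(cfg)
  # overwrite outcome with sex-specific slopes -1 and -3 g/ppb
  slope <- ifelse(d$sex == "male", -1, -3)
  d$birthweight_g <- 3000 + slope * d$exposure_ppb + d$stratum_effect_g
  ia <- interaction_analysis(d, "exposure_ppb", "sex")
  expect_equal(sort(ia$effects$estimate), c(-30, -10), tolerance = 1e-8)
  expect_lt(ia$wald_p, 1e-6)
})

test_that("single-level modifiers yield an explicit not-estimable result", {
  d <- make_dataset(cfg_small())
  d$onelevel <- factor("all")
  expect_message(ia <- interaction_analysis(d, "exposure_ppb", "onelevel"),
                 "not estimable")
  expect_true(is.na(ia$wald_p))
  main <- fit_birthweight_fe(d, "exposure_ppb")
  expect_equal(ia$effects$estimate, main$beta_g_per_10ppb, tolerance = 1e-8)
})

test_that("Wald p-values are roughly uniform when the modifier is inert", {
  ps <- vapply(1:60, function(r) {
    cfg <- sim_config(n_countries = 2, strata_per_country = 15,
                      births_per_stratum = 10, n_months = 36,
                      true_erf = erf_linear(-2), noise_sd_g = 120,
                      within_stratum_sd_ppb = 10, seed = 500 + r)
    d <- make_dataset(cfg)
    interaction_analysis(d, "exposure_ppb", "sex")$wald_p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
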