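toy_world <- function() {
  conc <- tibble::tibble(cell_id = c("a", "b", "c"), country_id = "X",
                         year = 2019, conc_ppb = c(40, 50, 60))
  pop <- tibble::tibble(cell_id = rep(c("a", "b", "c"), 2), year = 2019,
                        sex = rep(c("male", "female"), each = 3),
                        count = c(1, 1, 0.5, 0, 1, 0.5))
  list(conc = conc, pop = pop)
}

test_that("population-weighted exposure matches the printed equation by hand", {
  w <- toy_world()
  out <- population_weighted_exposure(w$conc, w$pop)
  # totals (1, 2, 1): E = (40*1 + 50*2 + 60*1) / 4 = 50
  expect_equal(out$E_ppb, 50)
  expect_equal(out$newborns, 4)
})

test_that("uniform weights give the plain mean; point mass gives the cell value", {
  w <- toy_world()
  pop_u <- w$pop |> mutate(count = 3)
  expect_equal(population_weighted_exposure(w$conc, pop_u)$E_ppb, 50)
  pop_pm <- w$pop |> mutate(count = ifelse(cell_id == "c", 1, 0) * (sex == "male"))
  expect_equal(population_weighted_exposure(w$conc, pop_pm)$E_ppb, 60)
})

test_that("exposure equation reproduces brute-force double summation", {
  set.seed(99)
  for (r in 1:10) {
    n_cell <- sample(3:12, 1)
    conc <- tibble::tibble(
      cell_id = sprintf("s%02d", 1:n_cell),
      country_id = sample(c("A", "B"), n_cell, TRUE),
      year = 2010, conc_ppb = runif(n_cell, 20, 90))
    pop <- tidyr::expand_grid(cell_id = conc$cell_id, year = 2010,
                              sex = c("male", "female")) |>
      mutate(count = runif(dplyr::n(), 0.1, 30))
    out <- population_weighted_exposure(conc, pop)
    for (ct in unique(conc$country_id)) {
      num <- 0; den <- 0
      for (s in conc$cell_id[conc$country_id == ct]) {
        ptot <- sum(pop$count[pop$cell_id == s])
        num <- num + conc$conc_ppb[conc$cell_id == s] * ptot
        den <- den + ptot
      }
      expect_equal(out$E_ppb[out$country_id == ct], num / den,
                   tolerance = 1e-10)
      expect_true(out$E_ppb[out$country_id == ct] >=
                    min(conc$conc_ppb[conc$country_id == ct]) &&
                  out$E_ppb[out$country_id == ct] <=
                    max(conc$conc_ppb[conc$country_id == ct]))
    }
  }
})

test_that("grid mismatch and zero population are rejected before arithmetic", {
  w <- toy_world()
  expect_error(population_weighted_exposure(w$conc, w$pop |> filter(cell_id != "a")),
               "misaligned", class = "ozonebw_value_error")
  expect_error(population_weighted_exposure(w$conc, w$pop |> mutate(count = 0)),
               "zero total population", class = "ozonebw_value_error")
  rep_align <- check_grid_alignment(w$conc, w$pop |> mutate(year = 1999))
  expect_false(all(rep_align$ok))
})

test_that("attributable reduction follows the ERF with a floor at the TMREL", {
  erf <- erf_exact(erf_linear(-2), tmrel_ppb = 30,
                   grid = seq(10, 80, 0.25), n_draws = 200)
  expo <- tibble::tibble(country_id = c("A", "B", "C"), year = 2019,
                         E_ppb = c(30, 50, 20), newborns = c(10, 20, 5))
  out <- attributable_reduction(expo, erf)
  expect_equal(out$abs_g, c(0, 40, 0))       # E = TMREL -> 0; linear -> 40 g
  expect_equal(out$abs_lo, out$abs_g)        # exact draws: zero-width CI
  # monotone nondecreasing in E for a monotone-decreasing ERF
  sweep <- tibble::tibble(country_id = sprintf("c%03d", 1:60), year = 2019,
                          E_ppb = seq(15, 75, length.out = 60), newborns = 1)
  bs <- attributable_reduction(sweep, erf)
  expect_true(all(diff(bs$abs_g) >= -1e-12))
})

test_that("evaluation beyond the ERF grid clamps by default", {
  erf <- erf_exact(erf_linear(-2), tmrel_ppb = 30, grid = seq(20, 60, 0.5))
  expo <- tibble::tibble(country_id = "A", year = 2019, E_ppb = 70,
                         newborns = 1)
  expect_message(out <- attributable_reduction(expo, erf), "clamped")
  expect_equal(out$abs_g, 60)   # boundary value at 60 ppb
  out_lin <- attributable_reduction(expo, erf, extrapolation = "linear")
  expect_equal(out_lin$abs_g, 80)
})

test_that("relative reduction is the percentage of baseline, with carry-forward", {
  burden <- tibble::tibble(country_id = "A", year = c(2017, 2019),
                           E_ppb = 50, newborns = 10, abs_g = c(43.8, 43.8),
                           abs_lo = NA_real_, abs_hi = NA_real_)
  base <- tibble::tibble(country_id = "A", year = 2017, baseline_bw_g = 3151)
  expect_message(out <- relative_reduction(burden, base), "carried forward")
  expect_equal(out$rel_pct, rep(100 * 43.8 / 3151, 2), tolerance = 1e-12)
  expect_equal(round(out$rel_pct[1], 2), 1.39)
  # zero burden -> zero percent; doubling the baseline halves the percentage
  burden0 <- burden |> mutate(abs_g = 0, year = 2017)
  expect_equal(relative_reduction(burden0, base)$rel_pct, c(0, 0))
  base2 <- base |> mutate(baseline_bw_g = 2 * 3151)
  expect_message(out2 <- relative_reduction(burden, base2))
  expect_equal(out2$rel_pct, out$rel_pct / 2)
})

test_that("newborn-weighted aggregation matches hand computation and is associative", {
  burden <- tibble::tibble(country_id = c("A", "B"), year = 2019,
                           E_ppb = 50, newborns = c(1, 3),
                           abs_g = c(10, 40), region = c("r1", "r2"))
  agg <- aggregate_burden(burden)
  expect_equal(agg$estimate, (10 * 1 + 40 * 3) / 4)  # 32.5 g
  one <- aggregate_burden(burden |> filter(country_id == "A"))
  expect_equal(one$estimate, 10)
  eq <- aggregate_burden(burden |> mutate(newborns = 7))
  expect_equal(eq$estimate, 25)
  # overall equals the newborn-weighted mean of regional aggregates
  burden2 <- tibble::tibble(country_id = sprintf("c%d", 1:6), year = 2019,
                            E_ppb = 50, newborns = c(2, 5, 1, 8, 3, 4),
                            abs_g = c(12, 33, 8, 50, 21, 5),
                            region = rep(c("r1", "r2", "r3"), each = 2))
  by_reg <- aggregate_burden(burden2, by = "region")
  overall <- aggregate_burden(burden2)
  expect_equal(overall$estimate,
               weighted.mean(by_reg$estimate, by_reg$newborns),
               tolerance = 1e-12)
  expect_error(aggregate_burden(burden2[0, ]), class = "ozonebw_value_error")
})

test_that("Monte Carlo CIs behave like percentiles", {
  expect_equal(monte_carlo_ci(rep(5, 300)), tibble::tibble(lo = 5, hi = 5))
  set.seed(11)
  z <- matrix(rnorm(2 * 10000, mean = c(10, -3), sd = c(2, 0.5)), nrow = 2)
  ci <- monte_carlo_ci(z)
  expect_equal(ci$lo[1], 10 - 1.96 * 2, tolerance = 0.05 * 2 * 3.92)
  expect_equal(ci$hi[2], -3 + 1.96 * 0.5, tolerance = 0.05 * 0.5 * 3.92)
})

test_that("the burden pipeline with the true ERF equals the closed form", {
  cfg <- cfg_small()
  fld <- simulate_concentration_field(cfg)
  ann <- annual_peak_season(fld, epoch_year = cfg$epoch_year)
  pop <- simulate_population_grid(cfg, fld)
  expo <- population_weighted_exposure(ann, pop)
  tm <- cfg$tmrel_ppb
  erf <- erf_exact(cfg$true_erf, tmrel_ppb = tm,
                   grid = seq(floor(min(expo$E_ppb, tm)) - 1,
                              ceiling(max(expo$E_ppb)) + 1, 0.001))
  out <- attributable_reduction(expo, erf)
  f <- function(cc) true_erf(cfg$true_erf, cc)
  closed <- ifelse(expo$E_ppb <= tm, 0, -(f(expo$E_ppb) - f(tm)))
  expect_equal(out$abs_g, closed, tolerance = 1e-5)
})
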