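# ozonebw

Maternal ozone exposure and birthweight: survey-weighted stratified
fixed-effects estimation, a nonlinear exposure-response function (ERF) from
a varying-coefficient model, and country-level attributable-burden
assessment with Monte Carlo uncertainty.

## Who this is for

Environmental epidemiologists and health-impact-assessment analysts working
with stratified household-survey birth records (DHS-style microdata:
sampling strata, per-record design weights, birth histories) and gridded
monthly ozone products. The real microdata of this kind are
access-controlled, so the package also ships a synthetic-data generator
that reproduces the relevant statistical structure — stratified two-stage
sampling, heterogeneous stratum-mean exposures, seasonal concentration
cycles, stratum-level confounding — with a **known ground-truth ERF**, so
the entire chain is testable end to end.

## The methods

**Exposure metrics.** From monthly mean MDA8 ozone concentrations (ppb):
peak-season exposure (the WHO long-term metric — the maximum 6-month
running average over the 12 months preceding birth), the 9-month
gestational mean, and for annual products the birth-year peak-season value
and the gestation-weighted mean, `min(m,9)/9 · C_y + (1 − min(m,9)/9) ·
C_{y−1}` for birth month `m`. Reference levels are converted from µg/m³
(AQG 60, IT2 70, IT1 100) at 1.96 µg/m³ per ppb.

**Linear association.** Weighted least squares of birthweight (g) on
exposure per 10 ppb with sampling-stratum fixed effects (absorbed by
weighted within-stratum demeaning, with an explicit-dummy cross-check
path), month-of-birth × latitude-zone seasonality, 3-df natural cubic
splines for continuous confounders, and stratum-clustered robust standard
errors. A weighted stratified logit for low birthweight (< 2500 g) and a
Wald-test interaction analysis accompany it.

**Nonlinear ERF.** A varying-coefficient model estimates the marginal
effect β(c̄) of within-stratum exposure variation as a spline function of
the stratum-mean concentration c̄ — the first derivative of the ERF. The
ERF is then

    ERF(c) = ∫ from TMREL to c of β(u)/10 du,

integrated by cumulative trapezoid from a theoretical minimum risk exposure
level (default: WHO AQG). Uncertainty is propagated by drawing coefficient
vectors from their multivariate normal, integrating each draw, and taking
pointwise percentile bands.

**Attributable burden.** Per country `i` and year `y`, the
newborn-population-weighted exposure

    E_iy = Σ_s C_sy · Σ_k P_syk / Σ_s Σ_k P_syk

is evaluated through the ERF: the attributable reduction is −ERF(E_iy)
above the TMREL and zero below (floored). Country burdens are aggregated
with newborn-count weights; all intervals reuse the ERF draws (the only
propagated uncertainty source).

## Worked example

```r
library(ozonebw)
library(dplyr)

cfg <- sim_config(n_countries = 8, strata_per_country = 60,
                  births_per_stratum = 30, n_months = 36,
                  noise_sd_g = 120, within_stratum_sd_ppb = 10,
                  stratum_mean_range_ppb = c(30, 70), seed = 42)
field  <- simulate_concentration_field(cfg)
births <- simulate_births(cfg, field)
dat <- births |>
  left_join(assign_exposures(births, field) |> select(record_id, value_ppb),
            by = "record_id") |>
  rename(exposure_ppb = value_ppb)

fit <- fit_birthweight_fe(dat, "exposure_ppb", covariates = c("sex", "season"))
fit
#> <o3_fe_fit> weighted stratified fixed-effects model
#>   n = 14400 records in 480 strata (demean path, cluster SEs)
#>   birthweight change per 10 ppb: -26.6 g (95% CI -33.8 to -19.3)
```

A 10-ppb increment in peak-season ozone is associated with a 26.6 g lower
birthweight in this synthetic world (the generative ERF is sublinear with a
marginal effect near −20 g/10 ppb mid-range; the linear coefficient is a
design-weighted average of marginal effects). The nonlinear curve and its
integral:

```r
curve <- fit_varying_coefficient(dat, "exposure_ppb",
                                 covariates = c("sex", "season"), df = 3)
erf <- erf_uncertainty(curve, n_draws = 400, seed = 42)
marginal_effect_at(curve, 50)
#>   c_ppb estimate std.error conf.low conf.high
#> 1    50    -25.1      6.24    -37.3     -12.8
autoplot(erf)   # integrated ERF with its Monte Carlo band
```

Country-level burden from the annual peak-season field and a newborn
population grid:

```r
ann  <- annual_peak_season(field, epoch_year = cfg$epoch_year)
pop  <- simulate_population_grid(cfg, field)
expo <- population_weighted_exposure(ann, pop) |> filter(year == 2003)
burden <- attributable_reduction(expo, erf) |>
  relative_reduction(expo |> distinct(country_id, year) |>
                       mutate(baseline_bw_g = 3061))
burden |> select(country_id, E_ppb, abs_g, abs_lo, abs_hi, rel_pct) |> head(4)
#>   country_id E_ppb abs_g abs_lo abs_hi rel_pct
#> 1 C01         42.3  39.3   28.1   51.8    1.28
#> 2 C02         76.7 118.    84.4  152.     3.86
#> 3 C03         67.2  98.4   69.2  131.     3.21
#> 4 C04         69.5 103.    72.6  137.     3.37
aggregate_burden(burden)
#>   group    year estimate    lo    hi newborns
#> 1 overall  2003     78.3  58.4  100.    37978
```

The overall newborn-weighted attributable reduction is 78.3 g (95% CI 58.4
to 100.4); the ground-truth burden of this world, computable because the
generative ERF is known, is 60.6 g — inside the interval.

`run_pipeline()` chains all stages (optionally writing every artifact plus
an MD5 manifest), and `validate_births()` applies the record-level
eligibility filters (stillbirth flags, missing birthweight, non-singleton)
with a per-rule report.

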