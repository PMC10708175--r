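---
title: "Methods: peak-season ozone exposure, birthweight, and attributable burden"
author: "ozonebw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak-season ozone exposure, birthweight, and attributable burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
set.seed(1)
```

```{r load, message = FALSE}
library(ozonebw)
library(dplyr)
```

# The problem

Ambient ozone is a secondary pollutant whose long-term burden on perinatal
health is poorly quantified in low- and middle-income settings, where most
low-birthweight newborns are born. `ozonebw` implements an analysis chain
for estimating the association between maternal ozone exposure and
birthweight from stratified household-survey microdata (DHS-style birth
histories with sampling weights), deriving a nonlinear exposure-response
function (ERF), and translating it into country-level attributable
birthweight reductions.

Because the survey microdata that motivate this design are
access-controlled, the package ships a synthetic-data generator that
emulates the relevant statistical structure with a *known* ground-truth
ERF. Every stage is validated against that truth; the package makes no
claim about real-world effect sizes.

# Exposure metrics

The raw exposure material is a gridded field of monthly mean MDA8 ozone
concentrations (maximum daily 8-hour average, in ppb). Records are assigned
the concentration series of the grid cell containing their sampling
stratum; there is no interpolation, mirroring grid-lookup exposure
assignment and keeping misclassification behaviour analyzable. Four metrics
are provided:

* **Peak-season** (`peak_season()`, `assign_exposures(metric =
  "peak_season")`): the maximum 6-month running average of monthly means
  within the 12 months preceding birth (7 candidate windows, no
  wrap-around). This is the WHO long-term ozone metric.
* **Gestational** (`gestational_mean()`): the arithmetic mean of the 9
  months preceding birth, the dominant gestational duration when
  gestational age is unrecorded.
* **Yearly peak-season** (`yearly_peak_season()`): for annual-resolution
  products, the birth-year peak-season concentration of the record's cell.
* **Gestation-weighted** (`gestation_weighted()`): for annual products, the
  birth-year and prior-year concentrations weighted `min(m, 9)/9` and
  `1 - min(m, 9)/9` for birth month `m` — a May birth weights the birth
  year 5/9 and the prior year 4/9; births in month 9 or later fall wholly
  in the birth year.

Two conventions deserve emphasis because they are easy to get silently
wrong. First, pre-birth windows **exclude the birth month** (months
−12…−1); the month of birth is only partially lived through, and "preceding
birth" is the natural reading. `assign_exposures(include_birth_month =
TRUE)` switches to the alternative convention. Second, reference levels are
quoted in µg/m³ (AQG 60, IT2 70, IT1 100) but all analysis is in ppb;
`ugm3_to_ppb()` converts with the standard-conditions factor 1.96 µg/m³ per
ppb (25 °C, 1013 hPa), so the AQG is 30.61 ppb.

```{r exposure-example}
peak_season(c(30, 35, 40, 45, 50, 55, 60, 55, 50, 45, 40, 35))
gestation_weighted(c(`2009` = 45, `2010` = 54), birth_month = 5,
                   birth_year = 2010)
tmrel_preset("aqg")
```

Temperature and fine-particle confounders on monthly grids are prepared
with the same windowing functions.

# The linear association model

The core estimator (`fit_birthweight_fe()`) is a weighted least-squares
regression of birthweight (g) on exposure (per 10 ppb), with:

* **stratum fixed effects** — the survey's sampling strata (region ×
  urban/rural) absorb all stratum-constant confounding, observed or not;
* **sampling weights** used as-is (relative weights; the generator
  normalises them to mean 1 within stratum, and no further renormalisation
  is applied);
* **cluster-robust standard errors** at the stratum level. The variance
  estimator is a design choice: clustering matches the survey design and is
  the conservative default (`se_type` also offers `"HC1"` and `"iid"`);
* **covariates** organised in six adjustment blocks
  (`covariate_blocks()`): environmental, birth, pregnancy, reproductive,
  maternal and household. Seasonality enters as the categorical interaction
  of birth month (1–12) with latitude zone (south < 0°, tropical 0–23.5°,
  north > 23.5°). Temperature, maternal age, inter-pregnancy interval and
  household-head age enter as natural cubic splines with 3 degrees of
  freedom (boundary knots at the 1st/99th percentiles; the basis family is
  a design choice, as is entering fine particles linearly — a spline is one
  flag away via the covariate machinery).

Fixed effects are absorbed by weighted within-stratum demeaning
(Frisch–Waugh–Lovell); an explicit dummy-variable path (`method =
"dummies"`) is retained and tested to agree to numerical precision.
Singleton strata drop out with a warning. Columns of multi-level factor
expansions that are collinear with the fixed effects (e.g. the zone margin
of month × zone) are removed automatically; a genuinely collinear user
covariate raises an error naming it.

The low-birthweight companion (`fit_lbw_logit()`) replaces the outcome with
the indicator birthweight < 2500 g (exactly 2500 g is *not* low
birthweight) in a weighted logit with explicit stratum dummies. Strata
without outcome variation carry no information and are excluded with a
message. The usual incidental-parameter caveat applies to dummy-variable
logit with small strata; a conditional-likelihood variant was deliberately
not used so that the linear and logit specifications stay parallel.

`interaction_analysis()` fits a single model with level-specific exposure
slopes plus the modifier main effect, and tests slope homogeneity with a
joint Wald test on the interaction contrasts (chi-squared with
levels − 1 df). Levels observed in fewer than two strata are excluded.

# The nonlinear exposure-response function

The key identification idea: within-stratum exposure variation is plausibly
exogenous after fixed effects, and its marginal association with
birthweight may differ across strata with different long-run exposure
levels. `fit_varying_coefficient()` therefore replaces the single exposure
term with

\[(x_{is} - \bar c_s)/10 \times B(\bar c_s)\gamma,\]

where \(\bar c_s\) is the sampling-weighted stratum mean exposure and
\(B(\cdot)\) is a natural cubic spline basis (intercept + `df − 1` spline
columns, knots at stratum-mean quantiles, boundary knots at the observed
range). The fitted \(\beta(\bar c) = B(\bar c)\gamma\) is the marginal
birthweight change per 10 ppb as a function of the stratum-mean
concentration — the first derivative of the ERF. With `df = 1` the model
collapses exactly to the linear fit, a nesting identity that is tested.

Numerical and design choices:

* deviations are taken about the *weighted* stratum mean, which makes the
  interaction columns exactly orthogonal to the fixed effects;
* default `df = 3`; the basis is reported in the output metadata rather
  than asserted as canonical;
* identification guards: at least 10 strata and a stratum-mean range of at
  least 5 ppb, otherwise an error;
* the coefficient covariance for uncertainty propagation is the same
  cluster-robust estimator as the point fit.

`integrate_erf()` integrates \(\beta(u)/10\) from a theoretical minimum
risk exposure level (TMREL — default the AQG) by cumulative trapezoid on a
0.25-ppb grid containing the TMREL exactly:
\(\mathrm{ERF}(c) = \int_{\mathrm{TMREL}}^{c} \beta(u)/10\,du\), so
\(\mathrm{ERF}(\mathrm{TMREL}) = 0\), negative values are reductions, and
concentrations below the TMREL yield the signed (positive) integral.
Switching the TMREL shifts the curve by a constant and cannot change its
curvature. `erf_uncertainty()` draws coefficient vectors from a
multivariate normal (mean = estimate, covariance = cluster-robust vcov),
integrates **each draw** (integrate-then-summarise, preserving dependence
across grid points), and forms pointwise 2.5/97.5 percentile bands.
Per-draw curves are retained so downstream burden intervals reuse the same
uncertainty, which is the only uncertainty source propagated (exposure
uncertainty is deliberately excluded).

```{r erf-demo, message = FALSE}
cfg <- sim_config(n_countries = 6, strata_per_country = 30,
                  births_per_stratum = 25, n_months = 36,
                  noise_sd_g = 150, within_stratum_sd_ppb = 10,
                  stratum_mean_range_ppb = c(30, 70), seed = 42)
field <- simulate_concentration_field(cfg)
births <- simulate_births(cfg, field)
dat <- births |>
  left_join(assign_exposures(births, field) |> select(record_id, value_ppb),
            by = "record_id") |>
  rename(exposure_ppb = value_ppb)
curve <- fit_varying_coefficient(dat, "exposure_ppb",
                                 covariates = c("sex", "season"), df = 3)
erf <- erf_uncertainty(curve, n_draws = 400, seed = 42)
autoplot(erf)
```

# Attributable burden

For each country `i` and year `y`, `population_weighted_exposure()`
computes the newborn-weighted mean annual peak-season concentration

\[E_{i,y} = \frac{\sum_{s \in i} C_{s,y} \sum_k P_{s,y,k}}
                 {\sum_{s \in i} \sum_k P_{s,y,k}},\]

with `s` grid cells, `k` sex, `C` the annual peak-season field
(`annual_peak_season()` reduces monthly fields per calendar year) and `P`
the gridded population of 0-to-1-year-olds standing in for newborn counts.
`attributable_reduction()` evaluates the ERF at \(E_{i,y}\): the
attributable absolute reduction is \(-\mathrm{ERF}(E_{i,y})\) above the
TMREL and zero at or below it. Burdens are floored at zero — attributable
risk is not credited below the reference level, the standard
comparative-risk convention. Evaluation above the fitted support clamps to
the boundary value by default (the marginal effect is estimated to be
stable at high concentrations; `extrapolation = "linear"` is available).
The printed equation implies evaluation at the country-mean exposure, which
is what is implemented; evaluating cell-by-cell before averaging is a
different estimand and deliberately not the default.

`relative_reduction()` divides by a country-year baseline mean birthweight
(carry-forward of the most recent available year when a baseline year is
missing), and `aggregate_burden()` forms newborn-weighted means overall or
by group, per Monte Carlo draw, summarised to percentile intervals.
Aggregation is associative: the overall burden equals the newborn-weighted
mean of group burdens.

# The synthetic-data generator

`sim_config()` + `simulate_concentration_field()` + `simulate_births()` +
`simulate_population_grid()` emulate the statistical structure the
estimators rely on:

* stratified two-stage sampling: strata nested in countries, each tied to a
  grid cell, 25 births per stratum by default (survey clusters enrol 25–30
  households); Gamma(4) sampling weights, mean 1 within stratum — positive
  and right-skewed like design weights;
* heterogeneous stratum means: country means uniform over a configurable
  range (default 35–70 ppb, matching a mean exposure near 53 ± 10 ppb);
  cell offsets; a sinusoidal seasonal cycle; monthly white noise, which is
  what generates within-stratum exposure variation across birth dates;
* a known ground-truth ERF (`erf_linear()`, `erf_piecewise()`,
  `erf_sublinear()`; the default is sublinear-decreasing,
  \(f(c) = -29\sqrt{c}\), whose marginal effect near 53 ppb is about
  −2 g/ppb);
* optional stratum-level confounding: `confounding_g_per_ppb` links the
  stratum intercept to its long-run mean exposure — exactly the
  confounding that fixed effects must absorb, making the estimator tests
  meaningful;
* default outcome scale: baseline 3061 g, residual noise 450 g.

Ground truth (`true_exposure_ppb`, `stratum_effect_g`, the ERF spec) is
exported with every dataset so recovery tests never re-derive it through
the code paths being tested. Every generator is byte-reproducible for a
fixed seed.

What the generator does **not** emulate: real survey file formats, GPS
displacement, response-rate structure, residential mobility, reporting
error in birthweight (heaping at round values), gestational-age truncation,
or spatially correlated exposure error. Passing tests therefore demonstrate
the statistical machinery is correct, not that real-data estimates are
unbiased.

Missing covariates are handled by a single weighted hot-deck draw from
observed values of the same variable within country
(`inject_missingness()` / `impute_hot_deck()`); full chained-equation
imputation is out of scope.

# Validation-study design choices

The test suite fixes a handful of study designs once:

* **Recovery studies** (constant-slope and sublinear-truth) use n = 50,000
  births with within-stratum exposure noise of 12 ppb and residual noise of
  2–25 g. The recovery tolerances (0.3–0.5 g per 10 ppb; 15% of the ERF
  range) target *systematic* error, so residual noise is set low enough
  that sampling error is negligible against them; at zero noise the
  estimator is exact, which is tested separately.
* **The end-to-end burden study** uses 12 countries × 50 strata × 25
  births, stratum means spanning 30–70 ppb, residual noise 150 g and 400
  ERF draws. The stratum-mean range deliberately spans the TMREL and is
  evenly populated: the low tail of the varying-coefficient basis is
  otherwise informed by a handful of strata, where pointwise uncertainty is
  large and cluster-robust calibration degrades — the study is meant to
  validate the pipeline, not spline extrapolation.
* **Calibration checks** (CI coverage, Wald-test null uniformity,
  percentile-vs-analytic intervals) use 20–100 seeded replicates at sizes
  chosen so each study completes in seconds.

# Known limitations

* The marginal-effect curve is identified from between-stratum contrasts of
  within-stratum slopes; with few strata or a narrow stratum-mean range it
  is noisy at the support edges, and integration from a TMREL outside the
  support relies on the natural spline's linear extrapolation.
* Burden intervals propagate ERF uncertainty only; exposure-field and
  population uncertainty are excluded by design.
* The dummy-variable logit is subject to incidental-parameter bias in
  small strata.
* No gestational-age adjustment is possible, so estimates are overall
  effects (including any mediation through shorter gestation), and no
  residential-mobility correction is attempted.
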