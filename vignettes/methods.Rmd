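---
title: "Measuring deprivation gradients in access to and participation in community running events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring deprivation gradients in access to and participation in community running events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runequity)
```

## The analytical problem

Free, weekly, community-organised running and walking events are one of the
most successful population physical-activity interventions of the last two
decades. Because events are founded bottom-up by local volunteers, there is
no guarantee that geographic access to them — or participation in them — is
equitable across the socioeconomic spectrum. The natural observational
design is ecological: England is tiled into ~33,000 Lower layer Super
Output Areas (LSOAs) of roughly 1,500 residents each, every area carries a
deprivation score (the Index of Multiple Deprivation, 0 = least to 100 =
most deprived) and census covariates, and the event organiser can attribute
every finish to a home area. The questions are then: how far is each area
from its nearest event, month by month, as the event network grows? How
steep is the deprivation gradient in distance and in participation, and how
does it evolve? And which area characteristics predict participation once
the others are held fixed?

`runequity` implements that analysis as a pipeline over three plain tables
(areas, event registry, monthly finisher counts), together with a seeded
synthetic generator of all three, so every stage can be exercised and
validated end-to-end without access to the proprietary source data.
Everything is ecological: all statements are about areas, never about
individuals, and area-level results are deliberately *not* weighted by
population size.

## Distance to the nearest event

For area $a$ with centroid $c_a$ and month $m$, the access measure is

$$d_{am} = \min_{e \,\in\, \mathrm{active}(m)} \mathrm{geo}(c_a, x_e),$$

where $\mathrm{active}(m)$ is the set of events in operation on the 15th of
month $m$ and $\mathrm{geo}$ is the geodesic ("direct linear") distance on
the WGS84 ellipsoid, computed with Karney's algorithm (via
`geosphere::distGeo`), accurate to well under a metre. A haversine
great-circle variant (sphere of radius 6371.0088 km) is available behind
`method = "haversine"` as a cross-check; on the scale of this analysis the
two differ by well under half a percent. Boundary conventions, which the
monthly evaluation date makes consequential, are: launch dates are
*inclusive* (an event launched on the 15th counts that month) and closure
dates are *exclusive* (an event closing on the 15th does not). Ties in
distance are broken lexicographically by event id so panels are fully
reproducible. Distances are carried at full precision and only rounded for
reporting.

Straight-line distance is a proxy for access, not a travel-time model: 5 km
across a city and 5 km of rural road are very different journeys. That
limitation is inherited from the study design this package implements; road
networks and travel times are out of scope.

## The Relative Index of Inequality

The RII is a regression-based inequality measure: instead of comparing the
observed extremes (noisy), fit a model of the outcome on the deprivation
score and compare the *predictions* at the observed extremes,

$$\mathrm{RII} = \frac{\hat y(\mathrm{imd}_{\min})}{\hat y(\mathrm{imd}_{\max})}.$$

RII = 1 means no gradient; above 1 the least deprived do "more". Prediction
points are the observed minimum and maximum score in the analysis set — the
actual least and most deprived areas — not the nominal 0/100 ends of the
scale and not rank-based ridits; this follows the definition the analysis
replicates, where the ratio explicitly compares "the least deprived area"
with "the most deprived area".

Two outcome-specific model families are used each month:

* **Distance** — ordinary least squares of `distance_km` on `imd_score`
  (closed-form normal equations, `fit_ols()`). The RII is the ratio of two
  affine predictions. It is exactly invariant to rescaling all distances
  (both predictions scale together) but *not* to translating them: adding a
  constant moves the ratio towards 1. Both behaviours are asserted in the
  tests. If either extreme prediction is nonpositive the ratio is
  meaningless and the month errors out rather than returning a number.
* **Participation** — univariable Poisson regression with log link of the
  month's counts on `imd_score`, with $\log(\mathrm{population})$ as
  offset (`fit_poisson_glm()`). Under the log link the predict-and-divide
  definition collapses to the closed form
  $\exp\{\hat\beta_1(\mathrm{imd}_{\min} - \mathrm{imd}_{\max})\}$, an
  identity the test suite checks to $10^{-12}$. Because the offset cancels
  in the ratio, the participation RII is exactly invariant to a common
  population rescaling, and because a month-of-year seasonal factor
  multiplies every area's rate equally, seasonality moves the *level* of
  participation but not the RII (checked by simulation).

Areas with zero population have no defined offset; they are excluded with a
logged count. The generator never produces them, but real inputs might.

## Yearly determinants of participation

For each calendar year, counts are summed over the year's months per area
and modelled as

$$y_a \sim \mathrm{Poisson}\!\big(\mathrm{pop}_a \cdot
  e^{\beta_0 + \beta_1 \mathrm{imd}_a + \beta_2 \mathrm{eth}_a +
     \beta_3 \mathrm{dens}_a/1000 + \beta_4 \bar d_a}\big),$$

with four documented conventions:

* the **distance covariate** $\bar d_a$ is the mean of the area's twelve
  monthly distances in that year (the panel's natural reduction; a December
  or mid-year snapshot would be defensible alternatives and are easy to
  swap in);
* **population density is divided by 1000** (`pop_density_scale`), so its
  coefficient is per thousand persons/km² and of comparable magnitude to
  the other terms — per single person/km² the coefficient would be three
  orders of magnitude smaller than its conventionally reported size;
* **deprivation scores are time-invariant**: score revisions are not
  comparable across years, so a single vintage is used throughout;
* coefficients are reported per year, never pooled across years — the
  interesting result *is* the trajectory of the coefficients.

The Poisson maximum-likelihood fit uses iteratively reweighted least
squares with the offset held fixed, relative deviance change below
$10^{-8}$ (at most 100 iterations) as the convergence rule, and standard
errors from the inverse Fisher information. Likelihoods that are maximised
at infinity — the all-zero-count year is the canonical case — stabilise
numerically but are no MLE, so the fit is flagged non-converged (detected
as zero total counts or coefficient magnitudes above 100) and downstream
functions refuse to interpret it. The engine is cross-checked in the tests
against `stats::glm` and against a direct BFGS maximisation of the same
likelihood.

The **quasi-Poisson** sensitivity analysis keeps the point estimates and
multiplies standard errors by $\sqrt{\hat\phi}$, with $\hat\phi$ the
Pearson dispersion (chi-squared over residual degrees of freedom). On data
that are genuinely Poisson and correctly specified, $\hat\phi \approx 1$
and the adjustment is a no-op (asserted at $n = 3000$, tolerance ±0.1).
Note that when events launch *within* a fitted year the yearly aggregate is
a sum of rates at different distances, which the single mean-distance
covariate cannot represent exactly; the resulting lack of fit shows up as
$\hat\phi > 1$ even for Poisson counts. That is a property of the yearly
reduction, not of the fitting code, and it mirrors the real analysis.
**Urban/rural stratification** simply refits within each stratum.

## Quintiles and descriptive surfaces

Areas ranked by deprivation score (ties broken by area id) are split into
five groups as equal as possible, the remainder going to the lower — less
deprived — quintiles: 7 areas give group sizes (2, 2, 1, 1, 1). Quintile 1
is least deprived. Per period and quintile the package reports the
unweighted mean of area distances and the unweighted mean of area-level
rates $1000\,y_a/\mathrm{pop}_a$; a pooled (population-weighted) rate
variant exists behind `pooled = TRUE` for comparison but is not the
default, because the analysis is defined as unweighted across areas. The
summary table of area characteristics uses type-7 (linear-interpolation)
quantiles, R's default, fixed and documented since the convention matters
at these sample sizes only in the last digit.

## The synthetic generator

The generator is the package's study-condition stand-in for the real
national panel. Its defaults are fixed at values chosen to emulate the
documented structure of that panel, and they are not tuning knobs:

* **Deprivation scores** are $100 \cdot \mathrm{Beta}(1.1, 3.969)$: mean
  21.7 by construction, right-skewed with median near 17.4, support
  (0, 100]. The shapes are exposed through `imd_marginal_moments()` so
  tests can compare sample moments against analytic values.
* **Geography**: a default bounding box of about 200 × 330 km, five random
  city centres, 80% of areas urban and clustered around cities
  (σ ≈ 0.08°), the rest scattered uniformly. Population densities are
  lognormal (urban median 4500, rural 250 persons/km²); populations are a
  tight lognormal clamped to 934–7976.
* **Couplings**: deprivation is *rank-coupled* to an urbanicity latent
  ($0.35\,\mathrm{urban} + 0.25\,z + \varepsilon$, with $z$ the
  within-stratum density residual), which preserves the Beta marginal
  exactly while concentrating deprivation in dense urban areas. The
  strengths are moderate on purpose: strong enough to produce the urban
  deprivation gradient that drives the distance-inequality dynamics, weak
  enough that monthly linear distance models keep positive predictions at
  both deprivation extremes — as the real data do. Ethnic density rises
  with density, urbanicity and deprivation through a logistic latent.
* **Event roll-out**: a cumulative yearly schedule with a superlinear ramp
  over the first four years (12, 45, 96, 166) and linear growth (+22/year)
  thereafter, sized to the territory so the mean distance to the nearest
  event falls from the mid-30s–40s of km to about 4 km over a decade. The
  first-year stock launches on the first day of the window (the real
  registry predates the study window); later launches fall on days 1–15 so
  each year's events are active by its December evaluation date. Siting
  ramps from uniform-over-territory in the first year to density-weighted
  area centroids in the last (`siting_bias` exponent, default 0.5): the
  roll-out starts geographically unbiased and urbanises, which is exactly
  what makes the distance RII start near 1 and climb.
* **Counts**: per cell, Poisson with mean
  $\mathrm{pop}_a \exp(\alpha + \beta^\top x_{am}) \, s(m)$, where the
  defaults $\alpha = -4.4$, $\beta_{\mathrm{imd}} = -0.035$,
  $\beta_{\mathrm{eth}} = -0.009$, $\beta_{\mathrm{dens}} = -0.008$ (per
  thousand persons/km²), $\beta_{\mathrm{dist}} = -0.09$ (per km) mirror
  the magnitudes reported for the late study period, and $s(m)$ is a
  cosine month-of-year factor peaking in July with amplitude 0.25,
  normalised to average exactly 1 over a calendar year. Setting
  `dispersion` $= d > 1$ switches to a gamma-mixed Poisson
  (`rnbinom(mu, size = mu/(d-1))`), which has variance/mean exactly $d$ in
  every cell — the scheme that makes the quasi-Poisson sensitivity
  analysis meaningful.

Every generator is a pure function of (config, seed): the same
configuration is byte-for-byte reproducible, and the pipeline manifest
records hashes so reruns can prove it.

What the generator does *not* emulate: real LSOA boundary geometry and
population-weighted centroids, road networks, within-area covariate
dynamics over time, event capacity constraints, and event closures (the
registry supports closure dates; the generator never emits them). Passing
tests on synthetic data therefore demonstrate that the estimators recover
known structure under the assumed generative model — deprivation-gradient
signs and magnitudes, null calibration of the RII at 1, exact quasi-Poisson
behaviour — not that the substantive findings hold in any particular real
dataset.

## Numerical and design choices worth knowing

* Months are `"YYYY-MM"` strings throughout; they sort chronologically and
  serialise unchanged. Evaluation date for event activity is always the
  15th.
* IRLS initialises at $\mu = \max(y, 0.5)$, caps the linear predictor at
  700 before exponentiating (overflow guard), and reports the iteration
  count. Rank-deficient designs are an error, not a warning.
* The distance panel is computed as one area × event distance matrix and
  monthly argmins over the active columns, which is algebraically identical
  to the brute-force double loop the tests compare against but ~100× faster.
* With no closures, each area's distance series is non-increasing and
  adding an event can never increase any cell; both invariants are tested.
* `fit_ols` reports the Gaussian ML log-likelihood and an AIC counting the
  error variance as a parameter ($k = 3$), so AIC $= 2k - 2\ell$ holds for
  both engines.
* Problem sizes in the tests are chosen so statistical assertions are
  well-powered at desk scale: moment checks at $n = 4000$–5000 areas, RII
  null calibration at 2000 areas × 12 months × 20 seeds, coefficient
  recovery at 3000 areas × 20 seeds with the recovery year's registry held
  flat so the yearly aggregate model is exactly specified.
* CSV doubles are written at full precision; the fast CSV parser can be one
  ulp off on re-parse, so round-trip equality is asserted numerically
  rather than bitwise (same-config reruns of the pipeline remain
  byte-identical, which the manifest hashes verify).

## A minimal run

```{r example, eval = FALSE}
cfg <- synth_config(n_areas = 500, month_start = "2010-01",
                    month_end = "2013-12",
                    n_events_by_year = c(6, 14, 25, 40), seed = 2024)
ds <- simulate_dataset(cfg)

panel_summary(ds$areas)
autoplot(quintile_series(ds$areas, ds$distance_panel, ds$finishers),
         outcome = "participation")
autoplot(rii_series(ds$areas, ds$finishers, outcome = "participation"))
fit_yearly_determinants(ds$areas, ds$finishers, ds$distance_panel)
```

## Known limitations

Geodesic distance is a crude access proxy; finish counts conflate repeat
and unique participants; deprivation quintiles are computed within the
supplied territory (with national data these coincide with national
quintiles); RII confidence intervals are not produced; and no
spatial-autocorrelation or panel (across-year) modelling is attempted —
each year and month is fitted independently, which is the design being
implemented, not an oversight.
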