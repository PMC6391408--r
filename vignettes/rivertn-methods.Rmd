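---
title: "Methods: projecting riverine total nitrogen loading under socioeconomic and climate scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting riverine total nitrogen loading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivertn)
```

## The problem

Excess nitrogen export from watersheds drives eutrophication — algal
blooms, hypoxia and degraded water quality — in inland and coastal waters.
How much nitrogen a river network exports depends jointly on what society
does on the land (cropland extent, urbanization, fertilizer application,
food trade) and on precipitation, which controls how much of the nitrogen
applied to a landscape is flushed into streams. `rivertn` implements a
projection pipeline for riverine total nitrogen (TN) flux across a network
of watersheds under combined socioeconomic (SSP) land-use/land-management
scenarios and climate (RCP) precipitation pathways, together with a seeded
synthetic-world generator so that every stage of the pipeline is testable
without multi-gigabyte external archives.

## The loading model

TN flux per unit watershed area, $Q_{TN}$ [kg N km$^{-2}$ y$^{-1}$], is
modelled log-linearly:

$$\ln Q_{TN} = \beta_0 + \beta_1\, f_{NANI} + \beta_2\, P_{Annual}
 + \beta_3\, P_{MAM,p>0.95} + \beta_4\, LU_{D,C},$$

$$f_{NANI} = \operatorname{asinh}(NANI/2)
 = \ln\!\left(NANI/2 + \sqrt{(NANI/2)^2 + 1}\right).$$

The predictors are:

* $NANI$ — net anthropogenic nitrogen input [kg N km$^{-2}$ y$^{-1}$],
  entering through the inverse hyperbolic sine, which behaves like
  $\ln NANI$ for large inputs but is defined for the zero and negative
  inputs that net-exporting watersheds produce;
* $P_{Annual}$ — calendar-year precipitation total [mm];
* $P_{MAM,p>0.95}$ — extreme springtime precipitation [mm]: total
  precipitation on March–May days strictly exceeding the 95th percentile
  of a fixed 1981–2010 baseline;
* $LU_{D,C}$ — percent of watershed area that is developed or cropland.

The default coefficients (`tn_coefficients()`) are
$(0.538,\; 0.438,\; 0.0012,\; 0.0033,\; 0.0213)$; `calibrate_tn_model()`
refits them by ordinary least squares of log observed flux on the
predictors, and `select_tn_model()` searches every candidate land-use
variable formed as a percent-cover sum over a nonempty subset of the six
aggregated land-use categories (cropland, developed, pasture, forest,
grassland, wetland), optionally two disjoint such sums. The selection
statistic is minimum BIC; ties go to fewer land-use variables and then
lexicographic subset order. We use BIC because the search is exhaustive
over 62–363 candidates and an information criterion penalizes the extra
variable honestly; the original model-building literature does not name
its criterion, so this is a package design choice. Predicted fluxes are
obtained by plain exponentiation of the fitted log-linear predictor, with
no smearing or retransformation bias correction: the published model is
applied directly on the natural scale and no correction is documented for
it, so adding one would change the reported flux levels by a factor that
the downstream percent-change analyses would largely cancel anyway.

## NANI accounting

$NANI$ is the signed sum of five components, each per unit watershed area:
fertilizer input, agricultural nitrogen fixation, atmospheric deposition
and net food/feed import are added; nonfood crop export (cotton/tobacco
nitrogen leaving for non-food use) is subtracted. Net food/feed import may
be negative — a watershed that exports more crop and animal nitrogen than
its population consumes carries a negative term. Historically, continental
mean shares of NANI are roughly +72% fertilizer, +45% fixation, +14%
deposition, −30% import and +0.78% nonfood export; the synthetic generator
targets these shares (see below).

The scenario-mode ("driver") accounting mirrors the historical one
component by component:

* fertilizer is the area-weighted application rate over five crop types
  (C3/C4 annual, C3/C4 perennial, C3 nitrogen-fixing), optionally rescaled
  per HUC2 region so window totals match reference estimates
  (`scale_fertilizer_to_reference()`; the window is configuration, default
  1987–2012, and matching is exact after scaling);
* fixation is the nitrogen-fixing crop area times a constant rate
  (default 14,300 kg N km$^{-2}$ y$^{-1}$), itself derivable by
  `calibrate_fixation_rate()` from a national total — dividing a 6.9 Tg N
  national estimate by the corresponding crop area reproduces that rate;
* net import is predicted from a per-HUC2 linear regression of historical
  import on historical fertilizer and fixation (`fit_import_regression()`,
  with intercept, fitted on agricultural-census-year records), under the
  assumption that the trade relationship is stationary;
* deposition follows the climate pathway, rescaled per watershed by the
  overlap-window ratio of reference to modelled deposition
  (`scale_deposition()`). Per-watershed rescaling (rather than one
  national factor) preserves the spatial pattern of the reference data;
* nonfood export is held constant beyond its last reliable census value
  (`hold_constant_after()`, default anchor 2007); the same operation runs
  backward for pre-network deposition years.

Census-year tables are interpolated linearly between censuses, and years
before the first census are filled by extrapolating the OLS trend through
all census points (`interpolate_census()`); extrapolated fixation is
floored at zero, imports are not (they are net terms). Negative
driver-derived fertilizer or fixation cannot arise from the accounting but
is clamped defensively.

## Precipitation features

Daily precipitation per (watershed, climate model) series is reduced to
the two model predictors. The extreme threshold is the 95th percentile of
*all* in-season (March–May) daily values — including dry days — over the
1981–2010 baseline, computed by linear interpolation between order
statistics (`stats::quantile` type 7), independently per watershed and
model; a wet-day-only population is available as a switch
(`wet_day_only = TRUE`) because the convention is genuinely ambiguous in
the literature, but the all-days default follows the plain reading of
"daily precipitation". Exceedance is strict (a day exactly at the
threshold does not count), and thresholds are frozen from the baseline and
reused for all historical and future years, so a future intensification
of heavy rain increases the feature rather than the yardstick.

## Scenario engine

A scenario (`scenario_spec()`) names the SSP, the precipitation mode, and
three independent factor flags: cropland, developed land and fertilizer
application rates each follow either the future trajectory or historical
levels. The SSP–RCP pairing is a fixed table: SSP1-2.6→RCP2.6,
SSP2-4.5→RCP4.5, SSP4-6.0→RCP6.0, SSP5-8.5→RCP8.5, and for the two
scenarios without a same-forcing CMIP5 pathway, SSP4-3.4→RCP2.6 and
SSP3-7.0→RCP8.5.

**Historical levels in future years.** When a flagged driver stays
"historical" in a future-period year, the engine reads it at the
year-offset-mapped historical year (future start $+k \leftrightarrow$
historical start $+k$). This keeps 30 distinct annual values in every
window — so ensemble statistics retain interannual variability — and makes
the all-historical configuration reproduce the historical baseline
exactly, which the tests assert. Land-management-only runs keep
precipitation at historical levels using the full historical ensemble, so
the only across-model spread comes from how each model's historical
precipitation interacts with the scenario's land surface; RCP ensembles
are subsets of the historical ensemble (shared GCM identities), so
model-wise pairing of historical and future runs is well defined even when
ensemble sizes differ, and all statistics use the actual member count.

**Decomposition.** `decomposition_runs()` produces the historical-period
run, a future-period all-historical baseline, the combined all-future run,
and three single-factor runs: future cropland only (carrying its embedded
NANI changes through fertilizer area, fixation and the import regression),
future developed land only (changing only the developed share of
$LU_{D,C}$), and future fertilizer rates only (propagating into import).
NANI is driver-derived for both periods in these runs so that the two
periods are accounted identically. Deposition follows the precipitation
mode — historical-precipitation decomposition runs use historical
deposition — because a deposition pathway belongs to a climate outcome,
not to a land-management factor. Because the model is log-linear with an
asinh-transformed NANI, single-factor contributions are not additive;
`blend_drivers()` shrinks the future drivers toward historical levels by a
factor $\varepsilon$ to exhibit the linear limit in which they become
additive (the tests check a sub-2% residual at $\varepsilon = 0.01$ and a
measurable interaction at full scale).

## Robustness and aggregation

Regional loads are flux × area sums over member watersheds
(`aggregate_load()`), which makes aggregation exactly additive over
partitions — a conservation property the tests verify to $10^{-9}$
relative tolerance. A projected change is **robust** when strictly more
than 50% of the climate models show a significant difference between the
two 30-year samples of annual values — a two-sided Welch $t$-test at the
95% level — and strictly more than 80% agree on the sign of change (sign
of the difference in model means; zero counts toward neither side). Welch
rather than pooled-variance is used because precipitation variance can
change between periods; the samples are treated as independent because
calendar years are not physically paired across periods. Percent changes
are computed per model and then summarized as ensemble mean ± sample SD
(mean-of-ratios, not ratio-of-means). The multi-scenario direction mask
(`scenario_agreement()`) emits the across-scenario mean change only where
at least five of six scenarios agree on the direction.

## The synthetic world

`generate_world()` builds everything the pipeline consumes:

* **Watersheds**: log-normal areas around 3,500 km², cyclic HUC2
  assignment, and two disjoint region archetypes (a MARB-like interior
  block of HUC2 regions and a Northeast-like coastal one) plus CONUS.
* **Precipitation**: an occurrence–amount process — Bernoulli wet days
  (probability 0.20–0.45 across watersheds) with Gamma amounts (shape
  0.8, scale set so expected annual totals span 600–1400 mm). Each GCM
  carries a lognormal jitter (SD 0.06) on the scale parameter shared
  across pathways; future pathways multiply the wet-day scale by a trend
  factor (defaults 1.02/1.05/1.07/1.12 for RCP2.6/4.5/6.0/8.5 — wetter
  and heavier-tailed with forcing). This simple process controls both
  features the analysis consumes and nothing else, which is the point.
* **Land use**: Dirichlet 2015 compositions per watershed, linear paths
  through 2015 in both directions, hence continuity at the
  historical/future junction by construction. Scenario archetypes set the
  2015→2100 cropland/developed deltas and fertilizer-rate factors:
  bioenergy expansion (SSP4-3.4, strongest; SSP1-2.6 mild), food-demand
  expansion (SSP3-7.0, SSP4-6.0), middle-of-the-road (SSP2-4.5), and
  stable-to-declining cropland with urbanization (SSP5-8.5). Increases
  are financed from pasture/forest/grassland in proportion to available
  area, capped so no fraction leaves $[0,1]$.
* **Crop states**: per-watershed Dirichlet weights over the five crop
  types, with the nitrogen-fixing weight calibrated (one-dimensional root
  solve) so the continental fixation/fertilizer ratio matches the target
  share ratio; application rates around 9,000–11,000 kg N km$^{-2}$ of
  crop for fertilized annuals, ramping 0.85→1 over the historical era and
  to the scenario factor by 2100.
* **NANI components**: built *on top of* the historical crop states —
  fertilizer and fixation are the driver-derived values with small
  lognormal observational jitter, deposition is levelled to its target
  continental share, import follows a known per-HUC2 linear rule in
  fertilizer and fixation (the recoverable ground truth for the import
  regression), and nonfood export is a small positive term. Continental
  mean shares then land within ~2–3 percentage points of the
  +72/+45/+14/−30/+0.78 targets, which the generator self-check asserts.
  Because observation-mode and driver-mode NANI agree up to jitter,
  switching NANI sources between the historical baseline and future
  scenario runs does not create spurious jumps.
* **Calibration data**: predictor records drawn over realistic ranges with
  ln-scale Gaussian noise whose SD is set from the sample signal variance
  so the population $R^2$ matches a target (default 0.67; default size
  280 catchment-years).

Ground truth (generating coefficients, import rule, share targets) is
always emitted alongside the data so recovery tests never re-derive it.
Everything is deterministic under the master seed; each generator derives
its own sub-stream.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: spatial correlation of rainfall and land use
across watersheds (fields are independent given their parameters),
seasonality beyond the March–May window definition, storm clustering and
interannual persistence, measurement error structure in observed loads
(noise is homoskedastic on the log scale), the economics inside IAM
scenarios, and real geography. Tests on this world validate the
*machinery* — estimators, accounting identities, classifier error rates,
engine plumbing — not the empirical adequacy of the loading model for any
particular basin.

## Numerical choices and degenerate inputs

* Percentiles: `stats::quantile` type 7 everywhere.
* OLS via `stats::lm`; rank-deficient designs (constant or collinear
  predictors, including the all-categories percent sum, which is the
  constant 100) raise a classed `degenerate-design` error, or are skipped
  as candidates during selection.
* Zero-variance annual samples have no defined $t$ statistic and count as
  non-significant; $p = 0.05$ exactly is non-significant; ties at the
  50%/80% thresholds are non-robust.
* Scaling conventions: zero-over-zero rescaling factors are 1 by
  convention; zero input with nonzero reference is an `unscalable` error.
* Coefficients are reported at full precision; the printed defaults are
  stored exactly as printed.

## Problem sizes

The default world — 50 watersheds, 5 HUC2 regions, 7-member ensembles,
30-year periods with daily precipitation for the historical window plus
the future period — keeps a full pipeline run under a minute and is the
size at which the acceptance checks run. The `preset = "paper"`
configuration (2105 watersheds, 21/16/20/12/21-member ensembles) scales
the same code to the full-domain shape when wanted. Unit tests use
smaller worlds still (6–15 watersheds, shortened periods) since they
exercise logic, not statistics.

## Known limitations

* The import regression extrapolates a stationary trade relationship far
  out of sample; the package follows that assumption rather than
  questioning it.
* Percent changes with observation-mode historical NANI and driver-mode
  future NANI inherit any level mismatch between the two accountings; the
  synthetic generator calibrates them to agree, and real applications
  should rescale drivers to observations (the fertilizer and deposition
  rescaling operations exist for exactly this).
* No uncertainty propagation from coefficient standard errors into
  projections — ensemble spread across climate models is the only
  uncertainty reported, matching the analysis design this package
  implements.
* Robustness is classified per unit with no field-significance or
  multiple-testing control across watersheds.
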