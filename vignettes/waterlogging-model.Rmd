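---
title: "Modelling barley waterlogging stress: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling barley waterlogging stress: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barleywl)
```

## The problem

Soil waterlogging — pore space so water-filled that roots cannot respire —
is a major, under-modelled constraint on cereal production in wet temperate
climates. Its impact depends not just on how long the soil stays saturated
but on *when* saturation occurs relative to crop development: juvenile
waterlogging slows leaf appearance and delays flowering, while waterlogging
during grain fill senesces the canopy and truncates grain filling.
`barleywl` implements a desk-scale barley simulator whose purpose is to make
that phenology-dependent stress machinery, and the analyses built on it
(stress-pattern typologies, climate-scenario factorials, adaptation
screening), fully testable without any external data.

## The stress physiology

All stress is driven by one state variable, the **fraction of roots
waterlogged** (`rtfr`): the proportion of the root zone lying in soil layers
flagged as saturated, with partial-layer proration. Two dimensionless
indices respond to it:

* `oxdef_photo_factor(rtfr)` multiplies daily photosynthesis: 1 (no stress)
  for `rtfr < 0.8`, falling linearly to 0 at full saturation.
* `oxdef_pheno_factor(rtfr)` indexes the developmental response: 1 below
  the same 0.8 threshold, falling linearly to 0.8 at full saturation.

The threshold of 0.8 reflects experimental observations that barley
tolerates substantial partial root-zone saturation before photosynthesis and
development respond; both indices share one driver because their definitions
are identical.

The developmental effect is stage-dependent through a modifier function
(`stage_modifier_pheno`) anchored at 0.65 at stage 4.0, 0.95 at stage 5.5,
1.0 at flowering (stage 6), 1.5 at stage 10. Values below 1 apply before
flowering and *delay* development; values above 1 apply after flowering and
*truncate* grain filling. Two choices close the gaps the anchor table leaves
open, both config-exposed: the 0.65 value is extended flat below stage 4,
and a linear ramp joins 0.95 to 1.0 over stages (5.5, 6), preserving
continuity without inventing new extrema.

On a stressed day the daily thermal-time increment is multiplied by

```
1 + (stage_modifier(stage) - 1) * severity,
severity = (1 - oxdef_pheno_factor(rtfr)) / 0.2 * adaptation_gate
```

so the printed anchors are exactly the multipliers realised at full
saturation, milder stress interpolates towards 1, and the pre-/post-
flowering gating is automatic because the modifier crosses 1 at flowering.

### Three response stages and genotypic tolerance

Plant response to a waterlogging spell is staged:

1. **Lag** (`lag_days`, default 3): water supply is unimpeded, growth is
   unaffected.
2. **Full stress** (`adapt_days`, default 10, after the lag): oxygen-
   dependent processes are limited; the raw index applies.
3. **Adapted**: morphological adaptation (aerenchyma formation, root
   porosity) lifts the photosynthesis multiplier to a genotype floor
   (`y_oxdef_lim_photo_floor`, 0 = fully susceptible, 1 = fully tolerant).

Durations are not stated in the source physiology, so the defaults are
chosen to make a two-week saturation event traverse all three stages; both
are genotype-overridable. The same gate scales the developmental severity
(0 in the lag, 1 under full stress, `1 - floor` when adapted): the sources
do not spell out whether adaptation relieves the developmental pathway, and
we resolve the tension in favour of full recovery for fully tolerant
genotypes, consistent with adapted plants regaining pre-waterlogging
physiology. A spell resets whenever `rtfr` drops below the 0.8 threshold.

## The minimal crop model around it

Everything else is a deliberately minimal, standard crop-model scaffold:

* **Phenology**: thermal time on a three-point cardinal response (base 0,
  optimum 26, maximum 34 degC), accumulated through 10 phases spanning stage
  codes 1-11, with vernalisation and photoperiod factors (APSIM-style linear
  and quadratic forms, sensitivities 0-5) modulating the pre-floral phases.
  Spring presets use `vern_sens = 1`, `photop_sens = 1`,
  `tt_end_of_juvenile = 400`; winter presets use 2.5-4 sensitivities and up
  to 750 degree-days.
* **Water balance**: a layered cascading bucket. Rain fills the top layer;
  water above each layer's drained upper limit percolates downward limited
  by saturated conductivity and by room below; excess above saturation backs
  up and leaves as runoff; evaporative demand (Priestley-Taylor) is
  extracted top-down. Layers at or below a static water table are held
  saturated and excluded from storage change, so the daily balance closes
  identically. A layer is flagged waterlogged at 97% of the DUL-to-SAT
  range (not 100%, to avoid floating-point knife-edges).
* **Capillary fringe**: a layer resting on a saturated layer is also
  flagged waterlogged while its own content is in the upper half of the
  DUL-SAT range. Without this, a perched water table flickers in and out of
  the saturation flag on single dry days purely because of layer
  discretisation; with it, saturation spells have the multi-day to multi-week
  persistence that drives adaptation dynamics. The fraction (default 0.5) is
  config-exposed.
* **Roots**: linear descent (15 mm/day) from sowing depth, halted while the
  root zone is stressed or the layer at the front is saturated — roots do
  not elongate into anoxic soil. Root uptake skips saturated layers (anoxic
  roots do not extract water), but the surface layer always evaporates.
* **Growth and yield**: radiation-use-efficiency biomass
  (`radn x cover x RUE x f_CO2 x stress`), a stage-driven canopy-cover
  curve, and a harvest-index yield with a reproductive penalty equal to the
  mean effective photosynthesis multiplier over stages 5-7 — a compact stand-
  in for kernel-number determination around flowering. `f_CO2` is a
  rectangular hyperbola normalised to 1 at 350 ppm and about 1.2 at 700 ppm
  (half-saturation 175 ppm), config-exposed.
* **No nitrogen, pests, or crop failure**: simulations are intentionally run
  without nitrogen limitation, and sustained waterlogging degrades but never
  kills the crop.

## Synthetic weather, soils and scenarios

The weather generator is a first-order two-state Markov occurrence chain
(giving realistic multi-day wet spells) with gamma-distributed wet-day
amounts whose scale is derived from the target mean annual rainfall, so the
analytic expectation `365.25 x P(wet) x shape x scale` equals the target by
construction. Seasonal structure enters through a sinusoidal modulation of
wet-day amounts and sinusoidal temperature/radiation cycles with AR(1)
temperature residuals; wet days are made cooler and dimmer by fixed
depressions, honouring the interdependence of rainfall, temperature and
radiation without a full cross-correlation model. Everything is
deterministic under a seed. What it does **not** emulate: inter-annual
regimes (ENSO-like persistence), seasonal variation in wet-day *frequency*,
extreme-value tails beyond the gamma, or spatial correlation — so passing
tests demonstrate the machinery, not calibration to any real site.

Soil archetypes are seeded 5-7-layer profiles: freely drained (conductive
throughout), duplex waterlogging-prone (permeable topsoil over a slowly
permeable clay B horizon, 0.2-1.5 mm/day, so perched saturation builds over
wet winter spells and drains between them), and shallow water table. Future
climates are monthly delta-change perturbations (additive temperature
offsets, multiplicative rain/radiation factors) of a baseline series, with
the scenario's CO2 taken from the SSP585 empirical regression implemented
verbatim as printed; because its printed form is typographically ambiguous,
a year-to-ppm table can be substituted everywhere the formula is used, and
no downstream code depends on the formula's shape.

## The stress typology

Each season is collapsed to six phase means of daily `oxdef_photo` over
growth-stage bins JV1 [10,21), JV2 [21,32), FIN [32,65), FL [65,71),
GF1 [71,80), GF2 [80,87) on a 0-100 growth-stage scale (the published bin
table labels both [32,65) and [65,71) "FIN"; the second is renamed FL
here). The mapping from the 1-11 stage codes to that scale is a
piecewise-linear package convention anchored at emergence = 10, end of
juvenile = 21, floral initiation = 32, flowering = 65, start of grain
fill = 71, end of grain fill = 87. Seasons that never reached a bin are
excluded from clustering rather than zero-filled, to avoid conflating crop
failure with a stress pattern.

Clustering is Lloyd's k-means (k = 4) with k-means++ seeding, best of
seeded restarts; empty clusters are re-filled by moving the point farthest
from its centroid out of a cluster that can spare one, a rule that is stable
even on fully duplicated data. Labels SW0-SW3 (spring) / WW0-WW3 (winter)
order clusters by ascending total stress (sum of `1 - centroid`), ties
broken earlier-onset-first, with a verbal descriptor whose onset timing is
the earliest phase with a centroid below 0.95. Spring and winter seasons
are clustered separately. The phase means are the primary feature (the
trajectories being clustered are stress values); cumulated waterlogged-day
counts per bin are emitted alongside.

## Factorial pipeline and metrics

`run_factorial()` simulates every (site, genotype, sowing window, scenario,
realisation, year) cell twice under identical weather — waterlogging physics
on, and both indices pinned to 1 — giving the paired yields behind the
**yield penalty** `100 x (yield_default - yield_wl) / yield_default`, and
optionally a third run on the freely drained archetype as the simulation
analogue of a drained control for the **yield loss**
`100 x (yield_ck - yield_wl) / yield_ck`. An ensemble of stochastic weather
realisations with seeds derived from the master seed stands in for an
ensemble of climate projections (default 27). Frequency shifts of stress
patterns across climate periods are tested by one-way ANOVA with
realisations as replicates plus LSD letters; the tolerance benefit restricts
tolerant-minus-susceptible paired yields to season-years whose growing-season
rainfall (sowing to maturity of the unstressed run) exceeds the within-cell
90th percentile, and reports all-year and dry-year benefits alongside to
verify tolerance carries no dry-year cost.

## Numerical choices and degenerate inputs

* Phase-completion comparisons carry a 1e-9 degree-day epsilon: without it,
  `a + (target - a)` can land one ULP short of the target and stall
  development permanently.
* Leap days are generated and consumed like any other day; day-of-year 366
  simply extends the season.
* The saturation flag (97%) and capillary-fringe (50%) fractions, the 0.8
  stress threshold, the stage-modifier anchors, the three-stage durations
  and the CO2 response are all overridable through `wl_constants()`, with
  overrides validated against documented ranges.
* Weather readers reject NaN fields, non-contiguous day sequences and
  `maxt < mint` rows with the offending line number; writers emit C-locale
  CSV.
* k-means on fewer distinct points than clusters returns a zero-WSS fit
  rather than failing.

## Problem sizes used in the tests

The shipped tests run the full pipeline at deliberately small sizes chosen
to exercise every code path: the miniature fixture study is 2 sites x 2
genotypes x 2 sowing windows x 2 scenarios x 3 realisations x 5 years, the
directional acceptance checks use 2-3 realisations of 3-8 years, the
clustering oracle uses 10 points, and archetype recovery uses 400 synthetic
seasons. These sizes make the suite reproducible in minutes on one CPU
while leaving the statistical contrasts far from marginal.

## Known limitations

* Biomass has no drought-stress term, so dry-year yields are optimistic and
  the tolerance benefit in dry years reflects only the absence of
  waterlogging, which is the contrast of interest here.
* There is no terminal heat or drought stress. One measurable consequence:
  a waterlogging-delayed crop can drift its growth window into brighter
  spring days and out-yield its unstressed twin by a few hundredths of a
  percent. The yield-penalty sign property is therefore asserted to hold up
  to a 0.05-percentage-point allowance rather than exactly.
* The water balance has no lateral flow, no rising water tables, and a
  static capillary-fringe rule instead of a Richards-equation solution.
* Stage-dependence is applied to the phenology pathway only; the
  photosynthesis index is stage-independent, with the stage hook left open.
* The generator's occurrence chain is seasonally homogeneous; sites whose
  wet-day frequency (not just amount) is strongly seasonal are approximated.

## A worked miniature study

```{r fixture, eval = FALSE}
dir <- tempfile("study")
design <- make_fixture_study(dir, master_seed = 7)
results <- run_factorial(design, include_control = FALSE)
classified <- classify_results(results, seed = 2)
aggregate_penalty(classified$results,
                  by = c("site", "genotype", "scenario"))
tolerance_benefit(classified$results,
                  "winter_tolerant", "winter_susceptible")
```

On the waterlogging-prone duplex site this yields single-digit mean
percentage penalties for the susceptible winter genotype that grow under
the wetter 2080-style scenario, near-zero penalties on the freely drained
site, and a positive wet-year tolerance benefit — the directional behaviour
the test suite asserts.
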