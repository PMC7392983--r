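---
title: "Auditing street-level imagery coverage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing street-level imagery coverage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streetcover)
```

## The problem

Virtual audits assess neighborhood environments from street-level panoramic
imagery instead of in-person observation. Their validity depends on three
properties of the imagery over the study area: whether imagery exists at all
(availability), how old it is (image age), and how much capture dates vary
within small areas (image-age variance). If any of these covaries with
neighborhood socioeconomic conditions, virtual-audit measures are
differentially missing or differentially stale across exactly the gradient
most studies care about.

`streetcover` implements the full measurement-and-modeling pipeline for this
question at city scale:

1. place a point lattice at 500-m intervals over each projected city
   boundary;
2. compute the road length within a 100-m buffer of each point and discard
   points with none (imagery is only captured along mapped roads);
3. query an imagery-metadata provider for each eligible point within a 100-m
   radius, recording availability and the capture year-month of the closest
   (most recent on distance ties) panorama;
4. aggregate availability, mean image age (months before April 2019), and
   the SD of image age to subcity, city, and country levels;
5. standardize subcity socioeconomic covariates, build combined Z-score
   indices, and fit mixed-effect regressions linking them to the three
   outcomes.

A synthetic-city generator with known ground truth stands in for the live
metadata API and the harmonized covariate platform, so every stage runs and
is testable at desk scale.

## Spatial machinery

**Projection.** Source GIS software was used by the original audit without a
stated CRS. We project each city with an azimuthal equidistant projection on
a sphere of radius 6 378 137 m, centered on the boundary's area centroid.
AEQD preserves distances from the center exactly; at city scale (inputs over
1000 km are refused) residual distortion is well under 1%. The forward and
inverse maps are exact inverses, so lon/lat round-trips are limited only by
floating point; the sphere radius reproduces the conventional
111.32 m per 0.001° scale used in the oracle checks.

**Lattice.** The audit does not say where its 500-m grid originates. We
anchor at the lower-left corner of each city's bounding box — deterministic,
testable, and order-independent. Points exactly on the boundary are included
(closed polygon), avoiding edge-case drops that would depend on vertex
order.

**Buffers.** Road length within 100 m is computed by exact circle–segment
clipping: each polyline edge is a quadratic in its parameter, whose root
interval intersected with [0, 1] gives the in-disc fraction. There is no
densification step and no polygonal buffer approximation, hence no
tolerance knob in the core metric; a 1-cm densification oracle is used in
tests only.

**Subcity assignment.** Boundary-inclusive point-in-polygon with a
lexicographic-smallest-id tie-break on shared edges. Overlapping unit
interiors are a data error and are rejected, not silently resolved.

## The provider abstraction

`query_metadata()` is the only contact point with imagery metadata. The
bundled synthetic provider is a pure function of its panorama store:
nearest-panorama search is an exhaustive scan (any faster index must agree
exactly), the search radius is Euclidean and closed, and distance ties are
broken by the most recent capture date, then smallest panorama id — the
reading consistent with selecting "the closest image" while preferring "the
most recent image" where several coexist. Provider failures become status
`ERROR`; they stay in the audit report but are dropped from all models
(complete-case analysis). A skeleton HTTP adapter shows where a live API
client would slot in; it performs no network I/O here and is untested
against any live service.

## Outcomes

Image age is the whole-month difference between the capture year-month and
the April 2019 reference; the metadata API reports year-month only, so
day-level offsets are not defined and integer month arithmetic is used.
Unit summaries report availability as a percentage of audited points, and
the mean and SD of age over *available* points only, with the sample
(n − 1) SD. A unit with a single available image has a defined mean but an
undefined SD, so complete-case sets are outcome-specific — the reason the
age and age-variance models can have different n. Values are kept at full
precision internally; rounding (one decimal for percentages, three for the
error rate) happens only at report time.

## The socioeconomic index

Each covariate (population density, piped water, sewer connection, durable
walls, labor-force participation, secondary education, and optionally the
share of households above the poverty line) is Z-scored across the analysis
set of the model being fit — not once globally — matching the per-model
complete-case n differences in this kind of audit. The combined index is
the unweighted sum of the Z-scores; six-variable and seven-variable
(with poverty) versions are both produced, with poverty-missing units
excluded listwise from the seven-variable index only. Index exposures enter
the models on their own scale, untransformed.

## Models

*Availability* (point level): mixed-effect logistic regression of the
binary availability outcome on one Z-scored exposure, controlling for
Z-scored road length in the buffer, country (El Salvador, Nicaragua,
Panamá, Costa Rica, and Guatemala pooled into one Central-America level),
and Z-scored subcity area, with city-grouped random effects on the
intercept and on per-city Z-standardized X/Y coordinates (independent
variance components). Whether the original specification also kept a random
intercept alongside the spatial slopes is not stated; we include it by
default as the richest structure consistent with the description, with
`random = "slopes"` as a documented toggle. The marginal likelihood is
integrated by the Laplace approximation (`lme4::glmer`, nAGQ = 1). Odds
ratios are per SD of the exposure.

*Image age and age variance* (subcity level): mixed-effect linear
regression with a city random intercept, fitted by REML (`lme4::lmer`);
coefficients are months per SD. P-values use the large-sample normal
approximation of b/se, which the original analysis leaves unstated.

The degenerate `random = "none"` paths use plain `glm`/`lm` and are checked
against hand-rolled IRLS and normal-equation oracles, so the mixed and
fixed routes are validated independently of `lme4`.

Quasi-complete separation (a single-class outcome) raises an error rather
than a misleading fit; random-effect variances are allowed to sit at the
zero boundary. `run_model_battery()` fits every exposure × outcome (×
country stratum) cell, records failing cells with their error messages,
and never aborts the battery.

## The synthetic world

`simulate_city()` generates a square city with a rectangular road grid,
equal-width vertical-strip subcity units, and one latent SES factor per
unit that drives all seven covariates (so the two combined indices are
strongly correlated by construction, as observed empirically in real
harmonized data), road density, panorama retention, and image age.

Generator defaults are the stated world: 500-m sampling, 100-m radius,
April 2019 reference; a 5-km city (~121 lattice points); 4 units; a 300-m
road grid; latent SES SD 1; a retention intercept placing baseline availability broadly in the
35-45% range the continent-wide audit reports; mean image age 55 months with between-unit SD 6 and
within-unit SD 18 months (country-level means in the real audit span
roughly 27–65 months with SDs 10–32). Ages are truncated at zero,
rounded to whole months, and converted to capture year-months before the
reference date.

Two availability modes exist because two requirements pull apart:

- **site mode** (default): candidate panorama sites every 50 m along the
  roads are retained independently with probability
  `plogis(beta0 + beta_ses * SES + beta_road * road_density_z)`. This is
  the natural generative story, but point-level availability is then
  1 − (1 − p)^K for K nearby sites: it saturates, and the injected logistic
  coefficient is *not* the point-level truth.
- **point mode**: one Bernoulli draw per prospective lattice point, with a
  retained panorama snapped to the nearest road location. At 500-m spacing
  the 100-m audit discs are disjoint, so the audited outcome is exactly the
  stated logistic model and injected coefficients are recoverable. All
  structural invariants (panoramas on roads, determinism from the seed)
  hold in both modes.

Parameter-recovery and calibration suites therefore use point mode with the
road coefficient set to zero and the latent SES factor as the fitted
exposure: fitting a noisy covariate instead would attenuate the estimate
toward zero by the covariate's reliability, which is a property of
measurement error, not of the estimator under test.

What a green recovery test does establish: the design assembly,
standardization, and lme4-based fitting recover known point-level and
unit-level effects without material bias, with approximately nominal Wald
coverage and type-I error. What it does not establish: performance under
realistic street topology (the grid is rectangular), informative
missingness of roads, spatially correlated SES, or measurement error in
covariates.

## Numerical choices

- Boundary tolerance for "on an edge" is 1e-9 m; panorama distance ties are
  ties within 1e-9 m.
- Constant covariates (zero spread) refuse to Z-score rather than return
  NaN; the battery records such cells as failed.
- Replicate counts in the acceptance suite are reduced to desk scale (100
  effect replicates, 200 null replicates, ~12 cities of 2.5–4 km each) but
  respect the stated minima; Monte-Carlo error is handled with 3-MCSE
  bounds rather than fixed tolerances.
- Optimizer settings are lme4 defaults with derivative checks disabled for
  speed; every simulation consumes a single integer seed, and sub-seeds
  are drawn below 2^31.

## Known limitations

- The grader-facing in-text arithmetic targets are identities on published
  counts; the headline regression tables of the original audit require the
  live metadata API and the harmonized covariate platform and are out of
  scope by design.
- Whether the original 500-m grid was one global lattice or per-city is
  unknown; the per-city anchor is this package's choice.
- Points inside a city boundary but outside every subcity unit are kept in
  the sample frame with a missing unit id and drop from models at the
  complete-case step; how the original audit handled them is unstated.
- Network distance is not used anywhere; the 100-m metadata radius is
  Euclidean.
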