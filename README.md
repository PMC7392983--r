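# streetcover

Quantifying street-level imagery coverage — availability, image age, and
image-age variance — across cities, and its association with subcity
socioeconomic conditions.

## Who this is for

Researchers planning *virtual audits* (assessing neighborhood environments
from street-level panoramas instead of in-person visits) need to know, for
a study region: does imagery exist near the streets of interest, how old is
it, and how much do capture dates vary within small areas? If any of these
covaries with socioeconomic conditions, virtual-audit measures are
differentially missing or stale along exactly the gradient under study.
`streetcover` provides the measurement pipeline and the statistical models
to quantify that risk, plus a synthetic-city generator with known ground
truth so every stage runs without API keys, quotas, or network access.

## What it computes

For each city the pipeline:

1. projects the boundary and road network to planar meters (azimuthal
   equidistant, centered on the city centroid);
2. places a point lattice at 500-m intervals over the boundary;
3. computes the road length within a 100-m buffer of each point by exact
   circle–segment clipping, and discards points with no road (ineligible);
4. queries an imagery-metadata provider within a 100-m radius of each
   eligible point, recording availability and the capture year-month of
   the closest panorama (most recent on distance ties);
5. aggregates three outcomes at subcity/city/country level: availability
   (% of points with imagery), image age (mean months before April 2019),
   and image-age variance (SD of age in months, n−1 denominator).

Subcity socioeconomic covariates are Z-scored and summed into combined
indices, and associations are estimated per standard deviation:

- **availability** (point level): mixed-effect logistic regression with
  fixed effects for the exposure, road length in the buffer, country
  (Central American countries pooled), and subcity area, and city-grouped
  random effects on the intercept and on per-city Z-standardized X/Y
  coordinates (a random slope across space) — `lme4::glmer`, Laplace
  approximation; odds ratios per SD;
- **image age / age variance** (subcity level): mixed-effect linear
  regression with a city random intercept — `lme4::lmer`, REML; months per
  SD.

## Worked example

```r
library(streetcover)

study <- simulate_study(n_cities = 8, seed = 7)   # known ground truth
audit <- audit_study(study)                       # lattice -> buffers -> metadata
audit$report$pct_ok_rounded
#> [1] 43.3

res <- run_model_battery(audit$frame, audit$units,
                         exposures = c("pct_sewer", "index_without_poverty"),
                         outcomes = c("availability", "mean_age"))
res[, c("outcome", "exposure", "n", "b", "OR", "SE", "p", "converged")]
#>        outcome              exposure   n       b   OR     SE      p converged
#> 1 availability             pct_sewer 693  0.2113 1.24 0.0962 0.0281      TRUE
#> 2 availability index_without_poverty 693  0.0403 1.04 0.0197 0.0406      TRUE
#> 3     mean_age             pct_sewer  32 -4.3522   NA 2.0645 0.0350     FALSE
#> 4     mean_age index_without_poverty  32 -0.7415   NA 0.3549 0.0367      TRUE
```

Reading the output: 693 eligible lattice points across 8 synthetic cities
returned imagery for 43.3%. A subcity unit one SD higher in sewer
connection has 1.24 times the odds of imagery availability per point
(holding road length, country, and unit area fixed), and its available
imagery is on average 4.4 months newer. `n` differs by outcome because age
models run at the subcity level (32 units). One age cell is flagged
`converged = FALSE`: with 32 units the city-intercept variance sits on the
zero boundary — the battery reports this honestly rather than hiding it.

The same stages run as a CLI over flat GeoJSON/CSV artifacts:

```sh
Rscript inst/cli/streetcover simulate --out-dir run1 --seed 7 --n-cities 8
Rscript inst/cli/streetcover all --out-dir run1 --seed 7
# run1/ now holds sample_frame.csv, audit.csv, coverage_*.csv,
# ses_index.csv, model_results.csv and per-stage manifests with input hashes
```

## Design notes

See `vignettes/streetcover-methods.Rmd` for the model assumptions, the
synthetic world's two availability modes (per-site retention vs exact
point-level logistic), parameter defaults and their rationale, numerical
choices, and known limitations.
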