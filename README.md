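# icebears

Sea-ice phenology and polar bear land use, body condition, and
reproduction: a tested, reusable implementation of the analysis chain
used to quantify how sea-ice loss affects bears in seasonal-ice regions
such as Baffin Bay. It is written for quantitative ecologists who want to
run, check, or extend each stage of that chain — from daily ice-fraction
series to 35-year reproductive projections — on their own or simulated
data.

## What it computes

* **Ice phenology** — spring/fall transition dates, defined as the first
  persistent crossing of the 50% ice-covered fraction (5-day smoothing,
  5-day persistence), the ice-free duration `durfree = fall − spring`,
  OLS trends in d/decade, and linear forward scenarios (presets:
  *declining*, spring −0.83 d/yr and durfree +1.85 d/yr; *stable*,
  −0.21 and +0.29 d/yr).
* **Telemetry** — Argos speed/angle filtering (10 km/h; 15°/25° over
  2.5/5 km), daily best positions (qualities 1–3 in the 12:00 UTC ± 3 h
  window), strict 4/5/6-day thinning, haversine distances (R = 6371 km),
  and onshore arrival/departure detection (5-km coastal buffer, 14-day
  persistence, linear zero-crossing interpolation, >8-day gap exclusion
  with a 12–30-day open-water swimming exception, denning exclusions),
  with decadal Welch t-tests and trends.
* **Body condition** — multinomial logit of the 3-level BCS
  (reference BCS = 2) on class, decade and ice covariates
  (`BCS ~ class + p2000 + springtran + ts.springtran + durfree(t−1) +
  class×ice`), all-subsets candidate generation under marginality
  (340 models), AIC ranking, Akaike weights, ΔAIC < 4 full model
  averaging, importance scores, and Hosmer–Lemeshow GOF (df 16/8).
* **Reproduction** — binary litter-size logits for COY and YRL (with the
  |r| ≥ 0.9 collinearity screen), recruitment ratios with 10,000-draw
  bootstrap SEMs, and exact Kendall rank correlations.
* **Projection** — mean COY litter size over 35 years: resample unit
  records, refit the most-supported models, draw BCS then litter size
  under the scenario covariates, report percentile bands.
* **Synthetic data** — ice series, coastline, duty-cycled Argos-like
  tracks, and observation tables generated from known ground truth
  (defaults set to the published most-supported model coefficients), so
  every stage above is testable end to end.

## Worked example

Reconstruct the yearling litter data from the published Baffin Bay count
table and fit the decade-only litter-size model:

```r
library(icebears)
library(dplyr)

records <- litters_from_counts(filter(bb_litter_counts(), stage == "YRL"))
fit <- fit_binary_logit(
  tibble::tibble(p2000 = as.numeric(records$decade == "2000s")),
  as.integer(records$litter_size == 2))
tidy(fit)
#> # A tibble: 2 × 6
#>   outcome term      estimate    se     z      p
#>   <chr>   <chr>        <dbl> <dbl> <dbl>  <dbl>
#> 1 two_cub intercept    0.595 0.311  1.91 0.0562
#> 2 two_cub p2000       -0.759 0.404 -1.88 0.0601
plogis(tidy(fit)$estimate[1])
#> [1] 0.6444444
```

The decade coefficient (−0.759, SE 0.404) is the log-odds change in
having a two-cub yearling litter from the 1990s to the 2000s, and 0.64 is
the fitted 1990s two-cub probability — cub production shifted toward
singleton litters as the ice-free season lengthened. The full synthetic
chain runs as:

```r
report <- run_pipeline(default_config(seed = 1))
```

which generates ice, tracks and observations, detects land-use events,
fits and ranks the condition and litter models, and projects litter size
under the fitted scenario, returning a reproducible machine-readable
report.

## Layout

* `R/` — one file per stage (`seaice`, `telemetry`, `condition`,
  `reproduction`, `projection`, `synthetic-*`, `io`), plus tidiers and
  plotting.
* `tests/testthat/` — unit, property (oracle-backed), and acceptance
  suites; all fixtures are generated in code.
* `vignettes/icebears-methods.Rmd` — the model descriptions, design
  decisions, and generator assumptions in full.
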