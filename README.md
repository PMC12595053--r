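# ensotele

Quantifying how El Niño–Southern Oscillation (ENSO) variability propagates
into terrestrial climate and vegetation productivity over gridded monthly
data — for researchers in ecosystem remote sensing, agro-climatology and
climate-impact assessment who need a tested, reproducible version of the
standard teleconnection workflow.

## What it computes

Given an Oceanic Niño Index (ONI) style series and monthly raster cubes of
climate variables and sunlit/shaded gross primary productivity (GPPsun,
GPPshade), the package:

1. **Classifies ENSO phases.** The index is smoothed with the centred
   3-month running mean that defines the ONI and each month is labelled
   El Niño (index ≥ +0.5 °C), La Niña (≤ −0.5 °C) or neutral.
2. **Builds anomaly cubes.** Each variable is converted to monthly
   anomalies (per-calendar-month climatology removed), detrended per pixel
   by OLS, and 3-month smoothed; provenance flags enforce this order. A
   fine-resolution forest-loss raster can be aggregated into a conservative
   deforestation filter, combined with crop-suitability masks.
3. **Maps teleconnections.** For each pixel, the phase-conditional Pearson
   correlation r between the smoothed index at El Niño (or La Niña) months
   and the local anomaly series at lag ℓ ∈ {−3..+3}, with a two-sided
   p-value from t = r√((n−2)/(1−r²)) and p < 0.05 significance masking.
4. **Aggregates exposure by the Entropy Weight Method.** With the m × n
   matrix X of significant |r| values, P_ij = X_ij / Σ_j X_ij,
   E_i = −(1/ln n) Σ_j P_ij ln P_ij, d_i = 1 − E_i, w_i = d_i / Σ_i d_i and
   the per-pixel exposure index exp_j = Σ_i w_i X_ij (min–max scaled), in
   [0, 1]. Spatially patchier variables get larger weights.
5. **Classifies sensitivity.** Significant GPP correlations become
   productivity directions (+1 increase / −1 decrease, phase-aware) and the
   sun/shade pair maps into a four-class typology (both increase, both
   decrease, sun-only decrease, shade-only decrease) with area percentages.
6. **Detects timing.** Lag profiles of the pixel-wise r distribution across
   lags −3..+3, median sign-transition detection between consecutive lags
   (default pair (−1, 0)), and maps of pixels shifting from non-significant
   to significant across the transition.

A synthetic-data module generates ONI-like AR(1) series and teleconnected
cubes (climatology + trend + β·lagged index + noise) with known ground
truth, so the entire pipeline is testable without external downloads.

## Worked example

```r
library(ensotele)

res <- run_pipeline(run_config(seed = 12))
res$climate$elnino$ewm
#> <ewm_result> [ok] 354 domain pixels
#>      entropy weight
#> tmax  0.9952 0.0139
#> tmin  0.9728 0.0795
#> vpd   0.8685 0.3841
#> pr    0.9574 0.1245
#> soil  0.9341 0.1925
#> pdsi  0.9297 0.2054
#>   exposure range [0.006, 0.847]

res$gpp$elnino$areas
#>              category n_pixels    percent
#> 1       both_increase       53 23.6607143
#> 2       both_decrease       65 29.0178571
#> 3   sun_decrease_only       55 24.5535714
#> 4 shade_decrease_only       49 21.8750000
#> 5                none        2  0.8928571
```

The entropy/weight table reads exactly like a published exposure-index
table: `vpd` teleconnects over the smallest share of the synthetic grid, so
its spatial distribution is the most concentrated, its entropy the lowest
and its weight the largest (0.3841). The exposure grid combines the six
scaled signals with those weights, pixel by pixel, into a 0–1 index. The
area table mirrors the generator's four sensitivity quadrants: each
constructed category covers roughly a quarter of the masked pixels, with
the residual `none` share coming from pixels whose correlations miss the
p < 0.05 cut.

A command-line front end wrapping the same functions ships at
`inst/cli/ensotele` (subcommands `simulate`, `phases`, `preprocess`,
`correlate`, `exposure`, `sensitivity`, `lags`, `run-all`,
`table1-check`).

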