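---
title: "Methods: ENSO teleconnection exposure and sensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ENSO teleconnection exposure and sensitivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensotele)
```

## The problem

El Niño–Southern Oscillation (ENSO) is the dominant driver of interannual
climate variability across the tropics. Its warm (El Niño) and cool
(La Niña) phases teleconnect to terrestrial temperature, moisture and
vegetation productivity with region-specific sign, strength and timing.
`ensotele` implements the standard pixel-wise workflow for quantifying
those teleconnections over monthly raster records and summarising them as
a climatic *exposure* index (how strongly ENSO-linked climate stress hits a
pixel) and a productivity *sensitivity* typology (how the sunlit-canopy and
shaded-subcanopy layers of vegetation respond), plus a lag analysis of when
the response occurs.

## Phase classification

The ocean index is handled exactly as the Oceanic Niño Index is defined: a
centred 3-month running mean of monthly SST anomalies, with months at or
beyond ±0.5 °C labelled El Niño / La Niña. Three conventions are fixed
here and used everywhere:

* **Edge months** of the running mean use the available 2-month partial
  window instead of being dropped, so a 348-month index stays aligned with
  348-month cubes.
* **The threshold is inclusive** (≥ +0.5 °C is El Niño). "Exceeding
  ±0.5 °C" is ambiguous at the boundary; we document inclusivity and make
  the threshold an argument.
* **Phase filtering uses per-month labels**, not multi-month episodes. The
  NOAA-style episode catalogue (runs of ≥ 5 months, `extract_episodes()`)
  is provided for reporting only; correlations condition on the labelled
  months directly.

A `smoothed` flag on the series makes double smoothing an error rather
than a silent bias.

## Anomaly preprocessing

Cubes pass through a fixed order — monthly anomalies, per-pixel linear
detrending, 3-month smoothing — enforced by provenance flags so stages
cannot run out of order. "Anomaly" means the per-calendar-month
climatological mean is removed (the standard definition for monthly data);
a switch for a single overall mean exists because some workflows use it.
Detrending is ordinary least squares per pixel (via `stats::lm.fit` on the
stacked pixel matrix), removing spurious correlation between independently
trending series. Missing data propagate conservatively: a smoothed value is
missing if any window member is missing, and a pixel with fewer than three
valid months cannot be detrended and becomes missing.

The deforestation filter aggregates a fine-resolution binary loss raster
onto the analysis grid; under the default `"any"` rule one fine loss pixel
excludes the whole coarse cell (the conservative reading of "filter out all
potentially compromised pixels"), with a `fraction > tau` alternative. The
filter applies to the GPP layers only by default — the productivity signal
is what deforestation corrupts — and is configurable. Grid registration
between cubes and masks is checked, never resampled.

## Correlation maps

For a pixel and phase, the sample Pearson correlation is computed between
the smoothed index at the phase months and the pixel's anomaly series
shifted by the lag (positive lag: the field responds *after* the index;
months whose lagged partner leaves the record are dropped). Significance is
the two-sided p-value of `t = r sqrt((n-2)/(1-r^2))`, masked at a strict
`p < 0.05`. Choices worth knowing:

* **`min_n = 8`** phase months are required for a defined correlation;
  below that the pixel is undefined (NA), not an error. The t transform
  needs n > 2; eight guards against absurd fits when an ENSO phase is rare
  in a short record.
* **Zero-variance input is undefined, not zero.** A noise-free pixel with
  no teleconnection has no anomaly variance; reporting r = 0 would fake a
  measurement.
* **No multiple-testing correction** is applied, matching the per-pixel
  p < 0.05 mapping convention of this literature.
* **Serial correlation.** The 3-month smoothing makes consecutive months
  dependent, so nominal p-values on smoothed series are anticonservative
  (the effective sample size is roughly halved for 3-point running means of
  white noise). We follow the field's practice of reporting nominal
  p-values by default, and expose a Bretherton-style correction
  (`use_neff = TRUE`), which deflates n by
  `(1 - a1x a1y)/(1 + a1x a1y)` using the lag-1 autocorrelations. The
  significance-calibration test therefore runs on detrended *unsmoothed*
  anomalies (`require_smoothed = FALSE`), where the t-test is exact: on a
  40×40 null grid over 348 months the observed false-positive rate sits
  inside the 99% binomial band around 0.05. On smoothed series the same
  check would measure the smoothing bias, not the test.

The ONI itself is smoothed but not detrended or anomalized (its published
form already is an anomaly); consequently, even a noise-free teleconnected
pixel correlates with the smoothed index at slightly less than |r| = 1,
because the field's copy of the index has additionally passed through the
anomaly/detrend steps. Against the index processed by the same linear
chain the correlation is exactly ±1, which is how the noise-free tests are
written.

## Exposure: the Entropy Weight Method

Per phase, the six climate variables' significant |r| values form the
`m × n` signal matrix X over the retained pixel domain. The chain is
`P = X / rowSums(X)`, `E_i = -(1/ln n) Σ_j P_ij ln P_ij` (with
`0·ln 0 := 0`), `d_i = 1 - E_i`, `w_i = d_i / Σ d_i`,
`exp_j = Σ_i w_i X_ij`. Lower entropy means a spatially more concentrated
teleconnection and hence a higher weight. Open points we had to fix:

* **Retention rule.** "Only pixels with significant correlations were
  retained" does not say whether all six variables must be significant. We
  retain the *union* (at least one variable significant; non-significant
  entries contribute X = 0), which keeps the domain non-degenerate;
  `retention = "intersection"` is available.
* **Scale of the final index.** The weight formula uses X, and the index
  is described as ranging over [0, 1]; raw |r| sums do not guarantee that.
  We min–max scale |r| per variable over the domain before the weighted
  sum, so `exp_j ∈ [0, 1]` by construction. This choice is prominent here
  because it changes the index's absolute values (not its ordering within
  a variable).
* **Stress directionality** (drought- vs wetness-stress) is carried as a
  separate sign table for map colouring and never multiplied into the
  magnitude, so opposite-signed stresses cannot cancel.
* A variable that is significant nowhere has an all-zero row, cannot be
  normalized, and is dropped with a warning; a domain of fewer than two
  pixels is rejected (`k = 1/ln n` is undefined at n = 1); all entropies
  equal to 1 leave no weighting information and raise an error.

The bundled reference table (`ewm_reference_table()`) carries four
published crop × phase entropy/weight blocks; recomputing the weights from
the entropies reproduces the published values to one unit in the fourth
decimal — the published entropies are themselves rounded to 4 decimals, so
exact 4-dp equality is not attainable for every entry (observed maximum
deviation ≈ 6e-5, two of 24 entries land on the other side of the rounding
boundary).

## Sensitivity typology

Significant GPP correlations become productivity directions: under El Niño
`+1` for positive r, under La Niña the sign flips (a positive correlation
with an index that is dropping means productivity falls). The sun/shade
direction pair maps to four classes: both increase `(+1,+1)`, both
decrease `(-1,-1)`, sun-only decrease (sun −1, shade not decreased),
shade-only decrease (mirror). Pixels with one positive direction and no
negative one carry no stress signal and no joint increase; they are left
unclassified (`none`) and documented as such. Area percentages use all
masked pixels as the denominator, so the four signal classes need not sum
to 100% — with `none` they do.

## Lag analysis

Lag profiles summarise the pixel-wise r distribution (median, quartiles,
1.5·IQR whiskers, count) per lag in −3..+3 over all masked pixels with
defined r — not only significant ones, matching how such boxplots are
drawn. Transition detection scans for the earliest consecutive lag pair
where the median changes sign (landing on exactly 0 counts as a change);
when no sign change exists the conventional default pair (−1, 0) is
returned and flagged as not detected. Magnitude-only "clear changes" are
not automated — there is no defensible threshold — but any pair can be
passed to `transition_map()` manually. The transition map classes pixels
that are non-significant at the first lag and significant at the second by
their direction at the second lag, phase-aware as above.

## The synthetic generator

`sim_config()` describes one cube tied to an AR(1) index:
`x_t = φ x_{t-1} + ε_t`. Defaults are the packaged study conditions,
chosen once: 348 months (29 years, the span of the motivating record),
φ = 0.9 and innovation sd 0.25 °C, giving a stationary sd ≈ 0.57 °C so
multi-month ±0.5 °C episodes occur with realistic frequency; fields are
`climatology(month) + 0.002·t + β·index[t − lag] + N(0, 0.5²)` on a 20×20
grid. The climatology is a fixed 12-value sinusoid (amplitude 1) unless a
table is supplied — deliberately non-flat so the anomaly step is a real
operation. One root seed drives deterministic per-component substreams
(`derive_seed()`), so adding a variable never perturbs the others and equal
configs give bit-identical output.

What the generator emulates: the additive linear teleconnection structure,
per-pixel response lags, seasonal cycle, linear trends, masks, and a
sun/shade pair with independent β fields able to construct every typology
quadrant. What it does not emulate: spatial covariance of real climate
fields (noise is independent per pixel), ENSO's spectral asymmetries beyond
AR(1), non-linear or saturating vegetation responses, and observational
error structure. Passing tests therefore demonstrate the *methods* are
correct and calibrated on data satisfying their assumptions — not that
real-world teleconnection estimates are unbiased.

## Test problem sizes

The suite exercises full 348-month records on grids from 4×4 (exact
hand-checkable cases) through 24×24 (signed-block parameter recovery) to
40×40 (null calibration, 1600 pixels), and 1000-replicate property loops
for the Pearson kernel and EWM invariants; these sizes make every
distributional check well-resolved while the whole suite runs in well
under a minute. Continental-scale inputs (≈4 km grids over Latin America)
are deliberately out of scope for the tests: those results depend on
external observational archives, and the desk-scale synthetic conditions
are the controlled stand-in.

## Known limitations

* Nominal p-values on smoothed series are anticonservative (see above);
  users mapping smoothed-data significance should consider `use_neff`.
* The EWM weights depend on the significance mask, so they inherit any
  miscalibration of the per-pixel test.
* Phase-conditional correlations use the index's within-phase variance,
  which is small by construction; power is correspondingly lower than for
  full-series correlations, and `min_n` truncates rare-phase records.
* No reprojection: inputs must share a grid; only the fine→coarse loss
  aggregation resamples.
* I/O uses a plain-text interchange (CSV payload + JSON sidecar) rather
  than NetCDF/GeoTIFF containers; the sidecar carries the geotransform and
  time axis so round trips are lossless.
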