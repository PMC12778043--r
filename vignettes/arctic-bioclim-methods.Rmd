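---
title: "Methods: bioclimatic indicators and change analysis on gridded daily weather"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bioclimatic indicators and change analysis on gridded daily weather}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcbioclim)
```

`arcbioclim` turns daily gridded weather into annual bioclimatic
indicators and a set of change analyses: pixel-wise nonparametric trends,
climate clusters, area-weighted event coverage, newly emerging event
regimes, and a bivariate synthesis of significant change. This vignette
is the package's own account of the science: what each stage assumes,
which parameters matter, what the synthetic generator does and does not
emulate, and where design choices were genuinely open.

## The indicator set

All indicators are computed per pixel from daily series (the summer
warmth index from monthly means). Comparison conventions follow the
standard definitions exactly and deliberately mix strict and inclusive
thresholds, because that is how the indicators are defined in the
literature this package operationalizes:

* **GSL** — length of the *longest run* of days with daily mean
  temperature at or above 5 °C. "The period when temperature stays at or
  over the threshold" is not by itself an algorithm; the longest
  continuous run is adopted because it matches the convention the snow
  season length uses ("longest continuous period"), and the threshold
  comparison is inclusive. A persistence-rule variant (e.g. first/last
  5-day spell) would change season edges by a few days; it is left as an
  extension and the threshold is configurable.
* **GDD** — `sum(max(T - 5, 0))` over growing-season days. Reading "sum
  of temperatures which exceed the threshold" as a sum of raw
  temperatures would not yield °C days; the exceedance sum is the
  growing-degree-day convention. Exceedance is strict: a day at exactly
  5 °C contributes nothing.
* **FGS** — signed sum of sub-freezing daily minimum *skin* temperatures
  over growing-season days (≤ 0). Stored negative; coverage rules and
  magnitude plots use the absolute value.
* **FDD** — signed sum `sum(min(T, 0))` over the hydrological year
  (≤ 0). Because the accounting window contains one whole winter, no
  separate "winter season" definition is needed: summer days contribute
  zero.
* **SSL** — longest continuous snow-covered run in the hydrological
  year. A cell counts as snow covered when snow depth ≥ 0.01 m
  (configurable); "snow-covered grid cell" needs an operational depth
  and 1 cm of snow is a common remote-sensing detection limit.
* **SWI** — sum of monthly mean temperatures strictly above 0 °C.
* **ROS** — days with liquid precipitation strictly greater than 5 mm
  while snow covered. No seasonal window is applied: the snow-cover
  requirement already restricts occurrences to the snow season.
* **WWE** — days with daily mean temperature at or above 2 °C
  (inclusive) on snow cover, inside November–April.
* **HWMI / VPDI** — the cumulative magnitude of the strongest warm-season
  event, in the Russo family of heatwave magnitude indices: (i) for each
  day of year, a threshold equal to the 90th percentile of the variable
  pooled over a ±15-day window across the reference years; (ii) an event
  is ≥ 3 consecutive May–September days strictly above threshold;
  (iii) each event day contributes `max(0, (x - Q25) / (Q75 - Q25))`,
  where the quartiles are those of the reference years' annual maxima;
  (iv) the year's index is the largest event sum, 0 if no event. VPDI
  applies the same construction to vapour pressure deficit,
  `e_s(T) - e_s(T_dew)` with Magnus coefficients (17.625, 243.04 °C), in
  kPa. The reference period defaults to the first 30 data years and is
  configurable; published gridded products do not always document their
  exact variant, so any divergence from a specific atlas is a known
  limitation rather than a bug.
* **HWE** — days with daily maximum wind strictly above the pixel's own
  90th percentile, computed from the pixel's full-period daily
  distribution (the reference window is not standardized anywhere; the
  full period is the least arbitrary choice and gives a long-term mean
  of ≈ 36.5 events/yr by construction).

**Accounting years.** Winter-centred indicators (FDD, SSL, ROS, WWE) are
computed on a hydrological year (default July 1 – June 30, labelled by
the January year) so a single winter is never split across two labels;
the remaining indicators use the calendar year. The first data year has
no complete hydrological year and its four winter indicators are missing
rather than computed on a truncated window. Masked (ocean/ice) pixels
are missing, never zero.

**Degenerate references.** If the reference-period annual maxima have
zero inter-quartile range (possible only for tiny reference periods or
constant series), the magnitude index raises an error; a configurable
epsilon can replace the range, with a warning, for exploratory runs.

## Trend machinery

Sen's slope is the median of all pairwise slopes; the Mann-Kendall S
statistic uses the tie-corrected variance and a ±1 continuity correction
in the normal deviate, with an exact enumeration mode for n ≤ 7. No
pre-whitening is applied — the plain test is what raster trend mapping
conventionally uses — so serial correlation in input series inflates the
false-positive rate; on the synthetic data, whose annual values are
nearly independent, the empirical size stays near the nominal 5 %.
Missing years are dropped pairwise. Pixels with fewer than three valid
years report missing trends. Fractional-area and regional series use
ordinary least squares with a t-test on the slope, matching the
convention for area trends.

Regional anomaly series subtract the baseline-period mean (default
1951–1980 where the span allows) and smooth with a centred moving
average whose window shrinks symmetrically at the series ends — the
least-surprising edge rule when none is prescribed. Regional means are
area-weighted by default because every other spatial statistic in the
package accounts for cell area; an unweighted flag exists because
cluster-average plots in the literature may be plain pixel means.

Fold changes of event-area series are measured on the fitted
least-squares line (value at the last year over value at the first
year), which is robust to single-year noise at the endpoints; when the
fitted line starts at or below zero area the ratio is meaningless and
reported as missing.

## Climate classification

Features are per-pixel climatologies over a configurable period (default
1991–2020): mean annual temperature, mean annual precipitation sum, and
the annual maximum monthly-mean temperature difference. The range is
computed within each year and then averaged; computing it from the
long-term monthly climatology instead (a flag) gives slightly smaller
values because year-to-year phase shifts average out. Features are
Gaussian-normalized over land pixels so each carries similar weight, and
clustered with standard KMeans (`stats::kmeans`, 10 restarts, fixed
recorded seed). Cluster numbering is the algorithm's arbitrary order, so
all evaluation in the tests uses the adjusted Rand index, which is
invariant to relabelling.

## Area accounting, novelty, synthesis

Cell areas use the exact spherical formula
`R² Δλ (sin φ_top − sin φ_bot)` with R = 6371 km, so northern rows count
for less, and band sums match the closed form to rounding error. One
rule table drives both the coverage series and the novelty masks:
HWMI ≥ 3, VPDI ≥ 3, ROS > 0, WWE > 0, FGS > 0 in magnitude, and
HWE ≥ the pixel's 90th percentile of its own annual series. A pixel is a
"new" regime when the rule never held in the baseline window and held at
least once in the modern window; "past" is the reverse; pixels with no
valid data in either window leave the denominator entirely.

The synthesis compares the two 30-year windows per pixel and variable
with a two-sided Welch t-test (a pooled-variance flag exists; unequal
variances are the safer default when one window is systematically more
variable). P-values are recoded to 1 (p ≤ 0.05) or 0 and averaged within
the seasonal set {GDD, FDD, SSL, SWI} and the event set {FGS, ROS, WWE,
HWMI, VPDI, HWE}, so the proportions are quantized to quarters and
sixths. The count indicators are zero-inflated and discrete; the t-test
is applied to them regardless — faithfully to the convention this
package follows — which can only make it conservative where counts are
mostly zero, and that caveat matters when interpreting "no significant
change" for rare events. When both samples have zero variance the
statistic is undefined; equal means report p = 1 and differing means
p = 0. The bivariate colour map composes the two proportions on two
orthogonal ramps, and the hotspot contour marks pixels where both
proportions reach 0.5.

## The synthetic generator

The generator emulates a reanalysis-style daily product: a latitudinal
mean-temperature gradient (default 2 °C at 60 °N, −0.8 °C per degree
northward), a seasonal cosine (amplitude 15 °C, peak at day 200), AR(1)
daily noise (coefficient 0.7, marginal sd 3 °C), optional linear warming
plus an optional extra recent trend, Bernoulli-gamma precipitation (wet
probability 0.35, shape 0.7, scale 4 mm) split into rain and snow at
1 °C, a degree-day snowpack (3 mm w.e. per °C day, density
100 kg m⁻³), Weibull daily maximum wind (shape 2, scale 7 m s⁻¹), and a
non-negative dewpoint depression (mean 2 °C). These defaults were chosen
once as a plausible maritime-to-continental subarctic gradient in which
every indicator is active — snow seasons of a few months, growing
seasons of two to four months, occasional rain-on-snow and winter-warm
days — and they are not calibrated to any particular dataset. Each
variable draws from its own seeded RNG stream, so adding a variable
never perturbs the others and every run is bit-reproducible.

The calendar has 365 days with no leap years, which keeps day-of-year
climatology windows aligned across years (the seasonal cosine therefore
uses a 365-day period); real products have leap days and derive daily
fields from hourly data, neither of which is emulated. There is no
spatial correlation in the noise, no physically based snow energy
balance, no orography, and no real geography — so passing tests show
that the *machinery* is correct and well-calibrated under known forcing,
not that any particular real-world magnitude is reproduced.

Scenario presets encode the study designs used in the tests:
`stationary` (all forcing off), `warming` (trend, optionally
accelerating after a split year), `step_change` (a constant offset after
the split year, optionally restricted to a pixel block and combined with
precipitation scaling, a wind offset, and a skin-temperature offset),
and `event_injection` (all precipitation falls as snow so rain-on-snow
can occur only at explicitly injected warm, rainy, snow-covered days;
injections sit in January–March so calendar and hydrological year labels
agree). The step scenario's power design is worth spelling out: a
uniform warm step barely moves growing-season frost, because the season
is *defined* by days above 5 °C and therefore self-selects a similar
within-season temperature distribution before and after the step, and it
moves rain-on-snow in two opposing ways (more rain, less snow). A step
that is meant to shift *every* indicator therefore also perturbs the
skin-temperature offset (as would, e.g., reduced snow insulation) and
scales precipitation; the designed strong-forcing scenario uses
+4 °C, ×2 precipitation, +4 m s⁻¹ wind and −4 °C skin temperature.

## Problem sizes and numerics

The test suite and the acceptance script run the full machinery at
deliberately modest sizes chosen to exercise every code path with
comfortable statistical power: 73-year runs on 6×6 to 10×10 one-degree
grids for scenario-level checks, 5×5 × 3 years for the exact
engine-versus-oracle comparison, 1,000 fuzzed series for the Sen-slope
oracle and 2,000 for the Mann-Kendall size check. Counts and run lengths
are compared exactly; accumulated sums and indices to 10⁻⁹ relative;
spherical areas to closed forms at 10⁻⁴ relative or better. Statistical
properties (test size, trend-sign fractions, novelty symmetry) use
three-sigma binomial bands around their expectations.

## Known limitations

* The heatwave/VPD magnitude construction is one published variant of a
  family; gridded atlases do not always document theirs, so absolute
  index values are comparable only within a configuration.
* No pre-whitening in the Mann-Kendall test and no field-significance or
  false-discovery control across pixels; significance masks are
  per-pixel statements.
* The t-test on zero-inflated counts is conservative for rare events.
* The plain-text dataset format (a directory of `meta.json` plus one CSV
  matrix per variable) favours transparency and diffability over
  compactness; it is not intended for continent-scale archives.
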