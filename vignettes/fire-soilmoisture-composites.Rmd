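---
title: "Superposed-epoch composites of soil-moisture anomalies around large wildfires"
author: "firecomposite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superposed-epoch composites of soil-moisture anomalies around large wildfires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firecomposite)
```

## The analysis

Soil moisture controls wildfire hazard through two pathways: it governs
vegetation growth — and hence the accumulation of fuel — and it sets the
moisture content, and hence the flammability, of that vegetation. This
package implements an observational, event-based way of quantifying both
pathways from gridded satellite-style data.

The unit of analysis is the *largest local fire*: in every grid cell of a
regular latitude–longitude grid, the calendar month with the highest burned
area on record. Around each such event, monthly soil-moisture (and
temperature and vegetation-optical-depth) anomalies are extracted at whole-
month lags relative to the event month (lag 0), and composited across
events with medians and interquartile ranges — a superposed-epoch analysis.
Events are grouped by climate: cells are placed in long-term temperature ×
aridity boxes, and split into humid (aridity ≤ 2) and arid (aridity > 2)
regimes. The expectation under the two-pathway model is a contrast between
regimes: wet anomalies several months ahead of the fire where water limits
fuel growth (arid), dry anomalies shortly before the fire where ignition
conditions limit fire (humid).

### Anomalies

All variables are reduced to month-of-year z-scores. With a reference
period of $Y$ years, each cell's monthly climatology is

$$\bar{x}_{m} = \frac{1}{n_m}\sum_{y} x_{y,m}, \qquad
  s_{m} = \sqrt{\frac{1}{n_m - 1}\sum_{y}\left(x_{y,m}-\bar{x}_{m}\right)^2},$$

over the valid years $y$ of month-of-year $m$, and the anomaly is
$z_{y,m} = (x_{y,m} - \bar{x}_m)/s_m$. The reference statistics use the
sample ($n-1$) denominator; with 18 reference years the difference from the
population denominator is about 3%, and the choice is configurable through
`monthly_climatology()`. Cells with fewer than two valid years for a
month-of-year, or zero variance, are masked rather than producing infinite
z-scores. The event month itself is *not* excluded from the climatology —
the climatology is the plain multi-year statistic — which induces a mild
self-influence of order $1/Y$ on recovered event anomalies.

Daily inputs (soil moisture, vegetation optical depth) are first averaged
to monthly means; a month with fewer than 15 valid days is treated as
missing. The aggregation weights all valid days equally. Fields on other
grids are regridded by cell-averaging when coarsening and by
nearest-source-cell lookup when refining (the population layer's 0.5° →
0.25° direction is a refinement).

### Event sampling and filters

`select_largest_events()` excludes months with an observed-area fraction at
or below 80% from the maximisation (the record-level reading of the
quality rule: a poorly observed month is dropped, not the whole cell), then
takes the per-cell argmax of burned area, breaking exact ties toward the
earliest month so results are deterministic. Cells whose admissible months
never burn yield no event.

`filter_events()` then applies three conjunctive conditions:

* **window completeness** — every monthly soil-moisture anomaly from 5
  months before to 1 month after the event must be present (a window
  extending outside the record fails this condition);
* **temperature** — the cell's long-term mean 2 m temperature must be at
  least 0 °C, excluding freezing-affected retrievals;
* **population** — the cell's population density must lie strictly below
  the 25th percentile of density over *all* cells with soil-moisture data
  (not only event cells), isolating near-natural fire behaviour.

Survival is order-independent; the per-stage removal counts in the filter
report attribute each lost event to its first failing condition in the
order window → temperature → population, so the counts always sum to the
number of candidates.

### Climate classification

The aridity index is the ratio of the period-mean net radiation, expressed
as an equivalent evaporation depth, to the period-mean precipitation.
Net radiation in W m⁻² converts to mm day⁻¹ of evaporation as
$E = R_n \cdot 86400 / \lambda$ with $\lambda = 2.45\times10^6$ J kg⁻¹
(1 kg of water per m² is a 1 mm depth). λ is held fixed at its ~20 °C
value rather than made temperature-dependent; it is a configurable
constant. Cells are binned half-open `[lower, upper)` on long-term mean
temperature and aridity; values outside the configured edges are clamped
into the outermost bins and counted. Boxes with fewer than 25 member cells
are discarded from compositing. The humid/arid boundary at aridity 2 is
kept as a mandatory bin edge. The specific default edges (temperature 0–30
°C in 5 °C steps; aridity 0.5, 1, 2, 4, 8) are a package choice — any
exhaustive edges containing the value 2 are accepted.

### Significance

Observed composite medians are compared against a Monte-Carlo null built
by month resampling: each event's month is replaced by a random month with
month-of-year within ±1 of the event's (December wraps to January and vice
versa, crossing calendar years) drawn from a *different* year, uniformly
over all admissible record months. The identical composite statistic is
recomputed; over 1,000 repetitions the per-cell empirical 5th–95th
percentiles form the null band, and an observed median strictly outside
the band is flagged significant at the two-sided 90% level. Exact equality
with a band edge is *not* significant. No multiple-testing correction is
applied across boxes; flags are per-cell.

Resampling design choices: each repetition draws one admissible month per
event, independently across events and repetitions (draws with
replacement across repetitions); months are not otherwise screened for
burned area — the only exclusion rule is the different-year requirement,
with an optional burned-area screen deliberately left out of the default
because the admissibility rule is the explicit one. All draws come from a
single seeded RNG stream, pre-drawn in one vectorised block per event, so
a fixed seed makes bands bit-reproducible; per-repetition substreams were
not needed at these problem sizes.

## The synthetic-scene generator

`generate_scene()` produces every input the pipeline consumes, with a
truth record, so the full analysis is testable without downloading any
satellite product. Per cell, monthly soil moisture is

$$x_t = b + A\sin\!\left(\tfrac{2\pi (m_t + \phi)}{12}\right) + \sigma z_t,$$

with baseline $b \sim U(0.15, 0.35)$ m³ m⁻³, seasonal amplitude $A = 0.08$,
anomaly scale $\sigma = 0.04$, and $z_t$ a standardised AR(1) series with
lag-1 coefficient 0.5 — persistence comparable to monthly surface
soil-moisture memory without tuning to any particular product. Daily values
add white observation noise (sd 0.01) around the month's value, are clipped
to [0, 1], and are removed independently with the configured gap
probability (clustered orbital gaps are out of scope). The
vegetation-optical-depth proxy follows the same recipe on a 0.4–0.9
baseline. Temperature cell means are uniform on −2…28 °C, so a realistic
minority of cells is removed by the 0 °C filter.

The fire-preceding signal is injected *in z-space*: the configured profile
is added to $z_t$ at lags −L…0 before each designated burn month, then
mapped into physical units through the same $b + A\sin(\cdot) + \sigma z$
construction, so a correct z-score implementation recovers the injected
profile up to (i) sampling noise of the median and (ii) the $O(1/Y)$
climatology self-influence. Burned-area fractions for events follow a
Pareto law with tail index 1.5 (heavy-tailed, like observed fire-size
distributions), capped at 0.95, and strictly exceed all background burning
of the cell; the event month's observed fraction is forced to 1 so the
truth record stays the admissible argmax, while other months draw observed
fractions of $1 - p_{\rm gap} U(0,1)$ to exercise the 80% rule.
Precipitation and net radiation are generated jointly from a per-cell
target aridity drawn on 0.6–1.8 (humid) or 2.5–6 (arid), so computed
aridity straddles the regime boundary 2 by construction. Population
density is lognormal with meanlog 1.87 and sdlog 2 — heavy-tailed, with a
25th percentile near 1.7 people km⁻² as for the real gridded population
of the world. The default full scene uses a 24×24 grid over 2001–2018
with 500 fire cells; `scene_config()`'s 20×20 default shape suits smaller
runs (300 fire cells).

What the generator does *not* emulate: spatial correlation of anomalies
across cells, orbit-geometry gap clustering, sensor changes over the
record, multi-sensor merging artefacts, and seasonally varying fire
likelihood. Passing tests therefore demonstrate the statistical machinery
— anomaly normalisation, sampling, filtering, compositing, calibration of
the resampling null — on data with the assumed marginal structure, not the
fidelity of any geophysical retrieval.

## Numerical conventions

* One quantile definition everywhere: linear interpolation between order
  statistics (R type 7) for medians, interquartile bounds, the population
  threshold and the null-band percentiles.
* Ties in the burned-area maximum break to the earliest month.
* Binning is half-open `[lower, upper)`; the top bin of explicit
  stratification edges closes at the maximum so boundary events are kept.
* Masked values propagate: an event lag outside the record is a masked
  matrix entry, an all-masked lag yields masked composite statistics, and
  a masked composite cell yields a masked band and flag.
* `sd = 0` or `n < 2` climatology cells are masked before division can
  occur; `normalize_anomaly()` treats an unmasked zero sd as an internal
  contract violation.

## Problem sizes and calibration

The test suite and the acceptance script run entirely on synthetic scenes
chosen to make Monte-Carlo checks statistically meaningful at desk scale:
null-calibration uses 20×20-cell, 18-year scenes with 400 fire cells
(~95 events survive the full filter cascade) over 25 scene repetitions
with 1,000-resample bands, giving ~100 composite cells for the coverage
estimate; signal recovery uses 24×24 all-arid scenes with 500 injected
events, where the median's sampling error is ≈0.06 z-units per scene, so
recovery of the injected profile within ±0.1 is assessed on the mean of
the composite medians across five seeded scenes (sampling error ≈0.03)
while significance flags are checked per scene. With the single coverage
run one should expect the non-rejection rate to differ from the nominal
90% by a few points (binomial sd ≈ 3 points at 100 cells).

## Known limitations

* The population filter keeps only the sparsest quartile of cells, so
  retained event counts are roughly a quarter of the injected fire cells;
  composites on small scenes can end up with discarded boxes.
* The climatology includes the event month (no leave-one-out option yet),
  biasing recovered event anomalies toward zero by ~$1/Y$.
* The resampling null treats events as independent; spatially clustered
  real fires would violate that and make the band anti-conservative.
* `write_scene()`/`read_scene()` require the optional ncdf4 package; the
  in-memory pipeline and the TSV outputs have no such dependency.
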