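# firecomposite

Superposed-epoch analysis of soil-moisture and biomass anomalies preceding
large wildfires on gridded satellite-style data.

Soil moisture shapes wildfire hazard twice over: it drives vegetation
growth (fuel accumulation) and it sets vegetation moisture content
(flammability). `firecomposite` quantifies both pathways observationally.
In every grid cell it samples the month with the largest burned area on
record, converts the surrounding soil-moisture, temperature and
vegetation-optical-depth time series into month-of-year z-score anomalies

    z(y, m) = (x(y, m) − mean_m) / sd_m,

extracts them at whole-month lags around the event (lag 0 = fire month),
and composites medians and interquartile ranges across events grouped by
climate — long-term temperature × aridity boxes, and a humid (aridity ≤ 2)
versus arid (aridity > 2) split, where aridity is period-mean net
radiation expressed as equivalent evaporation divided by period-mean
precipitation. Significance comes from a Monte-Carlo null: each event
month is replaced by a random same-season (month-of-year ± 1,
December/January wrapping) month from a different year, the composite is
recomputed 1,000 times, and observed medians outside the empirical
5th–95th percentile band are flagged (two-sided 90% level).

Events pass a filter cascade before compositing: months with less than
80% observed area are excluded from the burned-area maximisation; events
need a complete soil-moisture anomaly window from 5 months before to
1 month after the fire; cells with long-term mean temperature below 0 °C
are dropped (freezing-affected retrievals); and only cells with population
density below the 25th percentile of all soil-moisture-covered cells are
kept, to isolate near-natural fire behaviour.

The package is aimed at ecohydrologists and fire scientists who want to
run this event-composite methodology on their own gridded products (any
NetCDF fields on a regular latitude-longitude grid) or study its
statistical behaviour. A built-in synthetic-scene generator with a truth
record emulates the statistical structure of the satellite inputs —
seasonal cycles, AR(1) anomaly persistence, daily observation gaps,
heavy-tailed burned areas and population densities, humid/arid contrast —
so the whole pipeline runs and is tested without any data download.

## Worked example

Generate a synthetic scene whose fire cells carry a wet-to-dry
soil-moisture profile (z = +0.5 five months before the fire, falling to
−0.6 in the fire month), then run the full analysis:

```r
library(firecomposite)

cfg <- scene_config(grid_shape = c(24L, 24L), n_fire_cells = 500L,
                    signal_profile = c(0.5, 0.3, 0, -0.3, -0.5, -0.6),
                    humid_fraction = 0.5, rng_seed = 42L)
scene <- generate_scene(cfg)
res <- run_pipeline(scene, list(temp_edges = c(0, 15, 30),
                                aridity_edges = c(0.5, 2, 8)))
print(res)
#> <fc_result>
#>                stage count
#>           candidates   500
#>       removed_window     0
#>  removed_temperature    31
#>   removed_population   353
#>             retained   116
#>       boxes_retained     3
#>      boxes_discarded     1
#>         events_humid    57
#>          events_arid    59
```

All 500 injected fire cells become candidate events; 31 sit in cells
colder than 0 °C, 353 fail the sparsely-populated cut (by construction the
population filter keeps about a quarter of cells), and 116 events remain,
split across the aridity-2 boundary. Per-box composites at the 5-month
lead, with the resampling band and significance flags:

```r
subset(res$box_table, lag == -5)
#>  box temp_lo temp_hi aridity_lo aridity_hi lag median  n  lower upper significant
#>    2      15      30        0.5          2  -5  0.825 34 -0.376 0.348        TRUE
#>    3       0      15        2.0          8  -5  0.727 34 -0.357 0.303        TRUE
#>    4      15      30        2.0          8  -5  0.432 25 -0.452 0.382        TRUE
```

Every retained box shows the injected wet anomaly at lag −5 (medians
0.43–0.83, well above the null band upper bounds of ≈0.3–0.4). The
temporal evolution for arid-regime events:

```r
res$evolution$soil_moisture.arid[, c("lag", "median", "q25", "q75", "n", "significant")]
#>  lag   median    q25     q75  n significant
#>   -5  0.62334  0.141  1.0597 59        TRUE
#>   -4  0.32303 -0.345  1.0084 59        TRUE
#>   -3  0.04670 -0.573  0.7257 59       FALSE
#>   -2 -0.00323 -0.695  0.7061 59       FALSE
#>   -1 -0.52763 -1.267  0.4989 59        TRUE
#>    0 -0.91191 -1.489 -0.0248 59        TRUE
#>    1  0.03582 -0.869  0.6911 59       FALSE
```

The composite median tracks the injected profile — significantly wet at
long lead, decaying through zero, significantly dry at and just before
the fire month — and recovers toward normal one month after. (The fire
month itself shows the injected −0.6 plus median sampling noise; the
climatology's inclusion of the event month biases recovered anomalies
slightly toward zero.)

`write_result(res, "out/")` writes the box table, regime evolutions,
filtered events and a run report as tab-separated files, and
`write_scene(scene, "scene/")` exports a scene as CF-style NetCDF plus a
truth table. A thin command-line wrapper for both steps is installed at
`inst/cli/firecomposite.R` (`simulate` and `run` subcommands).

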