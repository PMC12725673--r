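# vccr — virtual catch change reconstruction from LEK surveys

Most small-scale coastal fisheries have no catch time series: monitoring
started late or never, so nobody can say from records how catches or
fishing grounds have changed since the fleets formed. The fishers
themselves, however, have been observing those waters for decades.
`vccr` turns structured local-ecological-knowledge (LEK) interviews into
quantitative reconstructions of decadal catch and effort dynamics. It is
aimed at fisheries scientists and survey teams working in data-poor
settings who elicit, per fisher and per decade, a categorical catch-trend
score with a self-assigned percentage, plus hand-drawn fishing-ground
polygons.

## The model

Each fisher rates each active decade with one of five scores — major
decline (MD), decline (D), stable (S), increase (I), major increase
(MI) — and a percentage *Y* saying what the category means to them. The
pair becomes a signed fraction *f<sub>k</sub>* = sign(*Z<sub>k</sub>*) ·
*Y<sub>k</sub>* / 100, and the fisher's **virtual catch change** (VCC)
index cascades multiplicatively from a pre-1980s baseline of 1:

> *V<sub>k</sub>* = *X<sub>k−1</sub>* + *X<sub>k−1</sub>* ·
> *f<sub>k</sub>* &nbsp;&nbsp; (stable keeps the prior value, declines
> subtract a percentage of it, increases add one)

Fishers who entered after the 1980s are anchored not at 1 but at the
**cohort mean** of the preceding decade — the shifting-baseline
correction, which stops late entrants from treating an already-depleted
state as normal. Trajectories are aggregated into decadal means ± sd,
compared via relative change 100 (*V*<sub>new</sub> −
*V*<sub>ref</sub>) / *V*<sub>ref</sub>, and summarised with a cubic
trend line.

Around the core model the package provides the survey's sampling-design
calculator (Yamane *n* = *N* / (1 + *N e*²) aggregated across
population sources), rasterization of fishing-ground polygons into
normalized effort and VCC surfaces on a 0.01° grid, geodesic
centroid-to-port distance summaries, and a synthetic survey generator
with recorded ground truth for testing the whole pipeline.

## Worked example

Sampling design — how many interviews does a village with four
conflicting fisher counts need at ±10% precision?

```r
library(vccr)
aggregate_sampling_effort(
  tibble::tibble(village = "Cojimies", N = c(451, 724, 388, 700)))
#> # A tibble: 1 × 5
#>   village  n_sources mean_n min_n max_n
#> 1 Cojimies         4     84    80    88
```

Target 84 interviews, with an 80–88 band reflecting source
disagreement. A full survey, end to end, on synthetic data:

```r
s <- generate_survey(survey_config(n_villages = 4,
                                   fishers_per_village = 50), seed = 7)
run <- run_pipeline(s$interviews, s$grounds, s$ports, cellsize = 0.05)
run
#> VCC reconstruction run
#>   retained interviews: 158 of 200 contacted
#>   decadal means: 1980s=1.136, 1990s=1.297, 2000s=1.189, 2010s=0.691
#>   mean distance to port (km): 1980s=25.3, 1990s=30.3, 2000s=43.0, 2010s=55.4

run$aggregate
#> # A tibble: 4 × 4
#>   decade  mean    sd     n
#> 1 1980s  1.14  0.210    50
#> 2 1990s  1.30  0.383    89
#> 3 2000s  1.19  0.507   126
#> 4 2010s  0.691 0.394   158
```

The decadal means trace the rise-then-collapse parabola the score
distributions encode: catches a third above baseline by the 1990s, then
31% below baseline in the 2010s, while mean distance to port more than
doubles — fishers travelling farther for less. `n` grows over decades
because later decades include more active careers. The trend object
supports broom-style accessors:

```r
tidy(run$trend)
#> # A tibble: 4 × 5
#>   term  estimate std.error statistic p.value
#> 1 b0      0.998    0.0206      48.5   0.0131
#> 2 b1      0.0849   0.0523       1.62  0.352
#> 3 b2      0.0982   0.0332       2.96  0.208
#> 4 b3     -0.0347   0.00546     -6.35  0.0994
```

`autoplot(run$aggregate)` draws the trend figure;
`autoplot(run$effort)` and `autoplot(run$vcc_surfaces[["2010s"]])` map
where fishing concentrates and where perceived change is positive or
negative; `export_summary(run, "out/")` writes the CSV/JSON/ASCII-grid
bundle with a digest manifest.

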