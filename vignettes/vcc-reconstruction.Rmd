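---
title: "Reconstructing artisanal catch and effort trends from LEK interviews"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing artisanal catch and effort trends from LEK interviews}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vccr)
library(dplyr)
```

Many artisanal fisheries have never had a monitoring program, so there is
no time series to say how catches or fishing grounds have changed since
fleets formed. When logbooks are absent, the fishers themselves are the
longest-running observers available. `vccr` implements a semi-quantitative
reconstruction of decadal catch and effort dynamics from structured
local-ecological-knowledge (LEK) interviews, built around Ecuador's
coastal small-scale fleet but applicable to any fishery surveyed in the
same design: per-decade categorical catch-trend scores with
fisher-assigned percentages, participatory maps of fishing grounds per
decade, and a finite-population sampling design.

This vignette is the package's account of the model, its assumptions, the
tunable parameters, and the choices made where the design was genuinely
open. Everything quantitative shown here is computed by the package at
build or test time; nothing is asserted that the test-suite does not
itself compute.

## The virtual catch change model

Each fisher rates each active decade for up to three target species with
one of five categorical scores — major decline (MD), decline (D), stable
(S), increase (I), major increase (MI) — and states what percentage that
category means to them (a "decline" might mean a 25% drop for one fisher
and a 40% drop for another). The pair is converted to a signed fraction

$$f_k = \mathrm{sign}(Z_k)\, Y_k / 100,$$

where $Z_k$ is the score for decade $k$ and $Y_k$ the elicited
percentage; stable means $f_k = 0$. A fisher's *virtual catch* $V$ is a
dimensionless index anchored at the standardized pre-1980s catch of 1 and
updated multiplicatively:

$$V_{k} = X_{k-1} + X_{k-1} f_{k} = X_{k-1}(1 + f_{k}),$$

with $X_{k-1}$ the previous decade's virtual catch. The "±" of the
update is carried entirely by the score's sign: declines subtract a
percentage of the running value, increases add one. Because elicited
percentages are capped at 100, a decline can at most zero the catch and
$V \ge 0$ always.

The modelled decades are the 1980s through the 2010s. The 2020s are
excluded from the enumeration by design (the survey design treats
pandemic-era distortions as out of scope), and pre-1980 careers are
flagged rather than modelled: they anchor the baseline.

### Shifting-baseline correction

A fisher who started in 2005 never saw the 1980s abundance; anchoring
their trajectory at 1 would treat an already-depleted state as "normal"
— the classic shifting-baseline bias. The correction implemented in
`vcc_trajectories(baseline = "cohort")` anchors a post-1980s entrant at
the *cohort mean*: the average virtual catch that the fishers of the
same stratum had reached in the decade before entry. Anchors are
computed iteratively decade by decade — 1980s trajectories first, their
mean then available to 1990s entrants, and so on — which is well defined
because anchors only look backward. Fishers entering in (or before) the
1980s anchor at 1.

Cohort anchors are computed *within the stratum being aggregated*:
overall anchors for the overall trend, per-gear anchors for per-gear
trends. The alternative (always anchoring on the overall cohort) would
mix scales across strata whose trajectories have diverged.

The correction is exactly what the naive anchoring lacks: in a synthetic
population where veterans and late entrants experience identical
per-decade fractions, naive anchoring leaves the entry groups' final
means spread over a ~0.3 range while cohort anchoring collapses the
spread to zero (this is one of the package's acceptance checks). The
`baseline = "naive"` toggle is retained so the size of the bias can be
measured on any dataset.

### Pooling species into a fisher-level trend

The questionnaire elicits per-species trends; results can be aggregated
either per fisher or per (fisher, species) pair, and the survey this
package models does not state which pooling its overall trend uses.
Both modes are provided. The default (`pooling = "fisher"`) averages a
fisher's per-species signed fractions within each decade before running
the cascade, so each fisher contributes one trajectory and fishers with
three species are not over-weighted; rows produced this way are flagged
`derived`. `pooling = "species"` runs the cascade per (fisher, species)
unit and pools the units, which weights fishers by how many species they
reported but keeps species-specific dynamics intact. On heterogeneous
data the two give similar means with different $n$; tests exercise both.

### Aggregation, relative change, and trend fits

`vcc_aggregate()` reports, per decade (and stratum), the arithmetic mean
over active trajectories, the sample standard deviation ($n-1$
denominator, reported as 0 with a flag when $n = 1$), and $n$. Decadal
comparisons use the relative change $100\,(V_{new} -
V_{ref})/V_{ref}$. On the published decadal means (1, 1.46, 1.75, 1.73,
0.7) this reproduces the printed +19.9%, −1.14%, −30%, and −59.5%
figures to their printed precision — one of the acceptance checks.

Trend lines are ordinary least-squares cubics over (decade index, mean),
the decade index running 0 (pre-1980s baseline point, included by
default) to 4. Raw polynomial coefficients are used: with five points on
an abscissa of 0–4 the normal equations are perfectly well conditioned
and orthogonalization would only obscure the coefficients. With exactly
four points the cubic interpolates (zero residuals), which the tests
assert, and coefficient recovery on noisy synthetic cubics is checked
against an independent normal-equations solve.

## Survey sampling design

Sample sizes use the Yamane finite-population formula $n = N/(1 + N
e^2)$ at the conventional precision $e = 0.10$ (configurable). Villages
rarely have one authoritative fisher count, so the design target is the
mean of the per-source sample sizes, reported with min and max as a
variability band. The implemented convention — keep per-source $n$
unrounded, take mean/min/max, round each half-to-even at the end —
reproduces 19 of the 20 published village rows exactly.

The one exception is instructive. For Cañaveral (sources 20, 25, 39,
50) the unrounded mean is 24.51, which rounds to 25; the published table
prints 24. No rounding convention reproduces the whole table (rounding
each source first fixes Cañaveral but breaks Anconcito and Puerto
Cabuyal), and the published coverage ratio for the same village — 164%
of 41 interviews — equals 41/25, not 41/24 ≈ 171%. The package
therefore treats 25 as the internally consistent value and asserts the
printed 24 as a documented mismatch rather than silently reproducing or
ignoring it.

A numerical note: values that are exact halves in real arithmetic (700/8
= 87.5) can land just below the tie in binary floating point, so the
rounding helper pre-rounds to 9 decimals before the half-to-even step.

## Spatial analysis

Fishing grounds arrive as one WGS84 polygon per fisher × decade
(GeoJSON, with `fisher_id`, `decade`, `port_id` properties linking each
polygon to its interview). Three surfaces/statistics are produced on a
regular lon/lat grid, 0.01° cells by default:

* **Effort**: each polygon deposits weight 1; a cell accrues the weight
  of every polygon whose interior contains its *center*. Cell-center
  membership (not fractional overlap) is the usual raster semantics at
  this resolution and admits an exact brute-force oracle, which the
  tests run: rasterization must equal an independent point-in-polygon
  loop over all cell centers, exactly. Effort surfaces are normalized to
  [0, 1] by dividing by the maximum; *core fishing grounds* are the
  cells at or above 0.6 of the maximum (configurable), i.e. where 60% or
  more of the peak number of fishers operate.
* **VCC surfaces**: the unit weight is replaced by the fisher × decade
  virtual catch value and deposited additively, then rescaled onto
  [−4, 4]. The −4..4 scale is not fully specified by its name, so two
  readings are implemented: the default multiplies by $4/\max|v|$,
  preserving sign and — importantly — the zero of "no net perceived
  change"; a min–max affine alternative (`affine4`) is available behind
  a flag but not default, because it relocates zero. All normalizations
  are idempotent, and an all-zero surface is returned unchanged with a
  warning flag rather than divided by zero.
* **Distances**: each ground's planar (shoelace) centroid to its port of
  origin on the WGS84 ellipsoid (`geosphere::distGeo`), summarised as
  mean and median km per decade and per village. The planar degree-space
  centroid is a documented convention: at the near-equatorial latitudes
  of the target fisheries the difference from a locally projected
  centroid is below 0.1% of polygon size for polygons up to ~2°, which a
  test verifies. An alternative distance mode measures to the nearest
  point of a coastline polyline (`geosphere::dist2Line`) for surveys
  that define "distance from home" that way; point-to-port is the
  default reading.

Rasters are exported as ESRI ASCII grids (`.asc`), a plain-text format
readable by any GIS; the writer emits full-precision values and the
reader round-trips them exactly. Grid registration (row 1 at the
northern edge, cell centers at half-cell offsets) is fixed in
`grid_spec()` and documented there.

## The synthetic survey generator

`generate_survey()` exists so that every pipeline stage is testable
without field data. It draws a contacted roster with a decline rate of
275/1436, staggered career entry, per-decade categorical scores,
percentages, gears, up to three species per fisher, decline drivers, and
one rectangular fishing ground per fisher × active decade offshore of a
synthetic meridian coastline. Its defaults are the package's statement
of the study conditions it emulates:

* gear shares 75.4 / 21.4 / 1.6 / 1.2 / 0.4% (gillnet, bottom longline,
  spearfishing, hand gathering, handline);
* score simplexes drifting from ~66% positive categories in the 1980s to
  ~89% negative in the 2010s;
* an entry-decade simplex (0.12, 0.18, 0.22, 0.26, 0.22 over pre-1980s
  … 2010s) chosen so the expected share of the roster active per decade
  is 0.30 / 0.52 / 0.78 / 1.00, matching the reported decade activity
  counts (350, 608, 914, 1125 of 1161);
* perceived percentages truncated-normal around the categories'
  illustrative anchors (decline 25, major changes 70, sd 10/15, bounded
  to [1, 100]). Only anchors are reported by the surveys this emulates —
  the empirical distribution of elicited percentages is not — so these
  are labelled anchors, not an observed distribution;
* centroid-to-port offsets lognormal with decadal means 36.8 / 37.1 /
  46.6 / 54.4 km and log-sd 1.35, which makes medians roughly a third of
  means, the right-skew reported for mapped grounds.

Ports sit on a north–south meridian "coast" and grounds are rectangles
centred due west of the port, so each ground's true distance equals its
drawn offset; the generator records these truths (entry decades, drawn
distances, and the analytic per-decade expected signed fraction) to
enable recovery tests. Recovery is checked end to end: cohort means must
approach $\prod_k (1 + E[f_k])$ within Monte-Carlo error, measured
distance means must recover their targets within three standard errors,
and marginal shares must match within binomial error.

One sampling-noise subtlety: the configured distance means rise only
0.3 km between the 1980s and 1990s, far below the ~1.5 km Monte-Carlo
standard error of a decadal mean even at 10,000 fishers, so tests assert
strict increase on the configured targets and on the decade pairs whose
separation exceeds the noise, with 3-SE recovery for every decade.

What the generator does **not** emulate: behavioural realism (no fisher
decision model), spatial autocorrelation of effort beyond the shared
port geometry, bathymetry or coastline shape, seasonality, and any
correlation between a fisher's scores across decades beyond what the
per-decade simplexes induce. Passing recovery tests therefore show that
the *pipeline* is correct and unbiased under the stated sampling model —
not that the model captures every feature of real interview data.

## Degenerate inputs and error policy

Validation is strict and early. Interview rows failing score, decade,
percentage, consent, or age/experience checks are rejected with a line
number and reason (never silently repaired). A non-stable score with a
missing percentage is a hard error by default, because the survey design
always elicits one; an optional imputation mode substitutes configurable
category midpoints and is off by default. Trajectories with gaps or
duplicate decades error; a late entrant with no cohort to anchor on
errors rather than guessing. Zero-area polygons error in the centroid;
polygons outside the grid error naming the offending fisher; an unknown
port id errors. The experience threshold is implemented as ≥ 5 years
inclusive — the surveyed experience ranges start at exactly 5 — with a
`strict` flag for the strictly-greater reading.

## Problem sizes used in the tests

The test-suite sizes its simulations to what the checks need: exhaustive
cascade enumeration over all $5^4$ score sequences on a 5-point
percentage grid; parameter recovery on 1,000 fishers; marginal fidelity
on 10,000 fishers; rasterization oracles on 25 polygons over a 50×50
grid. These were chosen as the smallest sizes at which the Monte-Carlo
bounds in the checks are meaningful.

## Known limitations

* The VCC index is dimensionless; converting it to absolute tonnage is
  out of scope, as is uncertainty propagation beyond per-decade standard
  deviations.
* Elicited percentages are treated as exact; response-style differences
  between fishers (some round to tens, some anchor on the interviewer's
  example) are not modelled.
* GeoJSON support covers Polygon feature collections with a single outer
  ring per feature — the shape participatory-mapping digitisation
  produces — not multipolygons or holes.
* The cubic trend is descriptive, fitted to (at most) five aggregate
  points; it has no inferential content and its `glance()` statistics
  should be read accordingly.

## A compact worked run

```{r}
s <- generate_survey(survey_config(n_villages = 4,
                                   fishers_per_village = 50), seed = 7)
run <- run_pipeline(s$interviews, s$grounds, s$ports, cellsize = 0.05)
run
run$relative_changes
tidy(run$trend)
```
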