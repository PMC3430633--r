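---
title: "Annual land-cover mapping and decade-scale change trends: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annual land-cover mapping and decade-scale change trends: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lulctrends)
```

## The problem

National land-use/land-cover (LULC) monitoring in cloudy tropical regions
is hard to do with high-resolution optical imagery: cloud-free coverage is
sporadic and inconsistent between years. A practical alternative is a
moderate-resolution (250 m) 16-day composite vegetation-index product,
which trades spatial detail for dense, consistent temporal coverage. This
package implements that strategy as a complete, testable pipeline:

1. **Reference labelling** — paired human interpreters estimate percent
   cover of seven categories (woody, herb, ag, plant, built, bare, water)
   on 250 m footprints; consensus rules and percent-cover thresholds
   convert these to categorical training labels.
2. **Temporal features** — per pixel and year, five statistics (mean, sd,
   min, max, range) of four bands (EVI, red, NIR, MIR) over six calendar
   windows, with reliability filtering.
3. **Tiered per-biome classification** — a random-forest pair per biome
   (full-feature and annual-only models) with proximity-based outlier
   removal and out-of-bag (OOB) accuracy assessment.
4. **Change trends** — per-municipality linear regressions of annual class
   area on year, with missing-year rules, significance at p <= 0.05, and
   regression-based (not raw) net change.
5. **Multi-scale aggregation** — nets, gain/loss partitions, hotspot
   tables and a rank-sum comparison of gainer/loser municipality sizes at
   municipality, ecoregion, biome and country scales.

Because no real imagery ships with the package, a first-class synthetic
scene generator supplies landscapes, ground-truth cover trajectories,
composite cubes and reference samples with the statistical structure the
analysis assumes, so every stage is testable against known truth.

## Reference-sample rules

Each footprint carries two interpreters' percent-cover vectors (summing to
100) and an image year. If the interpreters agree on the majority cover
category *and* the year, their estimates are averaged element-wise;
otherwise an expert resolution is adopted verbatim, and with none supplied
the sample is excluded. "Majority" is the category with the largest
percent; ties break by the fixed category order (woody, herb, ag, plant,
built, bare, water), and a tie counts as agreement only when both
interpreters tie identically.

Class assignment: a category covering >= 80% labels the sample with that
category; otherwise 20–80% woody cover (closed interval) with bare, herb
and ag each below 80% labels it *mixed woody*; anything else is
unassigned and excluded from training and accuracy assessment. When both
rules could apply (woody exactly 80), the >= 80% rule wins — it is stated
first and is the stricter condition. Reporting groups eight categories to
five classes: ag+herb, mixed woody+plant, built+bare, woody, water.

## Temporal features and the tier rule

Composite k (1..23) is assigned to the month containing its nominal start
day-of-year 1 + 16(k−1); windows are the month sets {1–12}, {1–6}, {7–12},
{1–4}, {5–8}, {9–12} (named M12, H1, H2, T1, T2, T3). The composite→month
rule is our choice: the protocol names calendar windows but not the
assignment of composites to them. Composites flagged unreliable
(reliability value 3) are removed before statistics; a window with fewer
than three reliable composites is invalid and its statistics are null.
Only flag value 3 is removed — marginal values 1–2 are retained, exactly
as the filtering rule is stated.

The 120 features (5 stats x 4 bands x 6 windows) determine a per-pixel-year
tier: **full** (all six windows valid) routes to the initial classifier;
**annual_only** (valid 12-month window, some sub-annual window invalid)
routes to the secondary classifier trained on the 20 annual features;
**none** (invalid 12-month window) becomes No Data. A pixel with valid
sub-annual but invalid annual windows is *none*: the secondary model
requires annual statistics. The standard deviation uses the n−1
denominator (conventional sample statistic; the protocol does not
specify).

## Classifier

Each biome's classifier is a random forest with 1999 trees, minimum
terminal-node size 5, and floor(sqrt(p)) candidate predictors per split.
No forest implementation is available in the supported runtime, so the
package ships its own compiled bagged-CART learner (Gini splits, seeded
`mt19937_64` stream, OOB votes, proximity matrix); for a fixed seed the
forest is bit-reproducible across platforms. Vote ties break by the fixed
class order.

Training: an initial forest on all samples yields the proximity matrix;
the classic proximity outlier measure (raw score n_c / sum of squared
within-class proximities, standardized by the class median and mean
absolute deviation from the median; self-proximity excluded) removes
samples scoring above 10; both final models are refit on the retained
samples. OOB confusion matrices are reported in the five-class scheme —
predictions and references are grouped post hoc, since grouping reduces
inter-class confusion and maps are reported in five classes. The
cross-biome summary is the *unweighted* mean (and n−1 sd) of per-biome
overall accuracies; the test suite demonstrates as a negative control that
a sample-weighted mean does not reproduce the published summary value.

Map assembly applies the tier routing per pixel-year, groups to five
classes, and sets pixels with >= 4 No-Data years (of 10) to No Data in all
years. Municipality-level No-Data fractions are recorded per year.

## Trend analysis

Per municipality and class (woody, mixed woody/plant, ag/herb), annual
areas (pixel count x cell area, cell 231.7 m) are regressed on the year
index by ordinary least squares. A municipality-year with more than 1% of
total municipality area mapped as No Data is dropped from that
municipality's regressions (exactly 1% is retained; the denominator is
total mapped municipality area including No-Data pixels). Fewer than three
usable years makes the trend unestimable — the protocol is silent; three
is the minimum for a p-value. Strength is Pearson's R; the two-sided
p-value uses the exact t-transform t = R sqrt((n−2)/(1−R²)). A
zero-variance series takes slope 0, R = 0, p = 1 by convention. Net change
is the difference of regression-fitted areas at the endpoint years
(2001/2010), i.e. 9 x slope — regression estimates, not raw areas, enter
all absolute-area arithmetic. The regressor is the year index 1..10;
calendar years would give identical slope, net and R.

## Aggregation

Municipalities straddling units are assigned to the biome/ecoregion of
greatest overlap (ties to the lowest unit id). Rollups sum fitted
endpoint areas and nets over *all* municipalities, not only significant
ones; significant-only variants are computed separately. The invariants
`net = area_last − area_first = gain − loss` hold exactly at every scale,
and ecoregion, biome and country nets agree exactly because both unit
systems partition the municipalities. Printed-style percentages round
half-away-from-zero to integers. Hotspots rank by |net| (ties by
municipality id) and report the integer-rounded share of the national
total in their direction.

The gainer/loser size comparison is a two-sided Mann-Whitney rank-sum
test: exact enumeration for combined n <= 12 (midranks under ties), the
normal approximation with tie correction otherwise. Both U and the normal
deviate z are reported. The published value "U = 3.6" with p = 0.0003 is
not a plausible rank-sum U for groups of several hundred; 3.6 is instead
consistent with a two-sided normal deviate at that p, so the package
reports both statistics rather than assuming either reading.

## The synthetic world

The generator states one fixed world; its defaults are not tuned to test
outcomes:

- **Landscape**: nearest-seed tessellation (ties to the lowest
  municipality id) into compact municipalities; default desk scale 60x60
  pixels at 231.7 m, 12 municipalities, 3 biomes, 4 ecoregions, 10 years.
- **Trajectories**: per-municipality linear class-area targets with
  largest-remainder rounding (realized areas within one pixel of the
  line); change pixels flip at municipality-random locations — no spatial
  contagion, which the analysis nowhere exploits. Trends that would drive
  an area negative are clipped at zero with a warning.
- **Phenology**: stylized but physically bounded seasonal curves (EVI in
  [−0.2, 1], reflectances in [0, 1]); Gaussian observation noise, default
  sd 0.02 — a plausible composite-product noise scale; cloud probability
  0.05, matching a mostly-clear composited record; reliability flags use
  only {0 good, 3 unreliable}, because the filter keys only on value 3.
- **Reference samples**: minimum spacing 1000 m; default 100 samples at
  the desk scale (the spacing rule caps feasible counts on a small grid);
  interpreter noise sd 5 percent points; 10% forced majority
  disagreements; stratified/random split 50/50 — the protocol does not
  state the proportion, so it is a parameter with an even default.

What a green test establishes — and what it does not: the synthetic world
has no mixed pixels, no spatially correlated cloud, no phenological
drought/El Niño anomalies and no interpreter bias, so passing tests
verify the *pipeline arithmetic and routing rules*, not classification
skill on real imagery. Published-number tests verify printed arithmetic
relationships only.

## Numerical choices and degenerate inputs

- Percent vectors must sum to 100 within 0.5 (interpretation rounding).
- Windows with all-equal values give sd 0 and range 0 exactly; the
  vectorized feature path clamps tiny negative variances to zero.
- Forest ties (votes, split scores) resolve deterministically; split
  thresholds are midpoints guarded against floating-point underflow.
- `percent_change` with a nonpositive baseline is flagged undefined
  rather than returned as a number.
- One published summary value is irreproducible as printed: the n−1 sd of
  the four overall accuracies (92.2, 89.2, 82.0, 86.1) is 4.36, which
  truncates — but does not round — to the printed 4.3. The tests assert
  the computed value and note the truncation.

## Scaling of the shipped tests

Unit and acceptance tests run the full chain on 40–50 pixel grids with
499-tree forests (seconds instead of minutes); the forest defaults remain
1999 trees and all rule thresholds are at their protocol values. Nothing
in the pipeline is sensitive to tree count at the separability of the
noiseless fixtures, which is what those tests measure.

## Known limitations

- The learner is a compact reimplementation: no class weights, no
  missing-value surrogates, exhaustive threshold scan per candidate
  variable. Adequate for hundreds of samples and features, not tuned for
  the 10,000-sample national problem.
- Raster I/O is plain-text ESRI ASCII grid (band-per-file), not GeoTIFF;
  no projections or geodesy — synthetic scenes live on an abstract grid.
- The trend model is strictly linear; breakpoints, autocorrelation and
  spatial smoothing are out of scope.
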