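---
title: "Methods: ensembles of small models on a synthetic archipelago"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensembles of small models on a synthetic archipelago}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(islesdm)
```

# Scope and model

`islesdm` implements a climate-change impact assessment workflow for island
faunas with sparse presence-only records: per-species habitat suitability by
Ensembles of Small Models (ESMs), binary range maps and range-size change
under future climate scenarios, species-richness and corrected-weighted-
endemism hotspot surfaces with altitudinal/directional shift tests, and
protected-area overlap. Because real occurrence databases of this kind are
rarely redistributable, the package ships a synthetic-archipelago generator
with virtual species whose niches are known exactly; every downstream claim
the test suite makes is a recovery claim against that known truth.

## The ESM model

For a species with presences $P$ and pseudo-absence sets $A_s$, every
unordered pair $(i, j)$ of retained predictors gets its own binary
classifier (Random Forest by default, logistic regression available). Pair
skill is measured by the True Skill Statistic
$\mathrm{TSS} = \text{sensitivity} + \text{specificity} - 1$ under
spatial-block cross-validation, and the ensemble suitability is the
weighted mean

$$\hat p(x) = \frac{\sum_k w_k\, p_k(x)}{\sum_k w_k},
  \qquad w_k = \max(0, \overline{\mathrm{TSS}}_k),$$

so negative-skill pairs contribute nothing. Weighting by cross-validated
TSS rather than model selection is the mechanism of interest: with
two-predictor models even species with very few records can be fit without
overparameterization.

Two skill summaries coexist and serve different purposes:

* `ensembleTss` — the mean, over pseudo-absence sets, repeats and folds, of
  the ensemble's TSS on held-out blocks, each fold binarized at its own
  maxSSS threshold. This is the admission gate (default `tssMin = 0.8`):
  a mean of fold-level scores has a smooth null distribution, which keeps
  the null-model test (below) well calibrated, whereas a single TSS at a
  threshold refit on pooled predictions concentrates on few values.
* `threshold` — the maxSSS threshold fitted once on the cross-validation
  ensemble predictions pooled over repeats, used to binarize projections.
  Pooled CV predictions are less optimistic than training predictions.

## Cross-validation design

Blocks are squares of side equal to the median spatial autocorrelation
range of the retained predictors (estimated from empirical semivariograms;
the range is where semivariance reaches 95% of the sill). All points in a
block share a fold; blocks holding presences are dealt greedily to balance
presences per fold, absence-only blocks to balance fold sizes, so five
folds approximate 80:20 splits. Repeats redraw the lattice origin. The
paper-style protocol of "ten 80:20 splits" is therefore realized as
repeats of 5-fold block CV; fewer repeats are used in the shipped
configurations (noted below).

The null-model test refits the ensemble on datasets whose presences are
drawn uniformly from land and reports
$p = (1 + \#\{\mathrm{TSS}_\text{null} \ge \mathrm{TSS}_\text{obs}\}) /
(n_\text{null} + 1)$; 99 nulls give the 0.01 resolution used for the
admission claim "better than random".

# The synthetic archipelago

The generator is first-class, tested code; its defaults are the package's
study conditions.

* **Terrain** — island-shaped radial bumps (max-composed, so neighbouring
  islands do not fuse through land bridges) plus a Gaussian random field,
  thresholded at sea level; approximately 22% of a 150 x 150 km grid is
  land, in ~5 components. Cell size 1 km, the working resolution of
  30-arc-second climatology. All distances are planar km in a local
  equirectangular frame; occurrence-record distances use great circles on
  the authalic sphere (differences are negligible at these extents).
* **Climate** — monthly means from a latitudinal gradient (0.8 degC per
  degree), a seasonal sinusoid (semi-amplitude 7 degC, warmest in July), a
  6.5 degC/km lapse rate, and a *persistent* spatial anomaly field
  (sd 0.6 degC) shared by all months plus small independent monthly jitter
  (sd 0.15 degC). Persistence matters: anomalies represent stationary
  orographic and coastal effects, and it makes the derived bioclimatic
  layers realistically collinear, so the collinearity filter has genuine
  work (typically ~27 of 34 candidates are dropped). Precipitation is
  Mediterranean: 75% of ~600 mm falls in November-April, with a 25%/km
  orographic enhancement and a persistent lognormal anomaly.
* **Scenarios** — each (GCM, RCP, time-slice) triple maps to an additive
  warming and multiplicative drying: RCP 4.5 reaches +2.2 degC / -9%
  precipitation by the 2080s, RCP 8.5 +4.0 degC / -20%; the hot-model
  archetype (`hadgem2-like`) scales both by 1.15, `ensemble-like` by 1.05.
  Uniform monthly shifts make the additive bioclim identities exactly
  testable (BIO1/BIO5/BIO6 shift by the delta; BIO4/BIO15 invariant).
* **Virtual species** — twelve archetypes with product-Gaussian niches on
  annual mean temperature (`bio1`) and annual precipitation (`bio12`):
  cold-adapted (optima in the coolest decile; warming contracts them),
  warm-adapted, broad generalists, and single-island endemics (suitability
  masked to one component). `strong_niche` has a deliberately narrow
  temperature tolerance (10% of the land range) and is the strong-signal
  benchmark for skill, weight-concentration and truth-recovery checks.
* **Sampling bias** — records are drawn with probability proportional to
  true suitability times $\exp(-w\,d)$, with $d$ the distance to the
  nearest settlement ($w = 0.05$/km in the default pipeline), emulating
  accessibility bias; the bias model recovers $w$ from the records.
* **Protected areas / human modification** — random rectangular land
  patches accumulated until they cover 28% (+-5 points) of land cells
  (the national share the analysis mirrors); polygons are clipped to land
  at rasterization via the cell-centre rule rather than by vector
  clipping. The human-modification surface blends settlement proximity
  with a smooth field into [0, 1].

What the generator does **not** emulate: real spatial structure of Aegean
climate fields, interannual variability, biotic interactions, taxonomic
error, or roads (the accessibility model uses point settlements only, in
line with sampling effort being driven by towns rather than roads). A
green test suite therefore shows the machinery is correct and the recovery
claims hold on clean data, not that any particular real fauna behaves
this way.

# Predictor derivation and reduction

`deriveBioclim` implements the 19 standard bioclimatic variables with the
wrap-around quarter convention: all 12 consecutive three-month windows are
scored and ties go to the lowest starting month. `bio4` is 100 x the
sample SD of monthly means and `bio15` is $100\,\mathrm{sd}(p) / (1 +
\mathrm{bio12}/12)$. `deriveEnvirem` adds the Hargreaves PET family
(extraterrestrial radiation from latitude and mid-month solar geometry),
quarter PET sums under the same quarter convention, the Thornthwaite
aridity index $100 \cdot \text{annual deficit} / \text{annual PET}$
(equal to 100 in a rain-free year), the Willmott-Feddema moisture index,
continentality, and growing degree-days; only the PET and aridity members
are load-bearing for headline outputs, the rest complete the candidate
pool. `deriveTopographic` gives Horn slope/aspect, TPI, TRI and the
McCune-Keon heat load index from folded aspect; edge and coastal cells are
nodata, which downstream fitting handles by dropping incomplete rows.

`filterCollinear` works on a seeded sample of jointly valid cells (10,000
by default; rank correlations stabilize well below full-grid size). Order:
zero-variance layers out first; then while any pair has |Spearman rho| at
or above 0.7, the member of the worst pair with the higher mean absolute
correlation is dropped; then highest-VIF layers (fit by linear regression
on the remaining set) until all VIF < 10. Exactly collinear groups make
every member's VIF infinite, so ties are broken by mean |rho|. The
retained set is data-dependent output, not a constant. A `keep` argument
protects named layers from both passes; the virtual-species experiments
use it to keep the true niche axes in the candidate set, which is the
standard design for recovery benchmarks (the question is whether the
ensemble *finds* them, not whether the filter ever discards the truth).

# Occurrence preparation

Deduplication keeps one record per species and cell. Thinning retains, per
species, a large subset with all pairwise distances at or above the
thinning distance, by randomized greedy insertion with 20 restarts; tests
verify it reaches at least 90% of the exhaustive optimum on small
instances and is idempotent. The default thinning distance is one cell
diagonal (~1.4 km) — one record per neighbourhood at working resolution —
and species with fewer than 3 thinned records are discarded. The
accessibility model is a Poisson regression of per-cell counts on
distance-to-feature rasters with rate $q\,e^{-\sum_f w_f d_f}$; $q$ has a
closed-form profile, so only the non-negative decay rates are optimized
numerically.

# Projection diagnostics

Clamping counts, per cell, the predictors outside their training ranges
and nullifies suitability where the count is positive (the conservative
choice). Binarization uses the pooled-CV maxSSS threshold; candidate
thresholds are the midpoints of consecutive distinct scores plus the
extremes, ties resolved to the lowest threshold.

ExDet follows the two-part definition: univariate novelty NT1 sums the
scaled exceedances below/above the reference range; combinatorial novelty
NT2 is Mahalanobis distance to the reference mean/covariance, normalized
by the maximum Mahalanobis distance within the reference itself, so NT2
values above 1 flag novel combinations inside univariate ranges. Analogue
cells have NT1 = 0 and NT2 at most 1. The %N neighbourhood radius is the
reference set's own median nearest-neighbour Gower distance — a
scale-free choice, since the source tool's constant is not documented.

The niche-truncation index projects study-area and full-range occurrence
environments onto the first two principal axes of the pooled standardized
data, kernel-smooths both to normalized densities on a common lattice
(shared bandwidths), and reports $\tfrac12\sum |z_1 - z_2| = 1 - D$
(Schoener's D): 0 when the study sample spans the niche, towards 1 when it
captures a disjoint part. This is one defensible member of the family of
truncation indices, documented as an interpretation.

Range change classifies loss/stable/gain cells and reports
$100(G - L)/C$. Dispersal defaults to `buffered` with a 2-cell buffer:
no-dispersal would forbid the expansions that clearly occur for
warm-adapted species, while unlimited dispersal is overoptimistic; both
alternatives remain available and the mode is recorded in every output
row.

# Hotspots, shifts, and protection

SR is the cellwise presence count; WE sums inverse range sizes (so WE
summed over cells equals the number of species with a non-empty range —
an exact conservation law the tests assert); CWE = WE/SR. L1 hotspots are
the cells at or above the empirical 99th percentile in the inverse-CDF
(`type = 1`) convention with ties included: deterministic, rank-invariant,
and never dropping a top-scoring cell (100 distinct values yield 2 cells,
1000 yield 11). Altitudinal shifts are tested by Kruskal-Wallis on hotspot
elevations; directional shifts by a two-sample Watson $U^2$ on bearings
from the current-period centroid, with a permutation p-value (bearings are
the package's circular variable of choice; longitude-as-circular is not
implemented). A pooled multi-group Kruskal-Wallis across slices/GCMs is
also exposed, since two-group and pooled designs answer different
questions. Protected-area overlap uses the cell-centre rule and reports
the fraction of hotspot cells inside the network per metric x scenario,
with a monotone-trend summary across slices.

# Numerical and reproducibility choices

* Every stochastic function takes an explicit seed, seeds the RNG on
  entry and **restores the caller's stream on exit**; the pipeline expands
  one master seed deterministically per stage and species. Two runs with
  the same configuration produce hash-identical output tables.
* Rasters are a minimal S4 grid class (matrix plus local-km geotransform
  and a geographic origin); files are plain-text ESRI ASCII grids with a
  JSON sidecar, occurrences CSV, polygons GeoJSON, reports JSON/CSV.
* Degenerate inputs are explicit: flat metric maps refuse hotspot
  extraction; groups under 3 cells skip shift tests but still report
  centroids; constant predictions yield AUC 0.5 and a missing Boyce index;
  unmodellable species (all pair weights 0) are flagged, not dropped
  silently.

## Problem sizes

The shipped configurations are sized for a single CPU: the default
pipeline uses a 150 x 150 km grid, 12 virtual species, 300 records per
species, 2 pseudo-absence sets of up to 1,000 points, 2 repeats of 5-fold
block CV and 150-tree forests (~3 minutes end-to-end); `demoConfig()` is a
70 x 70 grid with 6 species (~30 s). Statistical calibration checks run
500 null replicates with reduced permutation counts. These sizes are the
package's reference experiment; nothing prevents larger grids, more
repeats or more trees via the configuration object.

# Known limitations

Bivariate Random Forests cannot represent interactions among three or more
predictors; the ensemble inherits that by construction. The variogram
range estimator is a heuristic (95% of a binned sill) adequate for block
sizing, not a fitted geostatistical model. The %N statistic is expensive
in dense grids and is therefore computed on capped reference samples. PA
polygons are rectangles, so vector-space overlap topology is simpler than
WDPA geometries; all overlap semantics are raster-side. The generator's
climate is stationary within a period — no interannual variance — so
evaluation scores on synthetic data run higher than typical field data
would allow.
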