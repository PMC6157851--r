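---
title: "Mapping social-ecological hotspots and coldspots: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping social-ecological hotspots and coldspots: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sesmap)
```

`sesmap` integrates four polygon-level value layers for an urban green
space — two social (citizen landscape values, visitor use) and two
ecological (forest habitat quality, expert-scored urban biodiversity) —
and quantifies their spatial agreement with quantile hot/coldspot maps and
the Jaccard overlap coefficient. This vignette explains the model behind
each stage, the tunable parameters and their defaults, the synthetic study
system used for validation, and the numerical and design decisions taken
where the methodology left choices open.

## The measurement model

**Analysis polygons.** All quantities are aggregated over a fixed set of
irregular management polygons (the planning units a parks department
actually works with). Areas are hectares computed from projected
coordinates in meters; every raster operation shares one 20 m analysis
grid, indexed row-major from the north-west corner.

**Landscape values.** A survey respondent can assign any of seven positive
landscape values to any polygon. The per-category layer counts distinct
respondents per polygon; the *multiple landscape value* sums the seven
counts. Two deliberate choices: a respondent counts at most once per
(polygon, value) — repeated rows are collapsed with a warning — and
polygon size is *not* corrected for, because the polygons are designed to
be internally homogeneous landscape units, so enlarging one would not add
new value content. Polygons never mentioned score 0: absence of mention in
a census of respondents is an observed zero, not missing data.

**Visitor use.** Route tracks (GPS-recorded or map-drawn polylines) are
first clipped to the study-area boundary, both to keep only intra-site use
and because segments outside the site could otherwise leak respondent
locations. The layer is clipped track length per polygon divided by
polygon area (m/ha). Density, not raw length, is used because track
length grows mechanically with polygon size. Trail density — the same
operation applied to the managed trail network — is carried as a
covariate in the correlation matrix.

**Forest habitat quality.** Stand-level inventory attributes enter the
structural index `I = f(d) · v`, where `v` is standing wood volume
(m³/ha) and `f` a logistic ramp over mean tree diameter `d` (cm), an
indicator of stand maturity:

$$ f(d) = \frac{1}{1 + e^{-k\,(d - d_0)}} $$

The source index specifies a sigmoidal `f` but not its constants, so the
package fixes a configurable logistic with `d₀ = 25` cm and `k = 0.2`/cm
(`habitat_quality_params()`). These defaults put `f` at 0.5 for a 25 cm
stand and above 0.995 beyond 52 cm, so mature stands score essentially
their full volume — the intended behavior of valuing old, large-diameter
forest — while young stands are discounted steeply. All tests treat `f`
as configured, not as ground truth. The index is rasterized per stand at
20 m and zonally averaged per polygon.

**Urban biodiversity.** Experts score, per biotope class, seven community
attributes of their taxon from 0 (no support) to 4 (very high support),
and rate their confidence on five labels mapped to weights
{0, 1, 2, 4, 8}. The biotope score is the arithmetic mean of
`score × confidence` over all (expert, taxon, attribute) responses. The
phrase "average weighted by confidence" admits a second reading — the
normalized weighted mean `Σs·c / Σc` — but only the product-then-mean
scheme spans the scheme's stated 0–32 range (4 × 8 = 32), so that is the
default; the normalized reading (range 0–4) and a hierarchical variant
(average within taxon, then across taxa) are available via the `scheme`
argument, and the package's tests demonstrate where they differ.
Zero-confidence responses are *included* (pulling scores toward 0) rather
than dropped; this too is switchable by filtering the input table.

## Integration and delineation

Layers are min-max normalized so each dataset carries equal weight;
missing values stay missing, and a constant layer is an error by default
(its normalization is undefined) with an opt-in all-zeros fallback.
Spearman rank correlations (average ranks for ties, two-sided p-values,
pairwise-complete polygons) quantify pairwise association; p-values are
descriptive, with no multiple-testing correction by default, matching how
such matrices are conventionally reported (a `p_adjust` switch exists).
The combined social and combined ecological layers are equally weighted
sums of their two normalized components, so each spans [0, 2]; missing
values propagate rather than being imputed, since imputation would
manufacture hot/coldspots.

Hot/coldspots are the top and bottom thirds of each layer. The method
is a *rank* quantile (equal polygon counts per class) — that is what a
quantile delineation means — with a value-range-thirds mode behind a flag
for sensitivity analysis. Ties at a class threshold all take that class's
label, which can make class sizes unequal; the event is logged. A polygon
tied into both classes at once, and the fully degenerate all-tied layer,
fall back to neutral with a warning.

Overlap between two hot (or cold) sets is the Jaccard coefficient in
percent, computed by default on 20 m grid cells (the formula's natural
unit, and area-weighting comes free); a polygon-unit mode is provided and
agrees with the cell mode up to raster discretization for polygon-constant
labels. Two empty sets are defined to overlap 0 % (with a warning) so
batch runs stay total. Bands are half-open: [0, 20) very low, [20, 40)
low, [40, 60) moderate, [60, 80) high, [80, 100] very high; exactly 20 is
"low". Overlay tables report hectares for all nine state combinations of
two maps and must conserve total polygon area — a tested invariant.

The strategy stage crosses each polygon's landscape-value, visitor-use and
combined-ecological states (hot → high, cold → low). Only the eight
{high, low}³ cells receive a strategy, looked up from an editable CSV
resource; neutral-in-any-layer polygons are left unclassified, because the
hot/cold states form a continuum and forcing the nearest cell would
overstate the method's resolution.

## The synthetic study system

No empirical dataset ships with the package, so `simulate_landscape()`
generates a complete study system whose *structure* — not whose numbers —
matches the setting the pipeline targets:

* 82 polygons tiling an elongated 2 × 10 km park (2000 ha), as Voronoi
  cells of clustered seeds: 73 % of seeds in the southern 18 % of the park,
  giving the right-skewed area distribution (most polygons under 10 ha,
  a long tail of large northern cells) typical of management units that
  are fine-grained near the city and coarse in the hinterland.
* Three latent surfaces on the 20 m grid, each a standardized north–south
  trend plus a smooth Gaussian-bump field (~1.2 km length scale):
  social-value propensity rising northward, use intensity falling off
  steeply from the south entrance, and forest maturity high toward both
  remote park ends (deeper on the north side, where polygons are large)
  and low across the intensively managed middle. Trend and noise weights
  are the `gradient_*` / `noise_*` parameters; defaults (trend 1,
  noise 0.25–0.45) plant gradients strong enough to be recoverable, which
  is the generator's contract.
* 599 respondents assign each of 7 value categories to polygons with
  probability `p_assign · w_c · s_i` (propensity `s_i`, category weights
  `w_c` spread 1.4–0.6, `p_assign = 0.08`); the scale reproduces summed
  multiple-landscape-value counts up to ≈330 per polygon.
* 366 route tracks are weighted random walks on a jittered 100 m trail
  lattice. Edge weights rise steeply with planted intensity
  (`(0.05 + u)⁴`), starts are drawn from the stationary distribution and
  transitions pick incident edges by weight, so stationary edge-visit
  rates are proportional to edge weights and summed track length per
  polygon follows the planted field. Walk lengths are lognormal with a
  ~5 km median, a plausible recreational outing. The ground-truth use
  latent is the walk model's *expected* track-length density per polygon
  (weighted in-polygon edge length over area), i.e. the noiseless value
  of exactly the quantity the visitor-use layer measures.
* ~440 forest stands (finer Voronoi cells, one per ~4.5 ha) take maturity
  from the latent field under multiplicative lognormal noise; diameter
  (5–55 cm) and volume (20–400 m³/ha) rise linearly with it. The lowest
  ~12 % of stands by maturity are non-forest and leave habitat no-data.
  Biotope classes are maturity quantile bins (37 classes) with cell-level
  noise, so mature-forest classes co-locate with high maturity; 2–3
  experts per each of 10 taxa score all classes with means increasing in
  class quality, confidence sampled uniformly over the five levels
  (no empirical confidence distribution exists to emulate).

Everything is deterministic under the configuration seed, and the ground
truth (latents plus their top/bottom-third labels) is written alongside
the data but never read by the analysis.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: real route topology (walks have no
purpose or home location), survey non-response and mode effects,
correlated expert biases, mixed land tenure, multi-polygon habitat
continuity, or any seasonal structure. Recovery results show the pipeline
is statistically faithful when its assumptions hold, not that any
particular park behaves like the simulation.

## Numerical choices and degenerate inputs

* **Cell membership** is by cell-center-in-polygon (even-odd rule), not
  fractional coverage: deterministic, cheap, standard zonal-statistics
  behavior. Slivers thinner than a cell can vanish; at 20 m on ~0.6 ha+
  polygons this is negligible and is documented rather than patched.
* **Rasterization overlap** is resolved last-geometry-wins, preserving
  input order — deterministic and easy to reason about.
* **Geometry** is held as ring lists in a projected meter CRS; validity
  is checked by segment-intersection scan and invalid input is rejected
  (not silently repaired). Geographic input is projected with a spherical
  transverse Mercator implemented in the package; for study areas tens of
  kilometers across the distortion is well below the 20 m grid
  resolution.
* **Polyline clipping** splits each segment at every ring-edge crossing
  and keeps sub-segments whose midpoints lie inside; clipped length is
  conserved to 1e-6 relative in the tested tessellation identities.
* **Zonal means** over zero valid cells yield `NA`, which propagates to
  pairwise-complete correlation handling — silent zeros would bias rank
  statistics. The one deliberate exception is the habitat layer's
  non-forest rule, where "no forest" is genuine information and cells
  default to zero (switchable to `missing`).
* **Voronoi cells** are computed by half-plane clipping against
  neighbors in increasing distance order with an early stop; cells tile
  the extent exactly by construction.
* **Problem sizes in the test suite.** Unit tests run on small
  constructed geometries and a 30-polygon, 1 × 3 km simulation; the
  replication study in the acceptance tests runs 100 full-scale seeds
  (82 polygons, 599 respondents, 366 tracks each), sized so the whole
  suite completes in a few minutes on one CPU.

## Known limitations

* Jaccard and correlation inference is descriptive; no spatial
  autocorrelation correction or hotspot significance testing is applied
  (the delineation is purely quantile-based by design).
* The habitat sigmoid's constants are package defaults, not estimated
  values; conclusions sensitive to `d₀` or `k` require a sensitivity run
  over `habitat_quality_params()`.
* Min-max normalization is outlier-sensitive; a single extreme polygon
  compresses the rest of the scale. Rank-based delineation is immune, but
  the combined layers are not.
* The eight-cell strategy matrix is guidance text, deliberately stored as
  an editable resource; it is not a decision-optimization method.
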