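---
title: "Mapping wet forest soils from a high-resolution DEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping wet forest soils from a high-resolution DEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetmapr)
```

## The problem

Wet soils in the boreal forest landscape — treed wetlands, riparian soils
along streams and lakes — are chronically under-represented on conventional
maps, yet they are exactly the soils that deform under forestry machinery
and export sediment, nutrients and mercury to surface waters when rutted.
Terrain indices computed from a high-resolution (2 m) LiDAR elevation model
can predict where the groundwater table sits close to the surface, but no
single index or threshold works across gradients in climate, soils and
topography. `wetmapr` implements the combined approach: derive a *stack* of
hydrologically informed indices at many thresholds and scales, then let a
supervised classifier trained on field plots learn which combination marks
a wet soil in each landscape, producing binary and probabilistic wet/dry
maps with chance-corrected accuracy assessment.

## The index stack

All indices derive from a conditioned DEM via single- or multi-direction
flow routing.

**Hydrological conditioning** (`condition_dem`). Raw LiDAR DEMs contain
closed depressions (real or artefactual) that interrupt modelled flow. We
first *breach* each single-cell pit along the least-total-lowering path to
lower ground, capped at `max_breach_length` (default 200 cells), then run a
priority-flood *fill* with an epsilon gradient (default 0.001 m per step)
for whatever remains, including flats. Breaching only lowers cells and
leaves no filled volume behind thin barriers; filling only raises, and only
where a breach within the cap is impossible. The epsilon is two orders of
magnitude below the DEM's ~0.3 m vertical error. After conditioning every
valid cell either lies on the border or has a strictly lower 8-neighbour,
which the test-suite checks by exhaustive scan. The least-cost-breach +
epsilon-fill pairing is this package's own conditioning recipe; it targets
the same "hydrologically correct" end state as the multi-step breaching
workflows used operationally on national DEMs.

**D8 routing** (`d8_pointer`, `d8_accumulation`). Each cell drains to its
steepest-descent neighbour (drop over distance, distance $\sqrt2$ on
diagonals). Ties are broken in the fixed order E, NE, N, NW, W, SW, S, SE
so routing is deterministic. Accumulation counts the cell's own area — on a
2 m grid 1 ha is exactly 2500 cells — and is computed in topological order;
a cycle aborts. Streams are the cells whose contributing area reaches an
initiation threshold (inclusive `>=`, which makes stream networks exactly
nested across thresholds). The default threshold list is 0.5, 1, 2, 5, 10,
15 and 30 ha; merged with rasterized lake/river polygons these give the
*source layers* of surface-water cells.

**Cartographic depth-to-water** (`dtw`):
$$\mathrm{DTW} = \Big[\sum_i \frac{\mathrm{d}z_i}{\mathrm{d}x_i}\,a_i\Big]\,x_c$$
the least accumulated slope cost over 8-connected paths between a cell and
any surface-water cell, with $a = 1$ cardinal, $\sqrt 2$ diagonal, $x_c$
the cell size. It is computed by a multi-source shortest-path expansion
from all water cells at once; each step is charged the slope of the cell
being entered, so water-cell slope never counts and a cell's own slope
does. Slope is Horn's 3×3 tangent (one-sided at edges). Water cells have
DTW 0; paths cannot cross nodata.

**Elevation above stream** (`eas`): the elevation difference between a cell
and the first water cell on its downslope D8 path; nodata where the path
leaves the grid dry. Computed per source layer, like DTW.

**Topographic wetness index** (`twi`, `twi_at_resolution`):
$\mathrm{TWI} = \ln(A_s/\tan\beta)$ with $A_s$ the D-infinity specific
catchment area. At 2 m the index is noisy and scale-inappropriate, so it is
computed on 24 m and 48 m block-mean aggregations of the DEM and placed
back onto the 2 m grid by nearest neighbour. The slope tangent is floored
at 0.001 so flats stay finite (the index is undefined at slope zero).
D-infinity uses Tarboton's triangular facets restricted to fully-in-grid
neighbours; cells with no in-grid downslope facet are sinks, and the total
area leaving the grid is returned as a conservation audit (it must equal
the valid grid area, and the tests require agreement to 1e-6 relative).

**Local roughness** (`focal_stdv`): the population standard deviation of
elevation in moving windows of 5, 10, 20, 40 and 80 cells, truncated at
edges. Even windows have no centre cell; the extra row/column is anchored
south/east.

**Fixed-threshold baseline** (`sfa_baseline_map`): the operational
single-threshold product used for comparison — wet iff DTW from a 1 ha
source layer is ≤ 1 m (inclusive).

Large rasters can be processed per tile with `tile_scheme` /
`tile_and_mosaic` (default 2 km overlap); the mosaic keeps, per cell, the
value from the tile where the cell lies deepest, so edge artefacts confined
to the overlap vanish. Tiling is an option for memory-bound runs, not a
requirement.

## From rasters to a classifier

`sample_rasters` reads each layer at the cell containing each plot
coordinate (floor convention; plots on nodata in any layer are dropped and
counted). The five observed soil-moisture classes collapse to a binary
label (`recode_binary`): dry + mesic → "dry" (groundwater deeper than
about a metre), mesic–moist + moist + wet → "wet" (within a metre at least
seasonally) — the grouping relevant for trafficability. With the national
class frequencies (6/54/27/10/3 %) this is a 60/40 split.

Near-duplicate layers are removed by an iterative filter
(`collinearity_filter`): while any pair of features has |Pearson r| > 0.9,
the member of the worst pair with the larger mean absolute correlation
against the remaining features is dropped; the drop sequence is reported.
Raw plot coordinates are metadata — the sampled `X_Coord`/`Y_Coord` layers
are the coordinate features.

Four learner families are supported (`tune_and_train`): random forest,
RBF-kernel support vector machine, single-hidden-layer neural network, and
Gaussian naive Bayes. Each is tuned by grid search with 10-fold
cross-validation; the selection metric is Cohen's kappa, the same statistic
used for final evaluation:
$$\kappa = \frac{p_o - p_e}{1 - p_e},\qquad
  p_e = \sum_i \frac{\text{row}_i\,\text{col}_i}{N^2}.$$
The data are split 75/25 (simple random split, seeded) before tuning;
evaluation reports the confusion matrix, overall accuracy, per-class "wet"
and "dry" accuracies (sensitivity/specificity), and kappa. Probabilities
are thresholded at 50 % everywhere; no cost-sensitive reweighting is
applied. Features are z-scored (training statistics) for the SVM and the
neural network only; trees and naive Bayes see raw values. Default grids:
`mtry` ∈ {2, 4, 8, 16} with 500 trees; SVM cost 0.1–100 by decades and
gamma 0.001–1; hidden sizes {5, 10, 20} with weight decay {0, 0.001,
0.01}; naive Bayes has a single Gaussian configuration (no kernel-density
variant is available in the underlying library). Variable influence is
measured by permutation importance: the mean drop in accuracy over
re-shuffles of one column at a time.

`predict_map` assembles the per-cell feature matrix in the model's stored
column order and emits a probability surface (percent) and its 50 %
thresholding; nodata propagates.

## The synthetic landscape and what it shows

No national inventory plots or LiDAR tiles ship with the package, so a
seeded generator supplies both sides of the problem with known ground
truth.

* `make_dem` builds terrain fixtures: an inclined plane (already drained),
  a V-valley with a single thalweg, a Gaussian hill, a plane with an exact
  count of single-cell pits, and a *composite landscape* of seeded smooth
  bumps and hollows on a regional tilt. `demo_landscape()` fixes the
  composite at 600 × 600 cells (1.2 × 1.2 km at 2 m): large enough —
  144 ha — that even a 30 ha stream initiation threshold produces a
  network, which a smaller desk-scale grid cannot.
* `make_plots` draws plot locations uniformly (cell centres plus 7.5 m
  Gaussian jitter, the midpoint of a 5–10 m GPS error band) and labels them
  Bernoulli from $P(\text{wet}) = \mathrm{logit}^{-1}(\beta_0 + \beta_1
  \cdot \mathrm{DTW})$ on the *true* depth-to-water. The defaults
  $\beta_0 = 2.2$, $\beta_1 = -0.6\,\mathrm{m}^{-1}$ put the 50 % crossing
  near 3.7 m and were fixed once, from the DTW distribution of the demo
  landscape, to reproduce the ~40 % wet prevalence observed in national
  inventory data. The five-class field is then assigned *within* each
  binary group by ranking the latent probability, with conditional
  frequencies renormalized from the national marginals — so the recode of
  the five classes always equals the drawn binary label, and the marginals
  come out near 6/54/27/10/3 % when prevalence is near 40 %.

On this landscape the full pipeline (`run_pipeline`) demonstrates the
method's central claim with known truth: the tuned random forest's
held-out kappa strictly exceeds that of the fixed 1 ha / ≤ 1 m baseline
map, and permutation importance ranks the label-defining DTW layer first.
The test suite asserts both, along with the property checks listed below.

What the generator does *not* emulate: real stream-burning errors, culverts
and road embankments, open-water masking, spatially structured label noise,
deposit-dependent drainage, and runoff climatology (ancillary rasters enter
the stack only if the user supplies them). Passing the synthetic checks
shows the machinery is correct and the workflow recovers a known
monotone wetness–DTW relation; it does not certify accuracy on any real
landscape.

## Numerical choices

* DTW step cost uses the entered cell's slope (outward from water), not an
  average of the two cells; documented so the exhaustive-path oracle in the
  tests matches exactly.
* TWI slope floor 0.001 (tangent); cells with non-positive catchment area
  are nodata.
* D8 ties broken in fixed compass order; stream test inclusive; flow
  accumulation counts the focal cell.
* Conditioning epsilon 0.001 m; a pit whose cheapest breach exceeds
  `max_breach_length` is filled instead. Conditioning is idempotent up to
  epsilon.
* Mosaic rule: farthest-from-tile-edge wins; edges coinciding with the grid
  boundary are exempt.
* The ASCII-grid writer prints 17 significant digits, so round trips are
  value-identical for doubles. GeoTIFF is not read or written by this
  build; grids in geographic (degree) coordinates are rejected because
  every index here is metric.

## Problem sizes used in validation

The shipped checks run the demo landscape at 600 × 600 cells with 5000
synthetic plots (about 3800 survive sampling across all 23 layers; plots
whose flow path leaves the grid without meeting a high-threshold stream
lack EAS there and are dropped, as logged). The whole suite, including one
tuned random forest, completes in under two minutes on a single core;
exhaustive oracles (all simple paths, path tracing, relaxation to fixed
point) are confined to grids of at most 10 × 10.

## Known limitations

* One raster format (ESRI ASCII grid), one CRS model (projected, metres);
  no reprojection.
* EAS is undefined (nodata) where the D8 path exits the grid before
  meeting water — frequent for sparse high-threshold source layers on
  small grids.
* Naive Bayes is Gaussian-only; there is no kernel-density variant.
* The composite landscape is smooth; classifiers that exploit fine-scale
  roughness may rank `STDV` layers lower here than they would on real
  LiDAR terrain.
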