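---
title: "Methods: corridor modeling and prioritization in climcorridor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: corridor modeling and prioritization in climcorridor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climcorridor)
```

## The model

climcorridor implements a regional corridor-prioritization workflow for
climate adaptation: species in fragmented lowland habitat are assumed to
need routes to high-elevation forest that can act as climate change
refugia. The workflow makes three modeling commitments:

1. **Structural, species-agnostic connectivity.** Movement cost is a
   property of land cover (and forest condition), not of any single focal
   species. Conductance — the inverse of resistance — is assigned per
   land-cover class from a lookup table, and forest conductance is
   multiplied by a biomass modifier `m = min(b, 100) / 100` (b in Mt C per
   cell) so that degraded, low-biomass forest conducts less. Conductance is
   deliberately *not* adjusted for topography (steep routes are acceptable,
   even useful, for long-term upslope range shifts) nor for climate
   dissimilarity along the route.
2. **Least-cost paths on a lattice.** The conductance raster becomes an
   8-connected graph; the edge between neighboring cells i and j costs
   `d(i, j) / ((c_i + c_j) / 2)`, center-to-center distance divided by the
   arithmetic-mean conductance (cell size for rook moves, `sqrt(2)` times
   that for diagonals). A least-cost path minimizes summed edge cost, so
   its accumulated cost is a resistance-weighted distance in meters.
   Zero-conductance cells (open water, built-up, zero-biomass forest under
   the default lookup) are hard barriers with no incident edges, not
   merely expensive cells.
3. **Distance-from-origin prioritization.** Corridor quality is
   multidimensional (short, protected, intact, biodiverse, linking large
   and topographically diverse habitat). Rather than a weighted sum, the
   variables are standardized, screened for collinearity, and decomposed
   by PCA; each corridor's priority index is its Euclidean distance from
   the origin in the space of the first three components. The index is
   direction-blind by construction: a corridor extreme on the unfavorable
   side of a component also scores high. We implement the definition
   exactly as stated and guard against pathological sign structure with a
   synthetic-recovery test (a corridor built to dominate every
   priority-favoring variable must attain the maximum index), not by
   re-weighting.

## Pipeline stages and their parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `min_start_area`, `min_end_area` | 5 | km² | minimum habitat size worth linking at regional scale |
| `lowland_elev_max` | 500 | m | mean-elevation ceiling for lowland start reserves |
| `highland_elev_min` | 1500 | m | mean-elevation floor for upper-montane end patches |
| `integrity_min` | 6 | index (0–10) | forest-integrity cutoff for end-patch cells |
| `hex_spacing` | 3000 | m | pitch of the hexagonal end-point lattice |
| `k` | 5 | — | end points paired per start node |
| biomass cap | 100 | Mt C | saturation of the forest conductance modifier |
| buffer half-width | 1000 | m | corridor swath (2 km width), a rule-of-thumb minimum for long-term gene flow |
| `rho_threshold` | 0.7 | — | absolute Spearman cutoff of the collinearity screen |
| `n_components` | 3 | — | retained principal components |
| class cuts | 2, 4 | index units | low `[0, 2)`, medium `[2, 4]`, high `(4, Inf)` |

Boundary conventions are inclusive on the side that admits a candidate:
area ≥ 5 km², mean elevation ≤ 500 m (start) and ≥ 1500 m (end); priority
class "2–4" is inclusive at both ends, forced by the wording of the
low/high cuts (`< 2`, `> 4`). Area is always computed from polygon
geometry in the working planar system; the `reported_area` attribute only
feeds the unreported-area cleaning rule.

Two thresholds are package choices where the method leaves them open. The
integrity cutoff for "medium-or-better" forest is a named configuration
value, 6 on the synthetic 0–10 scale, with no claimed provenance — users
of real integrity layers must set their own. The hexagonal pitch of
3000 m was chosen once so that a patch at the 5 km² threshold receives a
single representative point (a hexagonal cell at pitch s covers
(sqrt(3)/2)·s² ≈ 7.8 km²) and the point count grows roughly linearly with
patch area thereafter.

## Geometry and zonal conventions

The package runs on plain planar rasters (matrices plus origin and cell
size) and coordinate-matrix polygons; it never reprojects, and all
synthetic data use a metric Cartesian system. Conventions that matter for
reproducing numbers:

- **Cell-center rule everywhere.** A raster cell belongs to a zone when
  its center lies inside the region. This applies to zonal means and
  ranges and, by extension, to the overlay statistics: percent protection
  is the share of a region's cell centers inside the union of reserves
  (union first, so overlapping reserves are never double counted);
  overlap counts require at least one shared cell center; countries
  crossed and the primary country come from assigning the buffer's cell
  centers to country polygons, ties broken by the lowest country id. The
  rule is simple, fast, and exactly checkable against brute-force loops;
  its discretization error shrinks with cell size and the tests pin the
  convention on constructed cell-aligned geometries where the cell count
  equals the analytic area exactly.
- **Buffers are distance predicates.** The 1000 m corridor buffer is the
  set of points within the half-width of the polyline. Containment is
  evaluated exactly from point-to-segment distances (with an early-exit
  scan at the threshold); the explicit outline used for export, and the
  standalone buffer area, are traced on a fine auxiliary grid (default
  1/100 of the half-width) whose resolution is a documented argument.
  Pipeline ratios such as percent protection never depend on that
  auxiliary resolution because numerator and denominator are both
  cell-center counts on the working grid.
- **Exact convex clipping.** Marine reserves are clipped to the land
  extent, and synthetic countries are built as Voronoi cells, with
  Sutherland–Hodgman clipping against rectangles and half-planes — exact
  operations on convex clip regions, no tolerance parameters.
- **Interior points.** Each start node and patch gets a representative
  point guaranteed strictly inside its polygon (midpoint of the longest
  interior interval of a scanline nudged off vertex levels; largest part
  for multi-part geometries), which matters for C-shaped reserves whose
  centroid falls outside.

## Numerical choices in pathfinding

Dijkstra runs once per start node (one shortest-path tree serves all of
its k paired end points). Equal-cost relaxations keep the
lexicographically smallest (row-major) predecessor cell, making extracted
polylines byte-reproducible across runs and platforms. Start or end
locations that fall on a barrier cell are snapped to the nearest passable
cell within a 5-cell radius (Euclidean distance, then row-major index as
the tie-break); beyond that radius the pair is an error. Unreachable
pairs inside a batch are recorded with an explicit status rather than
failing the run, and every downstream table keeps one row per pair — no
silent drops. When fewer than k end points exist, all are used with a
warning.

The k-nearest pairing uses Euclidean distance with end-point id as the
tie-break. Paths start at the representative point of the reserve, not
its boundary.

## The synthetic landscape

`generate_landscape()` produces the full input bundle from a config and a
seed, deterministically. It emulates the *structure* the pipeline
assumes, not any real region:

- **Terrain**: a west lowland plain (the first `lowland_fraction` of the
  gradient) rising linearly to an east highland massif, plus
  Gaussian-smoothed noise (amplitude 3% of the ramp, smoothing sigma of 3
  cells), rescaled exactly to `[0, elev_max]`.
- **Land cover**: the `forest_fraction` share of cells with the highest
  score (smoothed noise plus a strong highland bonus) becomes forest —
  clumped patches, highland forest guaranteed — with a two-column
  non-forest gap at mid-slope that corridors must cross; the remaining
  cells are a cropland-dominated mosaic including scattered water and
  built-up barrier cells.
- **Biomass**: `Normal(biomass_mean, biomass_sd)` truncated at zero on
  forest cells, exactly zero elsewhere; the default mean 60 / sd 30
  (Mt C) yields both zero-biomass forest (barriers under the modifier)
  and cells above the 100 Mt C cap, so both ends of the modifier are
  exercised.
- **Integrity**: a 0–10 index around 8 on forest with smoothed spatial
  variation (so contiguous low-integrity pockets fall below the default
  cutoff), around 2 off-forest.
- **Reserves**: convex blobs with WDPA-like attributes. The first slots
  are fixed pathological fixtures — a byte-identical duplicate pair, a
  "proposed" record, a marine reserve straddling the eastern grid edge
  whose land portion is below 5 km², a 'UNESCO-MAB Biosphere Reserve'
  designation, an unreported-area record, a sub-threshold (~3 km²)
  reserve, and a highland reserve above the 500 m mean — so every
  cleaning and selection rule fires on every generated table. Remaining
  records are well-formed lowland reserves (7.5–12 km²), placed with
  margins so they stay inside the grid (and are clipped to it as a final
  guarantee). KBAs are scattered blobs; countries partition the extent by
  a Voronoi tessellation.

This design makes the count arithmetic of a run fully predictable: with
`n_reserves` records, cleaning removes 4 and the start-node filters
remove 3 more, so `n_reserves - 7` start nodes emerge, each tracing
`min(k, n_end_points)` corridors. The test suite and the acceptance
script exercise this at a regional scale (300 × 300 cells at 100 m,
482 reserves, hence 475 start nodes and 2375 corridors) and run the full
metric/priority/statistics pipeline at 150 × 150 — sizes chosen so the
whole suite completes in minutes on one core while still covering every
stage at realistic densities.

What the generator does **not** emulate: real spatial autocorrelation
structure and class frequencies of any land-cover product, geodesy (no
curvature, no projection distortion), multi-resolution inputs (synthetic
rasters are generated at the working resolution; a finer option exists
only to exercise the majority-rule resampler), reserve shape complexity
(blobs are convex), and real attribute errors beyond the fixture
pathologies. Passing tests therefore demonstrate the correctness of the
algorithms and conventions, not calibration of any threshold to a real
region.

## Statistics

Spearman's rho is the Pearson correlation of mid-ranks with the
two-sided t approximation on n − 2 degrees of freedom; Kruskal-Wallis
uses the tie-corrected H with the chi-square approximation (fully tied
data return H = 0 by convention); Dunn's pairwise z uses pooled mid-ranks
with tie correction and two-sided normal p-values, Holm-adjusted across
pairs. All p-values are asymptotic — group sizes in this workflow are in
the hundreds — and the pairwise battery is gated on the omnibus test at
alpha = 0.05 (overridable). Standardization uses the n − 1 divisor; the
PCA is the eigendecomposition of the correlation structure (via
`prcomp` on z-scores), and `sum(index^2) = (n - 1) * (lambda_1 +
lambda_2 + lambda_3)` is enforced as a test identity.

Two pragmatic choices in the priority stage: variables that are constant
across corridors (possible on small landscapes, e.g. a single end patch)
are dropped with a message before standardization, since they carry no
ranking information and would otherwise make z-scores undefined; and the
collinearity screen resolves each flagged pair by a per-variable drop
rank (the overlapping-PA count and end-patch area are the designated
victims of their documented pairs), falling back to dropping the
later-listed column.

## Known limitations

- Least-cost paths are single best routes; corridor swaths, randomized
  shortest paths, and circuit-theory current maps are out of scope.
- All-pairs routing is intentionally avoided (k-nearest pairing keeps the
  computation regional-scale); corridors to the 6th-nearest and farther
  end points are never considered.
- The cell-center overlay convention undercounts features smaller than a
  cell; at the intended 100 m working resolution this is negligible for
  the km²-scale features the pipeline targets.
- The priority index inherits the direction-blindness of
  distance-from-origin scoring discussed above.
- Real-data inputs must be pre-aligned on one projected grid; the package
  validates alignment but does not resample continuous rasters or
  reproject.
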