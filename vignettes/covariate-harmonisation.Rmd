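---
title: "Harmonising gridded covariates on a 3 arc-second master grid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonising gridded covariates on a 3 arc-second master grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covgrid)
```

## The problem

Gridded population models — both top-down disaggregation of census counts
and bottom-up prediction from survey enumeration areas — consume large
collections of ancillary gridded layers ("covariates"): distance to roads
and water, land-cover class edges, nighttime radiance, built-up surface
and volume, climate normals, and so on. These layers come from sources
with wildly different resolutions, extents, formats and conventions, and
are only usable once co-registered to one fixed analysis lattice.
`covgrid` implements that harmonisation as a tested, desk-scale toolkit:
every operation in the production workflow is present, exercised on
seeded synthetic windows small enough that exhaustive oracles can verify
each step.

## The master grid

The target lattice is geographic WGS84 at 3 arc-seconds (about 100 m at
the equator). The cell size is carried internally as the exact rational
3/3600 degree; the conventional printed value 0.00083333333 is a display
truncation, and `grid_constants()` reproduces both it and the
conventional southern-edge constant −59.9999994° (the truncated-decimal
image of the exact lattice edge at −60°). Working internally with the
exact rational avoids any cumulative drift across the 432,000 columns of
the default global grid. Sub-extent windows are first class: every
window's edges must lie on the global lattice (anchored at 180° W,
84° N), so layers produced on different windows stay mutually aligned.

The landmass is defined by aggregating the terrestrial classes of a
finer land-cover product to the grid by exact cell counting and applying
an inclusive 25% terrestrial-share threshold ("at least 25%"): cells at
exactly the threshold are land. Oceans and seas are NoData; inland water
is part of the landmass. The NoData sentinel is −99999 everywhere on
disk; in memory NoData is `NA`.

Per-row cell areas use the spherical quadrangle closed form
$R_a^2\,\Delta\lambda\,(\sin\varphi_n - \sin\varphi_s)$ with the
authalic radius $R_a = 6371.0072$ km, which keeps areas consistent with
the equal-area treatment of polygons below and has error well under
0.3% against the ellipsoid — small against every tolerance in the
package and trivially checkable in closed form.

## Resampling, gap filling, climate and slope

Three resampling methods cover the sources: bilinear (continuous
fields), nearest neighbour (categorical), and exact area-average
aggregation for finer binary/fractional sources (which must be integer
subdivisions of the target lattice — the fixture contract). Bilinear on
categorical input is rejected rather than silently averaged.

Coastal gaps — cells that are land on the master grid but NoData in a
source whose own coastline disagrees — are filled iteratively: each pass
assigns to every unfilled land cell the mean (continuous) or mode
(categorical) of its valid 8-neighbours, with simultaneous (Jacobi)
updates, until no unfilled land cell remains. The 8-neighbour ring
iterated to closure is the minimal rule that guarantees completion;
categorical ties break to the smallest class code, which is arbitrary
but deterministic and documented. A landmass component with no valid
cell anywhere cannot be filled and raises an error naming the component
rather than inventing data.

Annual precipitation is the monthly sum divided by 12 and scaled by the
catalogue factor 10 at write time (raw mm are kept internally); the
annual temperature is the arithmetic mean of the available (non-NoData)
months, since missing-month handling is otherwise undefined — a cell
with no valid month stays NoData. Slope uses the Horn 3×3 operator on
geographic spacing, with the east–west metre spacing scaled by
cos(latitude) per row and one-sided differences at the window edge.

## Distance transforms

All "distance to X" covariates share one kernel: the minimum
great-circle distance (haversine, mean radius 6371.0088 km) from each
cell centre to the centre of any feature cell, in km. Cells inside
features report 0; cells outside the domain (usually the landmass) are
NoData. Two variants exist because the sources need both:

* `distance_to_features()` — distance to the nearest feature cell
  (used for water, roads, built surface);
* `distance_to_boundary()` — the feature set is first restricted to its
  boundary cells (feature cells 8-adjacent to a non-feature cell, the
  grid edge counting as outside), so interior cells of large features
  report their distance to the edge (used for land-cover classes and
  protected areas, whose sources speak of distance to the class or
  area *edge*).

The implementation prunes the candidate set to boundary cells — exact,
since the nearest feature cell seen from outside is always on the
boundary — and is required to agree with a brute-force scan over *all*
feature cells to 1e-9 km, which the suite verifies on 120×120 windows.
An empty feature set (e.g. a window without any road) follows a
configurable policy: NoData by default, zero-filled where the
production convention ships zeros (roads).

One subtlety: for the boundary variant, annual nesting of protected
areas implies distances can only shrink over years *off* the protected
areas; inside a growing area the edge can move away from a cell. The
invariant suite therefore checks distance monotonicity on off-feature
cells and presence nesting everywhere.

## Water masks

The water-coverage fraction is the exact count-aggregation of the fine
permanent-water class, restricted to the landmass (ocean and coastline
cells removed). Rather than a single majority mask, a family of binary
masks is emitted at the seven thresholds 25, 50, 60, 75, 80, 85 and
90% of cell coverage, inclusive (≥), consistent with the landmass
rule; the family is nested by construction. The derived
distance-to-inland-water covariate uses the 75% threshold — a stated
choice, not the family minimum. Coastline features are ocean cells
8-adjacent to land (inland water is land and never coastline), which is
the minimal formalisation of a coastline on a cell lattice.

## Land-cover reclassification

The 22 source land-cover classes are aggregated to nine covariate
classes (cultivated 11, woody/tree 40, shrub 130, herbaceous 140,
sparse vegetation 150, aquatic vegetation 160, artificial surface 190,
bare 200, water/snow/ice 210). The authoritative 22→9 table is not
published; `default_reclass_map()` reconstructs it by legend family and
every entry point accepts a user-supplied two-column table instead
(`read_reclass_map()`), so the mapping is config, not code. Note the
numeric collision between legends: source code 130 (a grassland class)
maps to covariate class 140, while covariate class 130 means shrub —
the mapping applies to the *source* legend only and is not meant to be
re-applied to its own output. Per year, the pipeline runs reclassify →
nearest-neighbour downsample → majority gap fill → nine binary layers →
boundary-distance transform; the nine binaries partition the valid
cells, which the suite asserts.

## Protected areas

Point records are converted to polygons by geodesic buffering at 70 m
radius (64 vertices; vertex distances verified to 0.1%, polygon area to
0.5% of the circle). Rasterisation is cell-centre containment — chosen
over fractional rules because it admits an exact point-in-polygon
oracle. Annual presence is cumulative: the layer for year *y* contains
every area with status year ≤ *y*, so presence masks are nested over
years. Marine and terrestrial subsets are rasterised separately, then
merged as (terrestrial ∪ marine) ∩ landmass — marine areas contribute
exactly their onshore cells. Two IUCN groups are kept: category 1
(strict nature reserves and wilderness areas) and categories 2–6;
records with unknown category should be assigned to the broader 2–6
group upstream. Eight years × two groups yield sixteen presence
mosaics, each converted to a boundary-distance covariate. Invalid
geometries are dropped with a log message, mirroring the production
treatment of features with missing geometries.

## Nighttime-lights outlier filter

Annual radiance composites already mask clouds, aurora and biomass
burning, but abnormally bright cells persist near gas flares and
volcanoes. Around each listed site the filter collects the valid
observations in a square window (default half-width 10 cells) and
iteratively removes the largest observation, recomputing the standard
deviation of the remainder, until successive standard deviations differ
by less than 0.2 (strict comparison). The observation removed in the
converged iteration is restored — convergence means its removal changed
nothing material. Conventions fixed here because no published statement
decides them: the standard deviation is the population form (divide by
*n*); removed values are *capped* to the maximum retained observation
rather than deleted, preserving spatial completeness (a config flag
switches to NoData); windows are processed in site order with caps
applied cumulatively; lists shorter than three observations pass
through unfiltered. The filter applies to the earlier product version's
years (2015–2021); later years (2022–2023) pass through unfiltered, as
in the released catalogue. Standardisation itself is bilinear
resampling, zero-filling NoData land cells with centres between 75° N
and 84° N (above the source's coverage), and NoData outside the
landmass.

## Building footprints: BCB and PIB

Two allocation rules turn footprint polygons into per-cell metrics:

* **BCB (Building Centroid Based)** — each building belongs wholly to
  the cell containing its centroid; a straddling building contributes
  all of its area, perimeter and count to that one cell. Suited to
  counts and per-building statistics.
* **PIB (Pixel Intersected Based)** — each building is clipped to every
  cell it intersects; each cell receives the clipped piece's area and
  outline length, and counts every intersecting building once. Yields
  a continuous surface with area allocated where it physically lies.

Per-cell statistics are count, total/mean area, total/mean perimeter,
the variation coefficients (population standard deviation over mean,
NoData below two observations), and density (count per km² of geodesic
cell area). For PIB the mean and variation coefficient are computed
over clipped pieces by default; whether piece or whole-building values
are intended is genuinely ambiguous in the method's description, so a
`stats = "whole"` switch provides the other reading. Centroids on a
cell edge follow the half-open cell convention (west/north edges
inclusive), making assignment deterministic.

Polygon areas are evaluated on the authalic sphere with edges treated
as straight lines in lon/lat space, integrating the spherical area
element in closed form per edge. This choice is deliberate: cell
rectangles and clip cuts live in lon/lat space, so the area functional
is *exactly* additive under clipping, and the conservation law — the
PIB cell sums equal the footprint totals — holds to machine precision
rather than to a sliver tolerance. Perimeters and road lengths are
per-edge haversine sums. Cell edges are always computed directly from
the grid origin so adjacent cells share them bit-exactly; this matters
for features lying exactly on a window or cell edge.

Roads are clipped per segment to the cells they cross; per cell the
package reports total great-circle length (m), the number of distinct
road features (multi-segment features count once), density (m per km²)
and binary presence. An empty road network produces all-zero layers,
not NoData — the production convention for territories the road source
does not cover — and the road-distance covariate zero-fills in that
case for the same reason.

## Built-up fusion and height imputation

The built-up stack carries surface (m²) and volume (m³) at the epochs
2015/2020/2025/2030 plus a single-epoch (2018) mean-height layer.
Auxiliary evidence — PIB footprint areas per source and a settlement
fraction × cell area — is combined per cell by *maximum*, clipped to
the cell area; max is used because overlapping sources describe the
same buildings and summing would double-count. A cell is *missing* iff
the 2030 surface epoch reports zero or NoData there while some source
reports evidence; missing cells receive the evidence surface at all
four epochs. Fusion is monotone (never decreases any value), touches
exactly the missing set, and is idempotent.

Volume needs a height. Every volume-missing cell gets a Nadaraya–Watson
estimate $\hat h = \sum_i K(d_i/b)\,h_i / \sum_i K(d_i/b)$ over nearby
cells with known positive height, with great-circle distances $d_i$, a
Gaussian kernel, bandwidth 1000 m and search radius 5 km. Kernel
family, bandwidth and radius are not specified anywhere upstream; these
defaults are declared package choices (a smooth kernel over a radius an
order of magnitude above the cell size, so estimates vary smoothly
across a settlement), all configurable. When no donor lies within the
radius the window mean of known heights is used, and failing that a
default height of 5 m — a typical low-rise value — so added volume is
never silently zero. The imputed volume is height × evidence surface at
every epoch, so V/S at added cells equals the imputed height exactly, a
property the suite asserts to 1e-9. The non-residential variant runs
the same logic against footprints whose type tag is in a configured
non-residential set (defaults: "public", "industrial", "outbuilding";
the full production tag list is supplied as configuration, not code).

## Synthetic fixtures

Every input is generated, seeded, at window scale (default 120×120
cells, ~0.1°, chosen so brute-force oracles run in seconds): a
smoothed-noise coastline hitting the configured land share on the fine
lattice (the 25% coastline rule then yields a somewhat larger landmass
share, as it should); inland-water blobs; a 21-class land mosaic over
land with the water class as ocean; an elevation field whose own
coastline deliberately disagrees with the landmask to create coastal
gaps (but always covers every landmass component somewhere, as real
elevation sources do); lognormal radiance with spikes of 100× the local
background injected at listed sites; rotated-rectangle footprints with
roughly 30% of centroids placed within a fraction of a cell of an edge
so straddling occurs by construction; random-walk road polylines;
protected areas with status years spanning 2010–2022, about 20% point
records and a quarter marine; and a built stack with a configured
fraction of truly built cells zeroed across all epochs, with the hole
set emitted as ground truth. Generators are pure functions of the
configuration; truth side channels are consumed only by tests, never by
pipeline code.

What the fixtures do *not* emulate is statistical realism of global
geography: real class adjacency structure, real footprint shape
distributions, registration error between sources, or the native
formats of the archives. Passing tests therefore demonstrate the
correctness of the harmonisation operations and their invariants, not
the fidelity of any real covariate value.

## Numerical choices and limitations

* Distances: haversine on the sphere, R = 6371.0088 km. Areas: authalic
  sphere, R = 6371.0072 km. Both choices give clean closed-form
  oracles; ellipsoidal refinements would shift values by well under a
  percent and can be layered behind the same interfaces.
* Rasters are exchanged as single-band float32 GeoTIFF (written by the
  package's own minimal codec: uncompressed, WGS84 geokeys, NoData
  −99999 both as a tag and as the sentinel value) with a JSON sidecar
  carrying the grid spec and layer semantics, or as plain-text ESRI
  ASCII grids. Vectors travel as GeoJSON. Integer-valued layers
  round-trip bit-exactly; continuous layers to float32 precision.
* Pipeline runs use a 120×120 default window; the full synthetic run
  emits 191 files covering all 73 catalogue covariates across their
  years and passes the grid-conformance QA (lattice alignment, 3″
  resolution, sentinel, CRS) with zero violations.
* Mosaicking resolves overlaps by list order (first tile wins) — a
  deterministic stand-in for the source-specific precedence rules of
  real mosaics.
* Country/territory delineation, native archive formats, HPC-scale
  execution and the population model that consumes these covariates
  are all out of scope.
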