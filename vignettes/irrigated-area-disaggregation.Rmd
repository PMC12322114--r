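---
title: "Hierarchical dasymetric disaggregation of regional irrigated-area statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical dasymetric disaggregation of regional irrigated-area statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Annual statistics of *area actually irrigated* (AAI) are reported for
administrative regions (NUTS2, sometimes only NUTS1), while hydrological
and crop models need the irrigated area of each crop on a kilometre grid,
every year. `irrigrid` implements a dasymetric disaggregation of those
regional statistics onto a 1-km crop-type grid, guided by two ancillary
raster layers: the *area equipped for irrigation* (AEI, the
infrastructure that makes irrigation possible at all) and per-crop
growing shares within each cell's utilized agricultural area (UAA).

The method has three blocks:

1. **Regional disaggregation.** Where annual totals exist only at NUTS1,
   they are split to NUTS2 with fixed reference-year proportions
   `P_NUTS(n) = 100 * TAAI(n) / sum_n TAAI(n)` computed from the 2010
   census crop sums. The NUTS2 total is then split across the `C = 16`
   crop classes with fixed proportions
   `P_crop(c) = 100 * AAI(c) / sum_c AAI(c)`, giving annual regional
   crop targets `AAI(c, y) = P_crop(c)/100 * TAAI(y)`. Both proportion
   sets are assumed constant over the mapped years because the crop
   breakdown is only reported for the reference year. The crop *sum* is
   used as the denominator (not any separately reported total), so the
   proportions always close to 100%.

2. **Equipped-area harmonization.** A fine-resolution AEI snapshot (2005)
   and a coarse-resolution snapshot for the mapping reference year (2010)
   are combined: the fine map is block-summed to the coarse grid, the
   per-coarse-cell percent change ratio is formed, and ratio and fine map
   are both resampled bilinearly to the 1-km target grid and multiplied,
   yielding a fine-resolution 2010 equipped-area map
   `TAEI_1km = P_TAEI/100 * TAEI_1km,2005`.

3. **Grid allocation.** Per cell, crop equipped area is
   `AEI(c) = CGS(c) * TAEI` (crop growing share times total equipped
   area). Summing `AEI(c)` over each region gives the denominator of the
   zonal calibration coefficient `P_AAI(c, y) = 100 * target / AEI_region`,
   applied uniformly to all cells of the region:
   `AAI(cell, c, y) = AEI(cell, c) * P_AAI/100`. Conservation of the
   regional targets is exact by construction. Two post-processing steps
   follow, in this order: a per-cell capacity cap (where the crop-summed
   AAI exceeds the cell area of 100 ha, all crops in that cell are
   scaled by the same factor so the total equals exactly 100 ha), then a
   per-crop clamp to the crop growing area with the rainfed remainder
   `RF = GA - AAI`, so `AAI + RF = GA` holds exactly with `RF >= 0`.

## Numerical and design choices

**Change-ratio orientation.** The ratio as conventionally printed is
`100 * old/new` (2005/2010), yet it is used as a multiplier on the 2005
map to estimate 2010 — the two are mutually inconsistent (their product
has 2005²/2010 semantics). The package defaults to the *inverted*
orientation (`100 * new/old`), because only that choice makes the
harmonized map's coarse block sums agree with the coarse 2010 input —
a property asserted in the tests. The literal `as_printed` orientation
is retained behind `ratio_orientation` for reproduction.

**Zero denominators.** Coarse cells with no equipped area in the
denominator year get ratio 0 (flagged), hence no harmonized
infrastructure and no allocated irrigated area. Regions whose equipped
area for a crop is zero while the target is positive get coefficient 0;
the stranded target mass is reported as *unallocated* in diagnostics
rather than forced into other cells.

**Bilinear edge rule.** Outside the outer lattice of source cell
centres, coordinates are clamped to the boundary centres (edge
replication). This avoids nodata fringes at the rim; the interpolation
method itself fixes only the interior behaviour. Any nodata value among
the four contributing neighbours makes the output cell nodata, even at
zero weight — conservative, and only relevant where inputs have holes.

**Capacity cap before clamp, no redistribution.** The cap and the
growing-area clamp are applied in the order the product definition
narrates them. Mass clipped by either step is *not* redistributed to
other cells (nothing in the method's definition licenses that); it is
surfaced in diagnostics so the conservation loss is measurable. In
capped regions the regional sums consequently fall short of the targets
by exactly the clipped mass.

**Uncapped calibration coefficients.** Coefficients above 100% are
possible (the annual target can exceed the fixed-year equipped area) and
are not clipped; AAI ≤ AEI is an expectation of the data, not an
enforced constraint, so a violation warns rather than fails.

**UAA output layer.** The written `UAA_{year}.tif` follows the product
identity UAA = Total irrigated + Total rainfed, i.e. the crop-summed
growing area. When cell crop shares sum to less than 1 this is smaller
than the weight-derived per-cell UAA (which remains available in the
build result and is the basis of the 100-ha interpretation of cell
weights, capped at 100%).

**Flagged regions.** A NUTS1 unit with no usable reference data splits
its total evenly across its children (the even-split rule stated for
missing census data, extended to the all-zero case); a NUTS2 unit with
all-zero crop shares but a positive annual total reports the total as
unallocated instead of inventing a crop distribution.

## The synthetic world

Real inputs for this method are continental data products; the package
instead ships a generator that emulates their statistical structure with
known per-cell ground truth, so the full pipeline has an exact recovery
oracle.

Construction (all randomness from one master seed, split into
per-component streams so, e.g., survey sampling never perturbs the
world): regions are rectangular tiles (vertical NUTS1 bands, horizontal
NUTS2 sub-bands); fine equipped area is uniform on [5, 55] ha per 1-km
cell; the coarse 2010 snapshot is an exact block-sum multiple of the
fine 2005 map (constant global ratio 0.8 by default — the regime where
bilinear resampling of the ratio field is exact — or a smooth planar
field); cell weights are uniform on [60, 110]% (exercising the 100%
cap); crop shares are a symmetric Dirichlet(0.8) scaled by a uniform
[0.6, 0.95] total so per-cell sums stay below 1; each region × crop has
one irrigation fraction `p` on [0.05, 0.85] (the within-region
uniform-percentage assumption made exactly true), and yearly dynamics
multiply all crops of a NUTS1 unit by a common factor on [0.6, 1.1] so
the fixed reference-year proportions are exactly correct. These ranges
were chosen once as plausible magnitudes for irrigated European
landscapes (equipped area well below cell area, agricultural cells
mostly cultivated) and so that the unconstrained allocation stays below
the 100-ha cap unless the cap-trigger option deliberately scales one
designated cell's equipped area above it. The regional tables are then
*derived by aggregating the truth*, which makes the bundle
self-consistent to machine precision.

The ground-truth harmonized equipped-area map is computed with an
independent scalar brute-force bilinear interpolation, not with the
package's vectorized resampler, so the round-trip test is a genuine
dual-route check.

What the generator does **not** emulate: real European geography and
crop frequencies, non-nesting arc-minute source grids (an integer
coarse/fine nesting of 8 replaces them; a half-cell `target_offset` mode
exercises true interior bilinear weights), spatial heterogeneity of the
irrigation fraction within a region (the method itself assumes it away,
and the generator offers no heterogeneous mode, so recovery tests say
nothing about that error source in real data), survey stratification
weights, or reporting noise in the regional statistics. Passing the
recovery test therefore shows the implementation inverts its own model
exactly — not that the model matches real irrigation patterns.

Survey emulation: one point per sampled cell at the cell centre, crop
assigned by the cell's share distribution, irrigated with probability
equal to the crop's true irrigated fraction of its growing area in that
cell; irrigated points carry water-management code 1, others code 5,
all with primary land-use code U111.

## Validation statistics

The survey comparison aggregates both sides to square blocks: the point
side as `100 * irrigated points / total points` per block, the raster
side as `100 * irrigated area / block area` (partial edge blocks use the
covered area). Pairs present on both sides with both percentages at or
above 0.3% enter a per-crop Pearson correlation and OLS slope (side b on
side a), with two-sided p from the correlation's t statistic on n − 2
degrees of freedom. Choices worth noting:

- The 0.3% boundary is **inclusive** (the verbal rule is stated both as
  "below excluded" and "greater than retained"; inclusive was chosen and
  the threshold is configurable).
- Water-management code 2 (*potential irrigation*) is **not** counted as
  irrigated by default; the source material is itself inconsistent on
  this, so it is an explicit `include_potential` flag rather than a
  resolved decision.
- Points on shared block edges belong to the block to their lower-left
  in index space (half-open intervals).
- With several survey years, per-year block values are pooled *after*
  aggregation by default; pre-pooling is available (`pool = "before"`).

The two block percentages estimate the same field only where the true
irrigated fraction varies *between* blocks. In a world with few large
regions the fraction is constant within each region, so the point side
varies only by binomial noise and correlations are weak by construction
— `analysis/03_validate.R` shows both this regime and a well-powered
self-consistency design (regions coinciding with blocks, uniform
per-cell fraction, exhaustive one-point-per-cell survey) where per-crop
r exceeds 0.9.

## Problem sizes and runtime

All shipped tests and scripts run on worlds of at most 64 × 64 cells
(coarse factor 8), 16 crops and 3 years — a scale at which the full
pipeline completes in seconds on one CPU while still exercising every
code path (hierarchical split, resampling, calibration, cap, clamp,
survey comparison). The pipeline itself is resolution-agnostic; memory
grows linearly with cells × crops × years.

## Known limitations

- Planar grids only; no geographic (arc-minute) grid support and no
  area-weighted (conservative) resampling alternative to bilinear.
- The GeoTIFF codec is deliberately minimal: single band, uncompressed
  IEEE floats, classic TIFF, pixel-is-area, one projected CRS key.
  Files from other producers that use tiling, compression or integer
  samples are refused rather than misread.
- No irrigation-priority ranking between crops: allocation is driven by
  infrastructure and growing shares alone, so the method cannot
  concentrate irrigation on high-value crops beyond what the regional
  crop targets impose.
- Interaction of the 100-ha cap with regional conservation is only
  diagnosed (clipped mass per region), not corrected.
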