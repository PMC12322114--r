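# irrigrid

Annual, crop-specific irrigated-area mapping at 1-km resolution by
hierarchical dasymetric disaggregation of regional statistics.

## The problem

Regional surveys report how much cropland was actually irrigated (AAI)
per administrative region and year, but not *where* within the region or
*which crop*. Gridded maps of irrigation infrastructure (area equipped
for irrigation, AEI) and of crop growing shares exist, but at mixed
resolutions and reference years. `irrigrid` combines the two: it
harmonizes a fine 2005 AEI snapshot with a coarse 2010 snapshot into a
1-km equipped-area map, splits annual regional AAI totals down the
NUTS1→NUTS2 hierarchy and across 16 crop classes with fixed
reference-year proportions, and allocates each regional crop target to
cells proportionally to crop-specific equipped area:

```
P_NUTS(n)     = 100 · TAAI(n) / Σ_n TAAI(n)            (NUTS2 share of NUTS1)
P_crop(c)     = 100 · AAI(c) / Σ_c AAI(c)              (crop share of region)
AAI(c, y)     = P_crop(c)/100 · TAAI(y)                (annual crop target)
TAEI_1km      = P_TAEI/100 · TAEI_1km,2005             (harmonized AEI, P_TAEI
                                                        bilinearly resampled)
AEI(cell, c)  = CGS(cell, c) · TAEI_1km(cell)          (crop equipped area)
P_AAI(c, y)   = 100 · AAI(c, y) / Σ_region AEI(cell, c) (zonal calibration)
AAI(cell,c,y) = AEI(cell, c) · P_AAI(c, y)/100          (allocation)
```

Post-processing caps each cell's crop-summed irrigated area at the cell
capacity (100 ha) by proportional scaling, clamps per-crop irrigated
area to the crop growing area, and derives rainfed area as the
remainder, so that irrigated + rainfed = growing area exactly.

Because the real inputs are continental data products, the package
ships a seeded synthetic-world generator that emulates their statistical
structure with known per-cell ground truth; the full pipeline recovers
that truth cell-for-cell, which is the package's primary correctness
guarantee. A survey-comparison module (point classification by land-use
and water-management codes, block irrigated percentages, paired 0.3%
filtering, Pearson/OLS agreement statistics) reproduces the validation
procedure used for such products.

Everything is plain R; rasters are read and written as single-band
float64 GeoTIFF (EPSG 3035 tag, explicit nodata) by a compact built-in
codec.

## Worked example

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_build.R
Rscript analysis/03_validate.R
```

Step 1 generates and serializes a synthetic world (64×64 km grid,
3 NUTS1 × 2 NUTS2 regions, 16 crops, 2010–2012, constant AEI change
ratio 0.8, seed 101) under `results/world/`:

```
world: 4096 cells, 6 NUTS2 regions, 16 crops, 3 years
total true irrigated area 2010: 30907.4 ha
```

Step 2 builds the product (`results/product/` holds one GeoTIFF per
crop, irrigation status and year — e.g. `LMAIZ_IR_A_2010.tif` is
irrigated maize 2010 — plus `Total_IR_A_*`, `Total_RF_A_*`, `UAA_*`
layers and diagnostics CSVs) and checks it against the known truth:

```
max relative recovery error per year:
    2010     2011     2012
3.23e-15 2.80e-15 3.62e-15
max conservation error: 2.76e-16 (relative)
```

i.e. the pipeline reproduces the ground truth and the regional targets
to machine precision — the disaggregation is exactly conservative.

Step 3 compares built products against synthetic survey points. On a
self-consistency design (16 regions coinciding with 16-km comparison
blocks, every cell surveyed once) the point-side and raster-side block
irrigated percentages agree strongly per crop:

```
  crop_code n_blocks pearson_r slope  p_value stars
1      CERE       16     0.969 0.368 7.18e-10   ***
2     LMAIZ       16     0.956 0.372 7.70e-09   ***
```

On the study-scale world the same comparison is expectedly weak (the
true irrigated fraction is constant within each of the 6 regions, so
point-side block percentages vary only by sampling noise) — see the
methods vignette (`vignettes/irrigated-area-disaggregation.Rmd`) for
why, and for every numerical and design choice.

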