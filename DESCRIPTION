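Package: irrigrid
Title: Crop-Specific Irrigated Area Mapping by Hierarchical Dasymetric
    Disaggregation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Harmonizes multi-resolution irrigation-infrastructure rasters
    and disaggregates annual regional irrigated-area statistics onto a 1-km
    crop-type grid under conservation and per-cell capacity constraints.
    Regional totals are split down the administrative hierarchy (NUTS1 to
    NUTS2) and across crops using reference-year census proportions, then
    allocated to grid cells proportionally to crop-specific equipped area
    via zonal calibration coefficients. Includes a seeded synthetic-world
    generator with exact per-cell ground truth for end-to-end recovery
    testing, point-survey emulation, and the agreement statistics (block
    irrigated percentages, Pearson correlation, regression slope) used to
    compare gridded products against field surveys. Rasters are read and
    written as single-band GeoTIFF with affine transform, nodata and
    projected CRS tags.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
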