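# 1-km allocation of regional crop-specific irrigated-area targets.
#
# The allocation is dasymetric: within each region, the annual regional
# crop target is spread over cells proportionally to the crop-specific
# equipped area (crop share x harmonized total AEI). A single zonal
# calibration coefficient per region/crop/year makes the regional sums
# close exactly; two per-cell post-processing steps (capacity cap, then
# growing-area clamp) enforce physical bounds, with any clipped mass
# surfaced in diagnostics rather than redistributed.

#' A stack of per-crop raster layers on a shared geometry
#'
#' @param layers named list (by crop code) of numeric matrices.
#' @param geom a [grid_geometry()].
#' @param year the year the stack refers to.
#' @param kind one of `"share"`, `"growing_area"`, `"aei"`, `"aai"`,
#'   `"rainfed"`.
#' @param units value units (default `"ha"`).
#' @return an object of class `crop_stack`.
#' @export
crop_stack <- function(layers, geom, year = NA_integer_, kind = "aai",
                       units = "ha") {
  stopifnot(is.list(layers), length(layers) > 0, !is.null(names(layers)))
  d <- dim(layers[[1]])
  ok <- vapply(layers, function(m) is.matrix(m) && all(dim(m) == d), TRUE)
  if (!all(ok)) stop("crop_stack: all layers must share dimensions")
  if (d[1] != geom$nrow || d[2] != geom$ncol)
    stop("crop_stack: layer dimensions do not match geometry")
  structure(list(layers = layers, geom = geom, year = year, kind = kind,
                 units = units), class = "crop_stack")
}

#' @export
print.crop_stack <- function(x, ...) {
  cat(sprintf("<crop_stack> kind='%s', year=%s, %d crops, %d x %d cells\n",
              x$kind, x$year, length(x$layers), x$geom$nrow, x$geom$ncol))
  invisible(x)
}

#' Cell-wise sum over all crop layers of a stack
#' @param stack a `crop_stack`.
#' @return numeric matrix.
#' @export
stack_total <- function(stack) Reduce(`+`, stack$layers)

# extract one layer as a full grid object
stack_layer_grid <- function(stack, crop, nodata = -9999) {
  gm <- stack$geom
  grid_create(stack$layers[[crop]], x0 = gm$x0, y0 = gm$y0, dx = gm$dx,
              dy = gm$dy, nodata = nodata, units = stack$units, crs = gm$crs)
}

#' Region-membership raster
#'
#' Carries the NUTS2 membership of every cell as an integer index into a
#' vector of region identifiers; cells outside all regions are `NA`.
#'
#' @param index integer matrix of 1-based indices (NA outside regions).
#' @param region_ids character vector of NUTS2 identifiers.
#' @param geom a [grid_geometry()].
#' @return an object of class `region_raster`.
#' @export
region_raster <- function(index, region_ids, geom) {
  stopifnot(is.matrix(index), nrow(index) == geom$nrow,
            ncol(index) == geom$ncol)
  idx <- index[!is.na(index)]
  if (length(idx) && (min(idx) < 1 || max(idx) > length(region_ids)))
    stop("region index out of range of region_ids")
  structure(list(index = index, region_ids = region_ids, geom = geom),
            class = "region_raster")
}

#' Crop growing area per cell
#'
#' The utilized agricultural area (UAA) of a cell is its weight (percent
#' of cell area, capped at 100%) times the cell area; the growing area of
#' a crop is UAA times that crop's growing share.
#'
#' @param weight_grid percent `grid` (may exceed 100 before capping).
#' @param crop_share_grids `crop_stack` of per-crop share fractions.
#' @param cell_area_ha cell area in hectares (default from geometry).
#' @return list with `ga` (a growing-area `crop_stack`) and `uaa`
#'   (numeric matrix of hectares).
#' @export
crop_growing_area <- function(weight_grid, crop_share_grids,
                              cell_area_ha = NULL) {
  stopifnot(inherits(weight_grid, "grid"),
            inherits(crop_share_grids, "crop_stack"))
  if (any(weight_grid$values < 0, na.rm = TRUE)) stop("negative cell weights")
  if (any(vapply(crop_share_grids$layers, function(m) any(m < 0, na.rm = TRUE),
                 TRUE)))
    stop("negative crop shares")
  if (is.null(cell_area_ha)) cell_area_ha <- cell_area_ha(weight_grid)
  uaa <- pmin(weight_grid$values, 100) / 100 * cell_area_ha
  ga <- lapply(crop_share_grids$layers, function(s) uaa * s)
  list(ga = crop_stack(ga, geom_of(weight_grid),
                       year = crop_share_grids$year, kind = "growing_area"),
       uaa = uaa)
}

#' Crop-specific equipped area per cell
#'
#' Each crop's equipped area is its growing share times the harmonized
#' total equipped area; summed over crops it never exceeds the total
#' because shares sum to at most one per cell.
#'
#' @param crop_share_grids `crop_stack` of share fractions.
#' @param taei_1km harmonized total equipped-area `grid` (ha).
#' @return an equipped-area `crop_stack` (ha).
#' @export
crop_aei <- function(crop_share_grids, taei_1km) {
  stopifnot(inherits(crop_share_grids, "crop_stack"),
            inherits(taei_1km, "grid"))
  if (!same_geometry(geom_of(taei_1km), crop_share_grids$geom))
    stop("crop_aei: geometry mismatch")
  layers <- lapply(crop_share_grids$layers, function(s) s * taei_1km$values)
  crop_stack(layers, crop_share_grids$geom, year = crop_share_grids$year,
             kind = "aei")
}

#' Zonal sums of a crop stack over regions
#'
#' Exact per-region, per-crop sums over all non-nodata region cells.
#' Empty regions get 0.
#'
#' @param stack a `crop_stack`.
#' @param regions a [region_raster()] on the same geometry.
#' @return data.frame `region_id`, `crop_code`, `total_ha`.
#' @export
zonal_sum <- function(stack, regions) {
  stopifnot(inherits(stack, "crop_stack"), inherits(regions, "region_raster"))
  if (!same_geometry(stack$geom, regions$geom))
    stop("zonal_sum: geometry mismatch")
  idx <- factor(regions$index, levels = seq_along(regions$region_ids))
  out <- do.call(rbind, lapply(names(stack$layers), function(cc) {
    v <- stack$layers[[cc]]
    v[is.na(v)] <- 0
    s <- tapply(as.vector(v), idx, sum, default = 0)
    data.frame(region_id = regions$region_ids,
               crop_code = cc, total_ha = as.numeric(s))
  }))
  rownames(out) <- NULL
  out
}

#' Zonal calibration coefficients
#'
#' Per region/crop/year, the percent ratio of the regional irrigated-area
#' target to the regional equipped area: `coeff = 100 * target / AEI`.
#' Where the regional equipped area is zero but the target positive, the
#' coefficient is 0, the row is flagged, and the target mass is reported
#' as unallocated. Coefficients above 100% are not clipped (locally the
#' irrigated area may then exceed the equipped area; a warning notes it).
#'
#' @param targets data.frame `region_id`, `crop_code`, `year`, `aai_ha`.
#' @param regional_aei data.frame `region_id`, `crop_code`, `year`,
#'   `total_ha` (zonal equipped-area sums).
#' @return data.frame `region_id`, `crop_code`, `year`, `coeff_pct`,
#'   `regional_aei_ha`, `regional_target_ha`, `flagged`.
#' @export
calibration <- function(targets, regional_aei) {
  if (any(targets$aai_ha < 0) || any(regional_aei$total_ha < 0))
    stop("negative inputs to calibration")
  m <- merge(targets, regional_aei,
             by = c("region_id", "crop_code", "year"), all.x = TRUE)
  if (any(is.na(m$total_ha)))
    stop("missing regional equipped area for some (region, crop, year)")
  coeff <- ifelse(m$total_ha > 0, 100 * m$aai_ha / m$total_ha, 0)
  flagged <- m$total_ha <= 0 & m$aai_ha > 0
  if (any(coeff > 100 + 1e-9))
    warning("calibration coefficient(s) above 100%: irrigated area ",
            "locally exceeds equipped area in ", sum(coeff > 100 + 1e-9),
            " region-crop-year case(s)")
  out <- data.frame(region_id = m$region_id, crop_code = m$crop_code,
                    year = m$year, coeff_pct = coeff,
                    regional_aei_ha = m$total_ha,
                    regional_target_ha = m$aai_ha, flagged = flagged)
  out[order(out$region_id, out$crop_code, out$year), ]
}

#' Allocate regional targets onto the grid
#'
#' Every cell of a region gets the region's calibration coefficient:
#' `aai(cell, crop) = aei(cell, crop) * coeff(region, crop) / 100`. For
#' non-flagged rows the regional sums equal the targets exactly. Cells
#' outside all regions become nodata.
#'
#' @param aei_stack equipped-area `crop_stack` for one year.
#' @param calib [calibration()] table filtered to that year.
#' @param regions a [region_raster()].
#' @return an uncapped irrigated-area `crop_stack`.
#' @export
allocate_aai <- function(aei_stack, calib, regions) {
  stopifnot(inherits(aei_stack, "crop_stack"),
            inherits(regions, "region_raster"))
  if (!same_geometry(aei_stack$geom, regions$geom))
    stop("allocate_aai: geometry mismatch")
  if (length(unique(calib$year)) > 1)
    stop("allocate_aai: calibration table must cover a single year")
  present <- unique(regions$index[!is.na(regions$index)])
  layers <- lapply(names(aei_stack$layers), function(cc) {
    rows <- calib[calib$crop_code == cc, ]
    co <- rep(NA_real_, length(regions$region_ids))
    co[match(rows$region_id, regions$region_ids)] <- rows$coeff_pct
    if (any(is.na(co[present])))
      stop("allocate_aai: no calibration coefficient for region(s) ",
           paste(regions$region_ids[present][is.na(co[present])],
                 collapse = ", "), " crop ", cc)
    cell_co <- matrix(co[regions$index], nrow(regions$index),
                      ncol(regions$index))
    aei_stack$layers[[cc]] * cell_co / 100
  })
  names(layers) <- names(aei_stack$layers)
  crop_stack(layers, aei_stack$geom, year = aei_stack$year, kind = "aai")
}

#' Per-cell capacity cap
#'
#' Where the crop-summed irrigated area of a cell exceeds the cell
#' capacity (by default the cell area in hectares, i.e. 100 ha for a
#' 1-km cell), every crop layer in that cell is scaled by the same
#' factor `cap / total`, so the cell total equals the cap exactly and
#' between-crop ratios are preserved. No mass is redistributed to other
#' cells; the clipped mass is reported per region.
#'
#' @param aai_stack irrigated-area `crop_stack`.
#' @param cap_ha capacity in hectares (default: cell area).
#' @param regions optional [region_raster()] for per-region diagnostics.
#' @return list with `stack` (capped), `diagnostics` (data.frame
#'   `region_id`, `clipped_ha`, `n_cells`), and `triggered` (logical
#'   matrix of capped cells).
#' @export
apply_cell_cap <- function(aai_stack, cap_ha = NULL, regions = NULL) {
  stopifnot(inherits(aai_stack, "crop_stack"))
  if (is.null(cap_ha)) cap_ha <- cell_area_ha(aai_stack$geom)
  if (cap_ha <= 0) stop("cap must be positive")
  total <- stack_total(aai_stack)
  triggered <- !is.na(total) & total > cap_ha
  scale <- matrix(1, nrow(total), ncol(total))
  scale[triggered] <- cap_ha / total[triggered]
  layers <- lapply(aai_stack$layers, function(m) m * scale)
  clipped <- pmax(total - cap_ha, 0)
  if (!is.null(regions)) {
    idx <- factor(regions$index, levels = seq_along(regions$region_ids))
    cl <- tapply(as.vector(clipped), idx, sum, na.rm = TRUE, default = 0)
    nc <- tapply(as.vector(triggered), idx, sum, na.rm = TRUE, default = 0)
    diagnostics <- data.frame(region_id = regions$region_ids,
                              clipped_ha = as.numeric(cl),
                              n_cells = as.integer(nc))
  } else {
    diagnostics <- data.frame(region_id = "(all)",
                              clipped_ha = sum(clipped, na.rm = TRUE),
                              n_cells = sum(triggered))
  }
  list(stack = crop_stack(layers, aai_stack$geom, year = aai_stack$year,
                          kind = "aai"),
       diagnostics = diagnostics, triggered = triggered)
}

#' Derive rainfed area and final irrigated area
#'
#' Per cell and crop, the irrigated area is clamped to the crop growing
#' area (`aai_final = min(aai, ga)`, the clamped excess logged), and the
#' rainfed area is the remainder `rf = ga - aai_final`, so the identity
#' `aai_final + rf = ga` holds exactly with `rf >= 0`.
#'
#' @param growing growing-area `crop_stack`.
#' @param aai_capped capped irrigated-area `crop_stack`.
#' @return list with `aai` (final irrigated stack), `rainfed` stack, and
#'   `diagnostics` (data.frame `crop_code`, `clamped_ha`, `n_cells`).
#' @export
derive_rainfed <- function(growing, aai_capped) {
  stopifnot(inherits(growing, "crop_stack"), inherits(aai_capped, "crop_stack"))
  if (!same_geometry(growing$geom, aai_capped$geom))
    stop("derive_rainfed: geometry mismatch")
  crops <- names(aai_capped$layers)
  aai_f <- list(); rf <- list()
  diag_rows <- lapply(crops, function(cc) {
    ga <- growing$layers[[cc]]
    aai <- aai_capped$layers[[cc]]
    over <- !is.na(aai) & !is.na(ga) & aai > ga
    af <- pmin(aai, ga)
    aai_f[[cc]] <<- af
    rf[[cc]] <<- ga - af
    data.frame(crop_code = cc,
               clamped_ha = sum((aai - ga)[over]),
               n_cells = sum(over))
  })
  list(aai = crop_stack(aai_f[crops], aai_capped$geom, aai_capped$year, "aai"),
       rainfed = crop_stack(rf[crops], aai_capped$geom, aai_capped$year,
                            "rainfed"),
       diagnostics = do.call(rbind, diag_rows))
}
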