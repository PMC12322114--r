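# End-to-end pipeline drivers: simulate a synthetic world, build the
# gridded irrigated/rainfed product from an input bundle, validate the
# product against survey points. Each driver is deterministic given its
# inputs and returns its artifacts; writing is handled separately so the
# drivers compose in memory in tests.

#' Build the gridded crop-specific irrigated-area product
#'
#' Runs the full chain on an input bundle: regional disaggregation
#' (hierarchy shares, crop proportions, annual crop targets), equipped-
#' area harmonization (block sum, change ratio, bilinear resampling to
#' the target grid), per-cell allocation (crop growing area, crop
#' equipped area, zonal calibration, allocation), and post-processing
#' (per-cell capacity cap, then growing-area clamp and rainfed
#' derivation). Cells outside all regions are nodata in every output.
#'
#' @param bundle a [make_world()] bundle, or a directory written by
#'   [write_world()].
#' @param ratio_orientation `"inverted"` (default; multiply the old fine
#'   map by the new/old ratio) or `"as_printed"` (the literal old/new
#'   formula).
#' @param cap_ha per-cell capacity in hectares (default: the cell area,
#'   100 ha on a 1-km grid).
#' @return list of class `build_result`: `taei` (harmonized equipped
#'   area), `uaa` matrix, `ga` (growing-area stack), per-year lists
#'   `aai` (final irrigated stacks), `rainfed`, `aai_uncapped`,
#'   `cap_triggered` (logical matrices), `calibration` (one table, all
#'   years), `targets`, `nuts2_series`, `diagnostics`.
#' @export
run_build <- function(bundle, ratio_orientation = c("inverted", "as_printed"),
                      cap_ha = NULL) {
  ratio_orientation <- match.arg(ratio_orientation)
  if (is.character(bundle)) bundle <- read_world(bundle)
  stopifnot(inherits(bundle, "world_bundle"))
  rt <- bundle$region_table
  rr <- bundle$region_raster
  target_geom <- rr$geom
  years <- bundle$config$years

  stage <- "regional disaggregation"
  res <- tryCatch({
    shares <- compute_region_shares(bundle$crop_aai_ref, rt)
    n2series <- disaggregate_total_aai(bundle$aai_series, shares, rt)
    props <- compute_crop_proportions(bundle$crop_aai_ref)
    targets <- crop_aai_series(n2series, props)

    stage <- "equipped-area harmonization"
    fine <- bundle$aei_fine_2005
    factor <- round(bundle$aei_coarse_2010$dx / fine$dx)
    coarse_2005 <- aggregate_block_sum(fine, factor)
    ratio <- change_ratio(coarse_2005, bundle$aei_coarse_2010,
                          orientation = ratio_orientation)
    ratio_1km <- resample_bilinear(ratio, target_geom)
    fine_1km <- resample_bilinear(fine, target_geom)
    taei <- harmonized_aei(fine_1km, ratio_1km)

    stage <- "grid allocation"
    cga <- crop_growing_area(bundle$weight_grid, bundle$crop_share_grids)
    mask <- is.na(rr$index)
    ga_masked <- crop_stack(lapply(cga$ga$layers, function(m) {
      m[mask] <- NA_real_; m
    }), target_geom, kind = "growing_area")
    uaa <- cga$uaa; uaa[mask] <- NA_real_

    per_year <- lapply(years, function(y) {
      aei_stack <- crop_aei(bundle$crop_share_grids, taei)
      aei_stack$year <- y
      zs <- zonal_sum(aei_stack, rr)
      zs$year <- y
      calib <- calibration(targets[targets$year == y, ], zs)
      aai_unc <- allocate_aai(aei_stack, calib, rr)
      capped <- apply_cell_cap(aai_unc, cap_ha = cap_ha, regions = rr)
      fin <- derive_rainfed(ga_masked, capped$stack)
      list(calib = calib, aai_uncapped = aai_unc, aai = fin$aai,
           rainfed = fin$rainfed, cap_triggered = capped$triggered,
           cap_diag = capped$diagnostics, clamp_diag = fin$diagnostics)
    })
    names(per_year) <- as.character(years)

    diag_cap <- do.call(rbind, lapply(years, function(y) {
      d <- per_year[[as.character(y)]]$cap_diag; d$year <- y; d
    }))
    diag_clamp <- do.call(rbind, lapply(years, function(y) {
      d <- per_year[[as.character(y)]]$clamp_diag; d$year <- y; d
    }))
    calib_all <- do.call(rbind, lapply(per_year, `[[`, "calib"))
    rownames(calib_all) <- NULL

    structure(list(
      taei = taei, uaa = uaa, ga = ga_masked,
      aai = lapply(per_year, `[[`, "aai"),
      rainfed = lapply(per_year, `[[`, "rainfed"),
      aai_uncapped = lapply(per_year, `[[`, "aai_uncapped"),
      cap_triggered = lapply(per_year, `[[`, "cap_triggered"),
      calibration = calib_all, targets = targets,
      nuts2_series = n2series, region_shares = shares,
      crop_proportions = props,
      diagnostics = list(cap = diag_cap, clamp = diag_clamp,
                         unallocated = attr(targets, "unallocated")),
      years = years, region_raster = rr), class = "build_result")
  }, error = function(e) {
    stop("build failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

#' Write build outputs as the product file set
#'
#' One GeoTIFF per crop, irrigation status and year, following the
#' product naming convention: `{CROP}_IR_A_{YYYY}.tif` (irrigated),
#' `{CROP}_RF_A_{YYYY}.tif` (rainfed), `{CROP}_A_{YYYY}.tif` (growing
#' area, the sum of the two), plus `Total_IR_A_{YYYY}.tif`,
#' `Total_RF_A_{YYYY}.tif` and `UAA_{YYYY}.tif` per year, and a
#' `diagnostics.csv` with per-region/crop/year unallocated and clipped
#' mass.
#'
#' @param result a [run_build()] result.
#' @param dir output directory (created if needed).
#' @param float32 write 32-bit floats instead of 64-bit.
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(result, dir, float32 = FALSE) {
  stopifnot(inherits(result, "build_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gm <- result$aai[[1]]$geom
  as_grid <- function(m) grid_create(m, x0 = gm$x0, y0 = gm$y0, dx = gm$dx,
                                     dy = gm$dy, units = "ha", crs = gm$crs)
  for (y in result$years) {
    ys <- as.character(y)
    aai <- result$aai[[ys]]; rf <- result$rainfed[[ys]]
    for (cc in names(aai$layers)) {
      write_grid(as_grid(aai$layers[[cc]]),
                 file.path(dir, sprintf("%s_IR_A_%d.tif", cc, y)), float32)
      write_grid(as_grid(rf$layers[[cc]]),
                 file.path(dir, sprintf("%s_RF_A_%d.tif", cc, y)), float32)
      write_grid(as_grid(aai$layers[[cc]] + rf$layers[[cc]]),
                 file.path(dir, sprintf("%s_A_%d.tif", cc, y)), float32)
    }
    write_grid(as_grid(stack_total(aai)),
               file.path(dir, sprintf("Total_IR_A_%d.tif", y)), float32)
    write_grid(as_grid(stack_total(rf)),
               file.path(dir, sprintf("Total_RF_A_%d.tif", y)), float32)
    # the UAA layer follows the product identity UAA = Total_IR + Total_RF
    # (the crop-summed growing area); where crop shares sum to < 1 this is
    # smaller than the weight-derived per-cell UAA kept in `result$uaa`
    write_grid(as_grid(stack_total(aai) + stack_total(rf)),
               file.path(dir, sprintf("UAA_%d.tif", y)), float32)
  }
  cap <- result$diagnostics$cap
  names(cap)[names(cap) == "clipped_ha"] <- "cap_clipped_ha"
  clamp <- result$diagnostics$clamp
  names(clamp)[names(clamp) == "clamped_ha"] <- "clamp_clipped_ha"
  utils::write.csv(cap, file.path(dir, "diagnostics_cap.csv"),
                   row.names = FALSE)
  utils::write.csv(clamp, file.path(dir, "diagnostics_clamp.csv"),
                   row.names = FALSE)
  un <- result$diagnostics$unallocated
  if (!is.null(un) && nrow(un))
    utils::write.csv(un, file.path(dir, "diagnostics_unallocated.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Serialize a synthetic world bundle to a directory
#'
#' Rasters go to single-band float64 GeoTIFF (explicit nodata, EPSG 3035
#' tag), tables to CSV with documented headers, and the generating
#' configuration is echoed as `config.yml`.
#'
#' @param bundle a [make_world()] bundle.
#' @param dir output directory.
#' @param truth also write the per-crop/per-year ground-truth rasters.
#' @return `dir`, invisibly.
#' @export
write_world <- function(bundle, dir, truth = TRUE) {
  stopifnot(inherits(bundle, "world_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  cfg$years <- as.integer(cfg$years)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yml"))
  utils::write.csv(bundle$region_table, file.path(dir, "regions.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$aai_series, file.path(dir, "aai_series.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$crop_aai_ref, file.path(dir, "crop_aai_ref.csv"),
                   row.names = FALSE)
  rr <- bundle$region_raster
  utils::write.csv(data.frame(index = seq_along(rr$region_ids),
                              region_id = rr$region_ids),
                   file.path(dir, "region_levels.csv"), row.names = FALSE)
  gm <- rr$geom
  write_grid(grid_create(rr$index + 0, x0 = gm$x0, y0 = gm$y0, dx = gm$dx,
                         dy = gm$dy, units = "index", crs = gm$crs),
             file.path(dir, "region_index.tif"))
  write_grid(bundle$aei_fine_2005, file.path(dir, "aei_fine_2005.tif"))
  write_grid(bundle$aei_coarse_2010, file.path(dir, "aei_coarse_2010.tif"))
  write_grid(bundle$weight_grid, file.path(dir, "weight.tif"))
  for (cc in names(bundle$crop_share_grids$layers)) {
    write_grid(stack_layer_grid(bundle$crop_share_grids, cc),
               file.path(dir, sprintf("share_%s.tif", cc)))
  }
  if (truth) {
    write_grid(bundle$truth_taei, file.path(dir, "truth_taei.tif"))
    for (ys in names(bundle$truth_aai)) {
      st <- bundle$truth_aai[[ys]]
      for (cc in names(st$layers))
        write_grid(stack_layer_grid(st, cc),
                   file.path(dir, sprintf("truth_%s_%s.tif", cc, ys)))
    }
  }
  invisible(dir)
}

#' Read a serialized world bundle
#'
#' @param dir a directory written by [write_world()].
#' @return a `world_bundle`.
#' @export
read_world <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yml"))
  cfg$years <- as.integer(cfg$years)
  cfg$ratio_mode <- match.arg(cfg$ratio_mode, c("constant", "smooth"))
  class(cfg) <- "world_config"
  region_table <- utils::read.csv(file.path(dir, "regions.csv"),
                                  colClasses = "character")
  region_table$parent_id[region_table$parent_id == ""] <- NA_character_
  lv <- utils::read.csv(file.path(dir, "region_levels.csv"))
  gi <- read_grid(file.path(dir, "region_index.tif"), units = "index")
  rr <- region_raster(matrix(as.integer(round(gi$values)), nrow(gi$values)),
                      lv$region_id, geom_of(gi))
  aai_series <- utils::read.csv(file.path(dir, "aai_series.csv"))
  crop_aai_ref <- utils::read.csv(file.path(dir, "crop_aai_ref.csv"))
  share_files <- sort(list.files(dir, "^share_.*\\.tif$", full.names = TRUE))
  crops <- sub("^share_(.*)\\.tif$", "\\1", basename(share_files))
  cat_order <- crop_catalog()$crop_code
  ord <- order(match(crops, cat_order))
  share_layers <- lapply(share_files[ord], function(f)
    read_grid(f, units = "fraction")$values)
  names(share_layers) <- crops[ord]
  target_geom <- geom_of(gi)
  truth_files <- list.files(dir, "^truth_.*_\\d{4}\\.tif$")
  truth_aai <- NULL
  if (length(truth_files)) {
    yrs <- sort(unique(sub("^truth_.*_(\\d{4})\\.tif$", "\\1", truth_files)))
    truth_aai <- lapply(yrs, function(ys) {
      layers <- lapply(names(share_layers), function(cc)
        read_grid(file.path(dir, sprintf("truth_%s_%s.tif", cc, ys)))$values)
      names(layers) <- names(share_layers)
      crop_stack(layers, target_geom, year = as.integer(ys), kind = "aai")
    })
    names(truth_aai) <- yrs
  }
  truth_taei <- if (file.exists(file.path(dir, "truth_taei.tif")))
    read_grid(file.path(dir, "truth_taei.tif")) else NULL
  structure(list(
    config = cfg, region_table = region_table, region_raster = rr,
    aai_series = aai_series, crop_aai_ref = crop_aai_ref,
    aei_fine_2005 = read_grid(file.path(dir, "aei_fine_2005.tif")),
    aei_coarse_2010 = read_grid(file.path(dir, "aei_coarse_2010.tif")),
    weight_grid = read_grid(file.path(dir, "weight.tif"), units = "percent"),
    crop_share_grids = crop_stack(share_layers, target_geom,
                                  kind = "share", units = "fraction"),
    truth_taei = truth_taei, truth_aai = truth_aai,
    cap_cell = NULL, target_geom = target_geom), class = "world_bundle")
}

#' Simulate a world and serialize it
#'
#' Thin wrapper over [make_world()] + [write_world()] with a seed echo.
#'
#' @param config a [world_config()].
#' @param out_dir output directory.
#' @return the bundle, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  bundle <- make_world(config)
  write_world(bundle, out_dir)
  message(sprintf("simulate: seed=%d, %dx%d cells, %d regions -> %s",
                  config$seed, config$grid_height, config$grid_width,
                  length(bundle$region_raster$region_ids), out_dir))
  invisible(bundle)
}

#' Validate a built product against survey points
#'
#' Per crop: survey points are classified, aggregated to blocks as point
#' irrigated percentages, the product's crop layer for the matching year
#' is aggregated to the same blocks as area irrigated percentages, pairs
#' are filtered at the minimum percentage, and agreement statistics are
#' computed. With several survey years, per-year block values are pooled
#' after aggregation (`pool = "after"`, the default: each year's blocks
#' enter as separate pairs) or the years are merged before aggregation
#' (`pool = "before"`: point counts summed over years, product layers
#' averaged).
#'
#' @param result a [run_build()] result.
#' @param points survey points (`x`, `y`, `year`, `lu1`, `lu2`, `wm`,
#'   `crop_code`), possibly spanning several years.
#' @param block_km comparison block size in km.
#' @param min_ip_pct inclusive minimum irrigated percentage for pairing.
#' @param include_potential count potential irrigation (code 2) as
#'   irrigated.
#' @param pool `"after"` or `"before"` (see above).
#' @param min_blocks minimum pairs required to compute statistics.
#' @return data.frame of per-crop agreement statistics.
#' @export
run_validate <- function(result, points, block_km = 40, min_ip_pct = 0.3,
                         include_potential = FALSE,
                         pool = c("after", "before"), min_blocks = 3) {
  pool <- match.arg(pool)
  stopifnot(inherits(result, "build_result"))
  gm <- result$aai[[1]]$geom
  pts <- classify_survey_points(points, include_potential)
  yrs <- intersect(unique(pts$year), as.integer(result$years))
  if (length(yrs) == 0) stop("no survey year overlaps the built years")
  crops <- names(result$aai[[1]]$layers)

  per_crop <- lapply(crops, function(cc) {
    if (pool == "after") {
      prs <- do.call(rbind, lapply(yrs, function(y) {
        pa <- block_irrigated_percentage_points(
          pts[pts$crop_code == cc & pts$year == y, ], gm, block_km)
        layer <- stack_layer_grid(result$aai[[as.character(y)]], cc)
        pb <- block_irrigated_percentage_raster(layer, block_km)
        pr <- paired_filter(pa, pb, min_ip_pct)
        if (nrow(pr)) pr$block_id <- paste0(y, ":", pr$block_id)
        pr
      }))
    } else {
      p_cc <- pts[pts$crop_code == cc & pts$year %in% yrs, ]
      pa <- block_irrigated_percentage_points(p_cc, gm, block_km)
      mean_layer <- Reduce(`+`, lapply(yrs, function(y)
        result$aai[[as.character(y)]]$layers[[cc]])) / length(yrs)
      layer <- grid_create(mean_layer, x0 = gm$x0, y0 = gm$y0, dx = gm$dx,
                           dy = gm$dy, units = "ha", crs = gm$crs)
      pb <- block_irrigated_percentage_raster(layer, block_km)
      prs <- paired_filter(pa, pb, min_ip_pct)
    }
    if (is.null(prs) || nrow(prs) < min_blocks) {
      return(data.frame(crop_code = cc, n_blocks = nrow(prs) %||% 0L,
                        pearson_r = NA_real_, slope = NA_real_,
                        p_value = NA_real_, stars = "ns", flagged = TRUE))
    }
    agreement_stats(prs, crop_code = cc)
  })
  out <- do.call(rbind, per_crop)
  rownames(out) <- NULL
  out
}
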