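# Seeded synthetic input world with exact per-cell ground truth.
#
# The generator inverts the pipeline's own generative assumptions so the
# full build can be checked cell-for-cell: within a region each crop has
# one irrigation fraction (uniform-percentage assumption), regional
# yearly dynamics scale all crops of a NUTS1 unit equally (so the fixed
# reference-year proportions are exactly right), and the coarse
# equipped-area snapshot is an exact block-sum multiple of the fine one
# (so the change-ratio/resampling path is exactly invertible in constant
# ratio mode). The ground-truth total equipped-area map is computed here
# with an independent brute-force bilinear interpolation, not with the
# pipeline's resampler.

#' Configuration of a synthetic world
#'
#' @param grid_height,grid_width target-grid dimensions in cells (must be
#'   divisible by `coarse_factor`).
#' @param cell_size cell size in metres (1000 = the 1-km product grid).
#' @param coarse_factor integer nesting of fine cells per coarse cell per
#'   axis. The real inputs use non-nesting arc-minute grids; an integer
#'   nesting keeps block-sum oracles exact while the production code path
#'   still runs general resampling.
#' @param n_nuts1 number of top-level regions (vertical bands).
#' @param nuts2_per_nuts1 NUTS2 children per NUTS1 (horizontal sub-bands).
#' @param n_crops number of crop classes (at most 16, drawn from the
#'   output catalog).
#' @param years inclusive year range covered by the annual series.
#' @param ratio_mode `"constant"` (single global equipped-area change
#'   ratio; exactly recoverable) or `"smooth"` (spatially varying planar
#'   ratio field; recoverable only approximately near edges).
#' @param ratio the global change ratio (new/old) in constant mode, and
#'   the mean level in smooth mode.
#' @param target_offset if `TRUE`, the target grid is shifted half a cell
#'   against the fine equipped-area grid so resampling uses true interior
#'   bilinear weights instead of the identity.
#' @param cap_trigger if `TRUE`, one designated cell's fine equipped area
#'   is scaled up so its unconstrained crop-summed allocation exceeds the
#'   per-cell capacity in every year (for capacity-cap tests). Requires
#'   `target_offset = FALSE`.
#' @param seed integer master seed; component streams (equipped area,
#'   weights/shares, irrigation fractions) are derived from it so that,
#'   e.g., survey sampling never perturbs the world itself.
#' @param p_fixed optional scalar: fix every region/crop irrigation
#'   fraction at this value (and the yearly multipliers at 1) instead of
#'   drawing them. Degenerate worlds for identity tests.
#' @param share_fixed optional scalar in (0, 1]: give every cell a total
#'   crop share of exactly this value, split evenly across crops.
#' @param weight_fixed optional scalar: constant cell weight (percent).
#' @param aei_fixed optional scalar: constant fine equipped area (ha).
#' @return a list of class `world_config`.
#' @export
world_config <- function(grid_height = 64, grid_width = 64, cell_size = 1000,
                         coarse_factor = 8, n_nuts1 = 3, nuts2_per_nuts1 = 2,
                         n_crops = 16, years = 2010:2020,
                         ratio_mode = c("constant", "smooth"), ratio = 0.8,
                         target_offset = FALSE, cap_trigger = FALSE,
                         seed = 1L, p_fixed = NULL, share_fixed = NULL,
                         weight_fixed = NULL, aei_fixed = NULL) {
  ratio_mode <- match.arg(ratio_mode)
  cfg <- list(grid_height = as.integer(grid_height),
              grid_width = as.integer(grid_width),
              cell_size = cell_size, coarse_factor = as.integer(coarse_factor),
              n_nuts1 = as.integer(n_nuts1),
              nuts2_per_nuts1 = as.integer(nuts2_per_nuts1),
              n_crops = as.integer(n_crops), years = as.integer(years),
              ratio_mode = ratio_mode, ratio = ratio,
              target_offset = isTRUE(target_offset),
              cap_trigger = isTRUE(cap_trigger), seed = as.integer(seed),
              p_fixed = p_fixed, share_fixed = share_fixed,
              weight_fixed = weight_fixed, aei_fixed = aei_fixed)
  with(cfg, {
    if (grid_height %% coarse_factor != 0 || grid_width %% coarse_factor != 0)
      stop("grid dimensions must be divisible by coarse_factor")
    if (n_nuts1 < 1 || nuts2_per_nuts1 < 1 || n_crops < 1 ||
        length(years) < 1)
      stop("all counts must be positive")
    if (n_crops > 16) stop("at most 16 crop classes are supported")
    if (n_nuts1 > grid_width)
      stop("infeasible config: more NUTS1 bands (", n_nuts1,
           ") than grid columns (", grid_width, ")")
    if (nuts2_per_nuts1 > grid_height)
      stop("infeasible config: more NUTS2 sub-bands (", nuts2_per_nuts1,
           ") than grid rows (", grid_height, ")")
    if (cap_trigger && target_offset)
      stop("cap_trigger requires target_offset = FALSE")
  })
  class(cfg) <- "world_config"
  cfg
}

# deterministic per-component sub-seed below 2^31
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# independent scalar brute-force bilinear (clamped edges), used only to
# construct ground truth; intentionally separate from resample_bilinear()
brute_bilinear_at <- function(src_vals, src_geom, x, y) {
  nr <- nrow(src_vals); nc <- ncol(src_vals)
  fj <- (x - src_geom$x0) / src_geom$dx + 0.5
  fi <- (src_geom$y0 - y) / src_geom$dy + 0.5
  fj <- min(max(fj, 1), nc); fi <- min(max(fi, 1), nr)
  j0 <- min(floor(fj), nc - 1); i0 <- min(floor(fi), nr - 1)
  dx <- fj - j0; dy <- fi - i0
  (1 - dx) * (1 - dy) * src_vals[i0, j0] +
    dx * (1 - dy) * src_vals[i0, j0 + 1] +
    (1 - dx) * dy * src_vals[i0 + 1, j0] +
    dx * dy * src_vals[i0 + 1, j0 + 1]
}

#' Generate a complete synthetic input bundle
#'
#' Builds, from a single seed, every input the pipeline consumes
#' (region table and raster, annual regional totals, reference-year crop
#' table, coarse/fine equipped-area rasters, weight and crop-share grids)
#' together with the per-cell, per-crop, per-year ground-truth irrigated
#' area those inputs encode. The regional tables are derived by
#' aggregating the truth, so the targets are self-consistent with the
#' generative model and the full pipeline can recover the truth exactly
#' (constant ratio mode, no capacity triggers).
#'
#' The first NUTS1 unit reports its annual totals at NUTS1 level (to
#' exercise hierarchical disaggregation); all other regions report at
#' NUTS2 level.
#'
#' @param config a [world_config()].
#' @return a list of class `world_bundle`; see the package vignette for
#'   the component-by-component description.
#' @export
make_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  cfg <- config
  nr <- cfg$grid_height; nc <- cfg$grid_width
  fac <- cfg$coarse_factor
  cell_ha <- (cfg$cell_size / 100)^2  # ha per cell

  # --- region partition: vertical NUTS1 bands, horizontal NUTS2 sub-bands
  nuts1_ids <- paste0("R", seq_len(cfg$n_nuts1))
  n2_per <- cfg$nuts2_per_nuts1
  nuts2_ids <- as.vector(t(outer(nuts1_ids, LETTERS[seq_len(n2_per)],
                                 paste0)))
  region_table <- rbind(
    data.frame(region_id = nuts1_ids, parent_id = NA_character_,
               level = "NUTS1"),
    data.frame(region_id = nuts2_ids,
               parent_id = rep(nuts1_ids, each = n2_per), level = "NUTS2"))
  col_band <- pmin(((seq_len(nc) - 1L) * cfg$n_nuts1) %/% nc + 1L, cfg$n_nuts1)
  row_band <- pmin(((seq_len(nr) - 1L) * n2_per) %/% nr + 1L, n2_per)
  index <- outer(row_band, col_band,
                 function(r, c) (c - 1L) * n2_per + r)
  target_geom <- grid_geometry(nr, nc, x0 = 0, y0 = nr * cfg$cell_size,
                               dx = cfg$cell_size)
  rr <- region_raster(index, nuts2_ids, target_geom)

  # --- fine equipped area (2005 snapshot) on its own geometry
  fine_geom <- if (cfg$target_offset) {
    grid_geometry(nr, nc, x0 = -cfg$cell_size / 2,
                  y0 = nr * cfg$cell_size + cfg$cell_size / 2,
                  dx = cfg$cell_size)
  } else target_geom
  set.seed(sub_seed(cfg$seed, "aei"))
  fine_vals <- if (is.null(cfg$aei_fixed)) {
    matrix(stats::runif(nr * nc, 5, 55), nr, nc)
  } else matrix(cfg$aei_fixed, nr, nc)

  # --- change ratio field at coarse scale
  crn <- nr %/% fac; ccn <- nc %/% fac
  if (cfg$ratio_mode == "constant") {
    ratio_field <- matrix(cfg$ratio, crn, ccn)
  } else {
    set.seed(sub_seed(cfg$seed, "ratio"))
    a <- stats::runif(1, -0.2, 0.2); b <- stats::runif(1, -0.2, 0.2)
    xs <- (seq_len(ccn) - 0.5) / ccn; ys <- (seq_len(crn) - 0.5) / crn
    ratio_field <- cfg$ratio + outer(ys, xs, function(y, x) a * x + b * y)
    ratio_field <- pmax(ratio_field, 0.1)
  }

  # --- weights and crop shares on the target geometry
  crops <- crop_catalog()$crop_code[seq_len(cfg$n_crops)]
  set.seed(sub_seed(cfg$seed, "shares"))
  weight_vals <- if (is.null(cfg$weight_fixed)) {
    matrix(stats::runif(nr * nc, 60, 110), nr, nc)
  } else matrix(cfg$weight_fixed, nr, nc)
  if (is.null(cfg$share_fixed)) {
    alpha <- matrix(stats::rgamma(nr * nc * cfg$n_crops, shape = 0.8),
                    nrow = nr * nc)
    alpha <- alpha / rowSums(alpha)
    scale_sum <- stats::runif(nr * nc, 0.6, 0.95)
  } else {
    alpha <- matrix(1 / cfg$n_crops, nr * nc, cfg$n_crops)
    scale_sum <- rep(cfg$share_fixed, nr * nc)
  }
  share_layers <- lapply(seq_len(cfg$n_crops), function(k)
    matrix(alpha[, k] * scale_sum, nr, nc))
  names(share_layers) <- crops

  # --- per-region crop irrigation fractions and NUTS1-level annual scaling
  set.seed(sub_seed(cfg$seed, "fractions"))
  if (is.null(cfg$p_fixed)) {
    p_rc <- matrix(stats::runif(length(nuts2_ids) * cfg$n_crops, 0.05, 0.85),
                   nrow = length(nuts2_ids),
                   dimnames = list(nuts2_ids, crops))
    m_ry <- matrix(stats::runif(cfg$n_nuts1 * length(cfg$years), 0.6, 1.1),
                   nrow = cfg$n_nuts1,
                   dimnames = list(nuts1_ids, as.character(cfg$years)))
  } else {
    p_rc <- matrix(cfg$p_fixed, length(nuts2_ids), cfg$n_crops,
                   dimnames = list(nuts2_ids, crops))
    m_ry <- matrix(1, cfg$n_nuts1, length(cfg$years),
                   dimnames = list(nuts1_ids, as.character(cfg$years)))
  }

  build_truth <- function(fine_vals) {
    # ground-truth harmonized equipped area on the target grid, by
    # brute-force bilinear interpolation of ratio and fine snapshot
    coarse_geom <- grid_geometry(crn, ccn, x0 = fine_geom$x0,
                                 y0 = fine_geom$y0,
                                 dx = fine_geom$dx * fac)
    ctr <- geom_centers(target_geom)
    taei <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      rv <- brute_bilinear_at(ratio_field, coarse_geom, ctr$x[j], ctr$y[i])
      fv <- brute_bilinear_at(fine_vals, fine_geom, ctr$x[j], ctr$y[i])
      taei[i, j] <- rv * fv
    }
    truth_by_year <- lapply(cfg$years, function(y) {
      m_cell <- m_ry[region_table$parent_id[match(nuts2_ids,
                                                  region_table$region_id)],
                     as.character(y)]
      layers <- lapply(crops, function(cc) {
        p_cell <- matrix((p_rc[, cc] * m_cell)[index], nr, nc)
        p_cell * share_layers[[cc]] * taei
      })
      names(layers) <- crops
      crop_stack(layers, target_geom, year = y, kind = "aai")
    })
    names(truth_by_year) <- as.character(cfg$years)
    list(taei = taei, truth = truth_by_year)
  }

  tr <- build_truth(fine_vals)
  cap_cell <- NULL
  if (cfg$cap_trigger) {
    ci <- nr %/% 2L; cj <- nc %/% 2L
    tot_y <- vapply(tr$truth, function(st) stack_total(st)[ci, cj], 0)
    f <- 2.5 * cell_ha / min(tot_y)
    if (f > 1) {
      fine_vals[ci, cj] <- fine_vals[ci, cj] * f
      tr <- build_truth(fine_vals)
    }
    cap_cell <- c(row = ci, col = cj)
  }

  # --- derive the regional statistics by aggregating the truth
  ref_year <- cfg$years[1]
  zs_ref <- zonal_sum(tr$truth[[as.character(ref_year)]], rr)
  crop_aai_ref <- data.frame(region_id = zs_ref$region_id,
                             crop_code = zs_ref$crop_code,
                             aai_ha = zs_ref$total_ha,
                             reference_year = ref_year)
  taai_n2 <- do.call(rbind, lapply(cfg$years, function(y) {
    zs <- zonal_sum(tr$truth[[as.character(y)]], rr)
    agg <- tapply(zs$total_ha, zs$region_id, sum)
    data.frame(region_id = names(agg), year = y, taai_ha = as.numeric(agg))
  }))
  # first NUTS1 unit reports at NUTS1 level, the rest at NUTS2
  top1 <- nuts1_ids[1]
  kids1 <- region_table$region_id[!is.na(region_table$parent_id) &
                                    region_table$parent_id == top1]
  at1 <- taai_n2[taai_n2$region_id %in% kids1, ]
  agg1 <- tapply(at1$taai_ha, at1$year, sum)
  aai_series <- rbind(
    data.frame(region_id = top1, year = as.integer(names(agg1)),
               taai_ha = as.numeric(agg1)),
    taai_n2[!taai_n2$region_id %in% kids1, ])
  aai_series <- aai_series[order(aai_series$region_id, aai_series$year), ]
  rownames(aai_series) <- NULL

  coarse_2005 <- t(rowsum(t(rowsum(fine_vals, (seq_len(nr) - 1L) %/% fac)),
                          (seq_len(nc) - 1L) %/% fac))
  coarse_2010 <- ratio_field * unname(coarse_2005)
  coarse_geom <- grid_geometry(crn, ccn, x0 = fine_geom$x0, y0 = fine_geom$y0,
                               dx = fine_geom$dx * fac)

  structure(list(
    config = cfg,
    region_table = region_table,
    region_raster = rr,
    aai_series = aai_series,
    crop_aai_ref = crop_aai_ref,
    aei_fine_2005 = grid_create(fine_vals, x0 = fine_geom$x0,
                                y0 = fine_geom$y0, dx = fine_geom$dx,
                                units = "ha"),
    aei_coarse_2010 = grid_create(coarse_2010, x0 = coarse_geom$x0,
                                  y0 = coarse_geom$y0, dx = coarse_geom$dx,
                                  units = "ha"),
    weight_grid = grid_create(weight_vals, x0 = target_geom$x0,
                              y0 = target_geom$y0, dx = target_geom$dx,
                              units = "percent"),
    crop_share_grids = crop_stack(share_layers, target_geom,
                                  year = NA_integer_, kind = "share",
                                  units = "fraction"),
    truth_taei = grid_create(tr$taei, x0 = target_geom$x0, y0 = target_geom$y0,
                             dx = target_geom$dx, units = "ha"),
    truth_aai = tr$truth,
    cap_cell = cap_cell,
    target_geom = target_geom), class = "world_bundle")
}

#' @export
print.world_bundle <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<world_bundle> %dx%d cells, %d NUTS1 x %d NUTS2, ",
                     "%d crops, years %d-%d, ratio_mode=%s, seed=%d\n"),
              cfg$grid_height, cfg$grid_width, cfg$n_nuts1,
              cfg$nuts2_per_nuts1, cfg$n_crops, min(cfg$years),
              max(cfg$years), cfg$ratio_mode, cfg$seed))
  invisible(x)
}

#' Sample synthetic survey points from a world
#'
#' Emulates a point survey: cells with nonzero agricultural area are
#' sampled uniformly without replacement, one point at each sampled cell
#' centre. Each point is assigned a crop by the cell's share
#' distribution and marked irrigated with probability equal to that
#' crop's true irrigated fraction of its growing area in the cell.
#' Irrigated points get water-management code 1, others code 5; all
#' points carry primary land-use code U111.
#'
#' @param bundle a [make_world()] bundle.
#' @param n_points number of points (at most the number of cells with
#'   nonzero agricultural area).
#' @param year survey year (must be within the bundle's years).
#' @param seed integer seed for the sampling stream.
#' @return data.frame `x`, `y`, `year`, `lu1`, `lu2`, `wm`, `crop_code`.
#' @export
make_survey_points <- function(bundle, n_points, year, seed = 1L) {
  stopifnot(inherits(bundle, "world_bundle"))
  year <- as.integer(year)
  if (!year %in% bundle$config$years)
    stop("year ", year, " not covered by the bundle")
  gm <- bundle$target_geom
  cell_ha <- cell_area_ha(gm)
  uaa <- pmin(bundle$weight_grid$values, 100) / 100 * cell_ha
  share_sum <- stack_total(bundle$crop_share_grids)
  eligible <- which(uaa > 0 & share_sum > 0)
  if (n_points > length(eligible))
    stop("n_points (", n_points, ") exceeds the ", length(eligible),
         " cells with nonzero agricultural area")
  set.seed(sub_seed(seed, "points"))
  cells <- sample(eligible, n_points)
  ij <- arrayInd(cells, c(gm$nrow, gm$ncol))
  ctr <- geom_centers(gm)
  truth <- bundle$truth_aai[[as.character(year)]]
  crops <- names(truth$layers)
  share_mat <- vapply(bundle$crop_share_grids$layers, function(m) m[cells],
                      numeric(length(cells)))
  share_mat <- matrix(share_mat, nrow = length(cells))
  crop_pick <- vapply(seq_along(cells), function(k) {
    pr <- share_mat[k, ]
    sample(crops, 1, prob = pr / sum(pr))
  }, character(1))
  irr <- vapply(seq_along(cells), function(k) {
    cc <- crop_pick[k]
    ga <- uaa[cells[k]] * bundle$crop_share_grids$layers[[cc]][cells[k]]
    if (ga <= 0) return(FALSE)
    frac <- min(truth$layers[[cc]][cells[k]] / ga, 1)
    stats::runif(1) < frac
  }, TRUE)
  data.frame(x = ctr$x[ij[, 2]], y = ctr$y[ij[, 1]], year = year,
             lu1 = "U111", lu2 = "", wm = ifelse(irr, 1L, 5L),
             crop_code = crop_pick)
}
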