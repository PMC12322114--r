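# Point-survey vs gridded-product agreement statistics.
#
# Survey points are filtered to agricultural land use, classified as
# irrigated from their water-management code, and aggregated to blocks
# (e.g. 40 km) as irrigated percentages; the gridded product is
# aggregated to the same blocks as irrigated area over block area. Pairs
# present on both sides above a minimum irrigated percentage are compared
# by Pearson correlation and OLS slope.

WM_CODES <- c(1L, 2L, 3L, 4L, 5L, 8L)  # irrigation, potential irrigation,
                                       # drainage, both, none visible, n/a

#' Filter and classify survey points
#'
#' Keeps points whose primary or secondary land use is agriculture
#' (`U111`) or fallow land (`U112`), and classifies a kept point as
#' irrigated when its water-management code is 1 (irrigation) or 4
#' (irrigation and drainage); code 2 (potential irrigation) counts as
#' irrigated only when `include_potential` is on.
#'
#' @param points data.frame with `lu1`, `lu2`, `wm` columns.
#' @param include_potential treat potential irrigation (code 2) as
#'   irrigated.
#' @return the kept rows with a logical `irrigated` column added.
#' @export
classify_survey_points <- function(points, include_potential = FALSE) {
  wm <- as.integer(points$wm)
  bad <- !wm %in% WM_CODES
  if (any(bad))
    stop("unknown water-management code(s): ",
         paste(unique(wm[bad]), collapse = ", "))
  keep <- points$lu1 %in% c("U111", "U112") | points$lu2 %in% c("U111", "U112")
  out <- points[keep, , drop = FALSE]
  irr_codes <- if (include_potential) c(1L, 2L, 4L) else c(1L, 4L)
  out$irrigated <- as.integer(out$wm) %in% irr_codes
  rownames(out) <- NULL
  out
}

# block index of points/cells on a km block grid anchored at the grid
# origin; half-open intervals, edge points belong to the lower-left block
block_id_of <- function(gm, x, y, block_km) {
  block_m <- block_km * 1000
  bx <- floor((x - gm$x0) / block_m)
  by <- floor((gm$y0 - y) / block_m)
  # points exactly on the top/left boundary of the grid fall in block 0
  sprintf("B_%d_%d", as.integer(by), as.integer(bx))
}

#' Block irrigated percentages from survey points
#'
#' Assigns classified points to square blocks and computes, per block,
#' `100 * irrigated count / total count`. Blocks without points are
#' omitted; points outside the grid are dropped.
#'
#' @param points output of [classify_survey_points()].
#' @param geom the product [grid_geometry()] anchoring the block grid.
#' @param block_km block edge length in km.
#' @return data.frame `block_id`, `ip`, `n_points`.
#' @export
block_irrigated_percentage_points <- function(points, geom, block_km = 40) {
  inside <- points$x >= geom$x0 & points$x <= geom$x0 + geom$ncol * geom$dx &
    points$y <= geom$y0 & points$y >= geom$y0 - geom$nrow * geom$dy
  p <- points[inside, , drop = FALSE]
  if (nrow(p) == 0)
    return(data.frame(block_id = character(0), ip = numeric(0),
                      n_points = integer(0)))
  bid <- block_id_of(geom, p$x, p$y, block_km)
  nt <- tapply(rep(1L, nrow(p)), bid, sum)
  ni <- tapply(as.integer(p$irrigated), bid, sum)
  data.frame(block_id = names(nt), ip = 100 * as.numeric(ni) / as.numeric(nt),
             n_points = as.integer(nt), row.names = NULL)
}

#' Block irrigated percentages from an irrigated-area raster
#'
#' Aggregates an irrigated-area grid (hectares per cell) to square
#' blocks and computes, per block, `100 * irrigated area / block area`.
#' Partial edge blocks use the actually covered cell area as the
#' denominator. Nodata cells contribute neither area nor irrigated mass.
#'
#' @param aai a `grid` of irrigated hectares (or one crop layer).
#' @param block_km block edge length in km; must be an integer multiple
#'   of the cell size.
#' @return data.frame `block_id`, `ip`.
#' @export
block_irrigated_percentage_raster <- function(aai, block_km = 40) {
  stopifnot(inherits(aai, "grid"))
  gm <- geom_of(aai)
  cells_per_block <- block_km * 1000 / gm$dx
  if (abs(cells_per_block - round(cells_per_block)) > 1e-9)
    stop("block size must be an integer multiple of the cell size")
  k <- as.integer(round(cells_per_block))
  rows_g <- (seq_len(gm$nrow) - 1L) %/% k
  cols_g <- (seq_len(gm$ncol) - 1L) %/% k
  bid <- outer(rows_g, cols_g, function(r, c) sprintf("B_%d_%d", r, c))
  v <- aai$values
  valid <- !is.na(v)
  v[!valid] <- 0
  area_ha <- cell_area_ha(gm)
  taai <- tapply(as.vector(v), as.vector(bid), sum)
  ta <- tapply(as.vector(valid) * area_ha, as.vector(bid), sum)
  keep <- ta > 0
  data.frame(block_id = names(taai)[keep],
             ip = 100 * as.numeric(taai)[keep] / as.numeric(ta)[keep],
             row.names = NULL)
}

#' Pair and filter block percentages from two sources
#'
#' Keeps blocks present on both sides whose irrigated percentages are
#' both at or above the minimum (inclusive boundary; default 0.3%, the
#' threshold below which point surveys are prone to omission).
#'
#' @param a,b data.frames with `block_id` and `ip` columns.
#' @param min_ip_pct inclusive minimum irrigated percentage.
#' @return data.frame `block_id`, `ip_a`, `ip_b`.
#' @export
paired_filter <- function(a, b, min_ip_pct = 0.3) {
  m <- merge(a[c("block_id", "ip")], b[c("block_id", "ip")],
             by = "block_id", suffixes = c("_a", "_b"))
  m <- m[m$ip_a >= min_ip_pct & m$ip_b >= min_ip_pct, ]
  rownames(m) <- NULL
  m
}

#' Agreement statistics between paired block percentages
#'
#' Pearson correlation between the two sides, ordinary least-squares
#' slope of side b regressed on side a, the two-sided p-value from the
#' correlation's t statistic on n - 2 degrees of freedom, and the
#' conventional significance stars. Zero variance on either side yields
#' a flagged result with `NA` statistics instead of an error.
#'
#' @param pairs output of [paired_filter()] (columns `ip_a`, `ip_b`).
#' @param crop_code optional label carried into the result.
#' @return one-row data.frame `crop_code`, `n_blocks`, `pearson_r`,
#'   `slope`, `p_value`, `stars`, `flagged`.
#' @export
agreement_stats <- function(pairs, crop_code = NA_character_) {
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 paired blocks, got ", n)
  a <- pairs$ip_a; b <- pairs$ip_b
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    return(data.frame(crop_code = crop_code, n_blocks = n,
                      pearson_r = NA_real_, slope = NA_real_,
                      p_value = NA_real_, stars = "ns", flagged = TRUE))
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  slope <- unname(stats::coef(stats::lm(b ~ a))[2])
  p <- ct$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  data.frame(crop_code = crop_code, n_blocks = n,
             pearson_r = unname(ct$estimate), slope = slope, p_value = p,
             stars = stars, flagged = FALSE)
}
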