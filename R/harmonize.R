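# Multi-resolution equipped-area (AEI) harmonization.
#
# The equipped-area input stack mixes a fine-resolution snapshot (2005-
# style, e.g. 0.6 arc-min emulated here as the 1-km grid) and a coarse
# snapshot for the mapping reference year (2010-style, 5 arc-min emulated
# as an integer block nesting). The coarse/fine pair is combined into a
# fine-resolution reference-year map by (1) block-summing the fine map to
# the coarse grid, (2) forming the per-coarse-cell change ratio,
# (3) bilinearly resampling ratio and fine map to the target grid and
# (4) multiplying.

#' Block-sum aggregation of a fine grid to a coarse grid
#'
#' Each coarse cell is the sum of its `factor` x `factor` block of fine
#' cells. Nodata members are treated as zero; their count is returned as a
#' diagnostic attribute `n_nodata`.
#'
#' @param fine a `grid` whose dimensions are divisible by `factor`.
#' @param factor integer nesting of fine cells per coarse cell per axis.
#' @return a coarse `grid` (same units, scaled geometry) with attribute
#'   `n_nodata`.
#' @export
aggregate_block_sum <- function(fine, factor) {
  stopifnot(inherits(fine, "grid"))
  factor <- as.integer(factor)
  nr <- nrow(fine$values); nc <- ncol(fine$values)
  if (factor < 1L) stop("factor must be a positive integer")
  if (nr %% factor != 0L || nc %% factor != 0L)
    stop(sprintf("grid dimensions (%d x %d) not divisible by factor %d",
                 nr, nc, factor))
  v <- fine$values
  n_nodata <- sum(is.na(v))
  v[is.na(v)] <- 0
  # sum factor-blocks: collapse rows then columns
  rows_g <- (seq_len(nr) - 1L) %/% factor
  cols_g <- (seq_len(nc) - 1L) %/% factor
  coarse <- rowsum(v, rows_g)
  coarse <- t(rowsum(t(coarse), cols_g))
  out <- grid_create(unname(coarse), x0 = fine$x0, y0 = fine$y0,
                     dx = fine$dx * factor, dy = fine$dy * factor,
                     nodata = fine$nodata, units = fine$units, crs = fine$crs)
  attr(out, "n_nodata") <- n_nodata
  out
}

#' Per-cell change ratio between two equipped-area snapshots
#'
#' Forms the percent ratio between two co-registered coarse grids. The
#' published formula defines the ratio as 100 x old/new, yet it is then
#' used as a multiplier on the old map to estimate the new one; only the
#' inverted orientation (100 x new/old) makes that product consistent
#' with the new-snapshot totals, so `inverted` is the default and
#' `as_printed` is retained for literal reproduction.
#'
#' Zero-denominator cells get ratio 0 and are flagged (attribute
#' `flagged`, a logical matrix): a cell with no equipped area in the
#' denominator year carries no harmonized infrastructure downstream.
#'
#' @param coarse_2005,coarse_2010 coarse `grid`s with identical geometry.
#' @param orientation `"inverted"` (default, 100 x 2010/2005) or
#'   `"as_printed"` (100 x 2005/2010).
#' @return a percent `grid` with attribute `flagged`.
#' @export
change_ratio <- function(coarse_2005, coarse_2010,
                         orientation = c("inverted", "as_printed")) {
  orientation <- match.arg(orientation)
  stop_if_geom_mismatch(coarse_2005, coarse_2010, "change_ratio")
  num <- if (orientation == "inverted") coarse_2010$values else coarse_2005$values
  den <- if (orientation == "inverted") coarse_2005$values else coarse_2010$values
  flagged <- !is.na(den) & den == 0
  ratio <- 100 * num / den
  ratio[flagged] <- 0
  out <- grid_create(ratio, x0 = coarse_2005$x0, y0 = coarse_2005$y0,
                     dx = coarse_2005$dx, dy = coarse_2005$dy,
                     nodata = coarse_2005$nodata, units = "percent",
                     crs = coarse_2005$crs)
  attr(out, "flagged") <- flagged
  out
}

#' Bilinear resampling onto a target geometry
#'
#' Each target cell centre is mapped into source cell-centre coordinates
#' and assigned the bilinear combination of the four surrounding source
#' centres. Outside the outer lattice of source centres, coordinates are
#' clamped to the boundary centres (edge replication), so no nodata
#' fringe is produced at the rim. If any of the four contributing
#' neighbours is nodata, the output cell is nodata.
#'
#' @param src a `grid` with at least 2 rows and 2 columns.
#' @param target a [grid_geometry()] describing the output grid.
#' @return a `grid` on the target geometry.
#' @export
resample_bilinear <- function(src, target) {
  stopifnot(inherits(src, "grid"), inherits(target, "grid_geometry"))
  nr <- nrow(src$values); nc <- ncol(src$values)
  if (nr < 2L || nc < 2L)
    stop("resample_bilinear: source grid must have at least 2x2 cells")
  ctr <- geom_centers(target)
  # fractional source indices (1-based, at cell centres)
  fj <- (ctr$x - src$x0) / src$dx + 0.5
  fi <- (src$y0 - ctr$y) / src$dy + 0.5
  fj <- pmin(pmax(fj, 1), nc)   # clamp to boundary centres
  fi <- pmin(pmax(fi, 1), nr)
  j0 <- pmin(floor(fj), nc - 1L); i0 <- pmin(floor(fi), nr - 1L)
  tx <- fj - j0                 # in [0, 1]
  ty <- fi - i0
  v <- src$values
  out <- matrix(NA_real_, target$nrow, target$ncol)
  for (i in seq_len(target$nrow)) {
    r0 <- i0[i]; wy <- ty[i]
    v00 <- v[r0, j0];      v01 <- v[r0, j0 + 1L]
    v10 <- v[r0 + 1L, j0]; v11 <- v[r0 + 1L, j0 + 1L]
    out[i, ] <- (1 - tx) * (1 - wy) * v00 + tx * (1 - wy) * v01 +
      (1 - tx) * wy * v10 + tx * wy * v11
  }
  grid_create(out, x0 = target$x0, y0 = target$y0, dx = target$dx,
              dy = target$dy, nodata = src$nodata, units = src$units,
              crs = target$crs)
}

#' Harmonized reference-year equipped area on the target grid
#'
#' Multiplies the fine-resolution snapshot (resampled to the target grid)
#' by the percent change ratio (also on the target grid):
#' `output = ratio / 100 * fine`. Cells whose coarse ratio was flagged
#' for a zero denominator are already 0 in the ratio grid and therefore 0
#' in the output.
#'
#' @param fine_2005_on_1km fine-snapshot `grid` on the target geometry (ha).
#' @param ratio_on_1km percent ratio `grid` on the same geometry.
#' @return a `grid` of harmonized equipped area (ha).
#' @export
harmonized_aei <- function(fine_2005_on_1km, ratio_on_1km) {
  stop_if_geom_mismatch(fine_2005_on_1km, ratio_on_1km, "harmonized_aei")
  out <- ratio_on_1km$values / 100 * fine_2005_on_1km$values
  grid_create(out, x0 = fine_2005_on_1km$x0, y0 = fine_2005_on_1km$y0,
              dx = fine_2005_on_1km$dx, dy = fine_2005_on_1km$dy,
              nodata = fine_2005_on_1km$nodata,
              units = fine_2005_on_1km$units, crs = fine_2005_on_1km$crs)
}
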