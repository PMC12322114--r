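# Planar single-band raster container used throughout the pipeline.
#
# Conventions: 0-based cell indices with row 0 at the top; cell (i, j) has
# centre x = x0 + (j + 0.5) * dx, y = y0 - (i + 0.5) * dy; intervals are
# half-open. In memory, nodata cells are NA; the numeric sentinel is only
# materialized on write.

#' Create a planar raster grid
#'
#' A `grid` is a single-band planar raster: a numeric matrix plus an affine
#' transform (top-left origin and cell size), a nodata sentinel, a units
#' declaration and an EPSG code. Row 1 of the matrix is the top row of the
#' raster; cell `(i, j)` (1-based here) has its centre at
#' `x = x0 + (j - 0.5) * dx`, `y = y0 - (i - 0.5) * dy`.
#'
#' @param values numeric matrix; `NA` marks nodata cells.
#' @param x0,y0 coordinates of the top-left corner of the top-left cell.
#' @param dx,dy cell size in map units (both positive; `dy` is the step
#'   downwards from `y0`).
#' @param nodata numeric sentinel used when the grid is written to file.
#' @param units free-text declaration of what the values mean
#'   (e.g. `"ha"`, `"percent"`, `"fraction"`).
#' @param crs EPSG code of the projected CRS (default 3035, the European
#'   Lambert azimuthal equal-area grid).
#' @return an object of class `grid`.
#' @export
grid_create <- function(values, x0 = 0, y0 = nrow(values) * dy, dx = 1000,
                        dy = dx, nodata = -9999, units = "ha", crs = 3035L) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (dx <= 0 || dy <= 0) stop("cell size must be positive")
  structure(
    list(values = values, x0 = as.numeric(x0), y0 = as.numeric(y0),
         dx = as.numeric(dx), dy = as.numeric(dy),
         nodata = as.numeric(nodata), units = units, crs = as.integer(crs)),
    class = "grid")
}

#' @export
print.grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid> %d x %d cells, %g x %g map units, units='%s', EPSG:%d\n",
              nrow(v), ncol(v), x$dx, x$dy, x$units, x$crs))
  cat(sprintf("  origin (top-left): (%g, %g); nodata sentinel %g; %d NA cells\n",
              x$x0, x$y0, x$nodata, sum(is.na(v))))
  rng <- range(v, na.rm = TRUE)
  cat(sprintf("  value range: [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.grid <- function(x) dim(x$values)

#' Grid geometry descriptor
#'
#' The geometry of a grid (everything except its values): dimensions,
#' origin, cell size and CRS. Used as the target description for
#' [resample_bilinear()].
#'
#' @param nrow,ncol grid dimensions in cells.
#' @param x0,y0 top-left corner coordinates.
#' @param dx,dy cell sizes.
#' @param crs EPSG code.
#' @return a list of class `grid_geometry`.
#' @export
grid_geometry <- function(nrow, ncol, x0 = 0, y0 = nrow * dy, dx = 1000,
                          dy = dx, crs = 3035L) {
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 x0 = as.numeric(x0), y0 = as.numeric(y0),
                 dx = as.numeric(dx), dy = as.numeric(dy),
                 crs = as.integer(crs)),
            class = "grid_geometry")
}

#' Extract the geometry of an existing grid
#' @param g a `grid`.
#' @return a `grid_geometry`.
#' @export
geom_of <- function(g) {
  grid_geometry(nrow(g$values), ncol(g$values), g$x0, g$y0, g$dx, g$dy, g$crs)
}

# x/y coordinates of all cell centres of a geometry
geom_centers <- function(gm) {
  list(x = gm$x0 + (seq_len(gm$ncol) - 0.5) * gm$dx,
       y = gm$y0 - (seq_len(gm$nrow) - 0.5) * gm$dy)
}

#' Test two grids for identical geometry
#' @param a,b grids or `grid_geometry` objects.
#' @param tol absolute tolerance on origin/cell-size comparison.
#' @return logical.
#' @export
same_geometry <- function(a, b, tol = 1e-9) {
  ga <- if (inherits(a, "grid")) geom_of(a) else a
  gb <- if (inherits(b, "grid")) geom_of(b) else b
  ga$nrow == gb$nrow && ga$ncol == gb$ncol &&
    abs(ga$x0 - gb$x0) < tol && abs(ga$y0 - gb$y0) < tol &&
    abs(ga$dx - gb$dx) < tol && abs(ga$dy - gb$dy) < tol
}

stop_if_geom_mismatch <- function(a, b, what = "grids") {
  if (!same_geometry(a, b)) stop(what, ": geometry mismatch")
  invisible(NULL)
}

#' Cell area in hectares
#' @param g a `grid` or `grid_geometry`.
#' @return scalar hectares per cell.
#' @export
cell_area_ha <- function(g) {
  gm <- if (inherits(g, "grid")) geom_of(g) else g
  gm$dx * gm$dy / 1e4
}

# map coordinates -> 1-based (row, col), half-open cells; points outside
# the grid get NA. A point on a shared edge belongs to the cell to its
# lower-left in index space (i.e. larger row / its own column).
cell_index_of <- function(gm, x, y) {
  j <- floor((x - gm$x0) / gm$dx) + 1
  i <- floor((gm$y0 - y) / gm$dy) + 1
  bad <- i < 1 | i > gm$nrow | j < 1 | j > gm$ncol
  i[bad] <- NA_integer_
  j[bad] <- NA_integer_
  list(row = as.integer(i), col = as.integer(j))
}
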