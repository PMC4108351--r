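#' Grid specification
#'
#' Describes a north-up raster grid in projected planar coordinates.
#' Row 1 is the northernmost row; cell `(r, c)` covers the half-open square
#' `[x0 + (c-1) s, x0 + c s) x (y0 - r s, y0 - (r-1) s]` where `s` is the
#' cell size in meters and `(x0, y0)` is the top-left corner. Two layers may
#' be combined only if their grid specs are identical.
#'
#' @param nrows,ncols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in meters (default 60, a resolution
#'   comparable to suburban residential lot sizes).
#' @param origin_x,origin_y Map coordinates of the grid's top-left corner.
#' @param crs_tag Opaque identifier of the projected coordinate system.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(nrows, ncols, cell_size = 60,
                      origin_x = 0, origin_y = nrows * cell_size,
                      crs_tag = "local-planar") {
  nrows <- as.integer(nrows); ncols <- as.integer(ncols)
  stopifnot(length(nrows) == 1L, length(ncols) == 1L,
            nrows >= 1L, ncols >= 1L, is.finite(cell_size), cell_size > 0)
  structure(list(nrows = nrows, ncols = ncols, cell_size = cell_size,
                 origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 crs_tag = as.character(crs_tag)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %g m, origin (%g, %g), crs '%s'\n",
              x$nrows, x$ncols, x$cell_size, x$origin_x, x$origin_y,
              x$crs_tag))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%gm", x$nrows, x$ncols, x$cell_size)
}

#' Test whether two grid specs are identical
#'
#' @param a,b `grid_spec` objects.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b) {
  a$nrows == b$nrows && a$ncols == b$ncols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y)) &&
    identical(a$crs_tag, b$crs_tag)
}

stop_if_misaligned <- function(a, b, what = "layers") {
  sa <- if (inherits(a, "raster_layer")) a$spec else a
  sb <- if (inherits(b, "raster_layer")) b$spec else b
  if (!same_grid(sa, sb)) {
    stop("cannot combine ", what, " on different grids (",
         format(sa), " vs ", format(sb),
         "); resample inputs explicitly before calling", call. = FALSE)
  }
  invisible(TRUE)
}

#' Area of one grid cell in square kilometers
#' @param spec A `grid_spec`.
#' @return Cell area in km^2.
#' @export
cell_area_km2 <- function(spec) (spec$cell_size / 1000)^2

raster_kinds <- c("slope_percent", "landcover_class", "exclusion_weight",
                  "urban_flag", "road_weight", "density", "probability")

#' Raster layer
#'
#' A single-variable grid tied to a [grid_spec()]. `values` is an
#' `nrows x ncols` matrix whose first row is the northernmost row. Missing
#' cells are `NA`. The `kind` determines validation: slope is a non-negative
#' percent, exclusion weights lie in \[0, 100\], urban flags are 0/1,
#' land-cover classes must belong to the declared legend, and probabilities
#' lie in \[0, 1\].
#'
#' @param spec A [grid_spec()].
#' @param values Numeric matrix (`spec$nrows` x `spec$ncols`) or a scalar to
#'   fill the grid with.
#' @param kind One of `r paste0('"', raster_kinds, '"', collapse = ", ")`.
#' @param legend For `landcover_class` layers, the vector of allowed class
#'   codes (optionally named by class label).
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(spec, values, kind, legend = NULL) {
  kind <- match.arg(kind, raster_kinds)
  if (length(values) == 1L) values <- matrix(values, spec$nrows, spec$ncols)
  if (!is.matrix(values) || nrow(values) != spec$nrows ||
      ncol(values) != spec$ncols) {
    stop("values must be a ", spec$nrows, " x ", spec$ncols, " matrix",
         call. = FALSE)
  }
  storage.mode(values) <- "double"
  x <- structure(list(spec = spec, values = values, kind = kind,
                      legend = legend),
                 class = "raster_layer")
  validate_raster(x)
  x
}

validate_raster <- function(x) {
  v <- x$values
  bad <- switch(x$kind,
    slope_percent    = which(!is.na(v) & v < 0),
    exclusion_weight = which(!is.na(v) & (v < 0 | v > 100)),
    urban_flag       = which(!is.na(v) & !(v %in% c(0, 1))),
    probability      = which(!is.na(v) & (v < 0 | v > 1)),
    landcover_class  = if (!is.null(x$legend))
                         which(!is.na(v) & !(v %in% x$legend)) else integer(0),
    integer(0))
  if (length(bad)) {
    i <- bad[1L]
    rc <- arrayInd(i, dim(v))
    stop(sprintf(
      "invalid %s value %g at cell (%d, %d)%s",
      x$kind, v[i], rc[1L], rc[2L],
      if (length(bad) > 1L) sprintf(" (and %d more)", length(bad) - 1L)
      else ""), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_layer:%s> %s, range [%s, %s], %d NA\n",
              x$kind, format(x$spec),
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE))),
              sum(is.na(v))))
  invisible(x)
}

# cell centers, used by windowed density and point-in-cell lookups
cell_center_x <- function(spec, col) spec$origin_x + (col - 0.5) * spec$cell_size
cell_center_y <- function(spec, row) spec$origin_y - (row - 0.5) * spec$cell_size

#' Map coordinates to grid cell indices
#'
#' Uses the half-open cell convention: a point on a cell's west or north
#' boundary belongs to that cell.
#'
#' @param spec A `grid_spec`.
#' @param x,y Numeric vectors of map coordinates.
#' @return A two-column integer matrix (`row`, `col`); `NA` rows for points
#'   outside the grid.
#' @export
xy_to_cell <- function(spec, x, y) {
  col <- floor((x - spec$origin_x) / spec$cell_size) + 1
  row <- floor((spec$origin_y - y) / spec$cell_size) + 1
  # a point exactly on the south/east grid edge belongs to the last cell
  col[x == spec$origin_x + spec$ncols * spec$cell_size] <- spec$ncols
  row[y == spec$origin_y - spec$nrows * spec$cell_size] <- spec$nrows
  out <- cbind(row = as.integer(row), col = as.integer(col))
  bad <- out[, 1L] < 1L | out[, 1L] > spec$nrows |
         out[, 2L] < 1L | out[, 2L] > spec$ncols
  out[bad, ] <- NA_integer_
  out
}

#' Urban area of a flag layer in square kilometers
#' @param urban An `urban_flag` raster layer.
#' @return Total urban area in km^2.
#' @export
urban_area_km2 <- function(urban) {
  stopifnot(inherits(urban, "raster_layer"), urban$kind == "urban_flag")
  sum(urban$values, na.rm = TRUE) * cell_area_km2(urban$spec)
}
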