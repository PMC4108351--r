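#' Street-network line density
#'
#' Length of road per unit area, in km of road per km^2. With `radius = 0`
#' the value is the exact polyline length clipped to each cell divided by
#' the cell area. With a positive radius, the per-cell lengths are summed
#' over the discrete disc of cells whose centers lie within `radius` meters
#' of the focal cell's center, and divided by the summed area of those
#' cells (the disc is truncated at the grid border).
#'
#' @param network A [road_network()].
#' @param spec Target [grid_spec()].
#' @param radius Window radius in meters (0 = per-cell density).
#' @param exclude_classes Road class codes left out of the density signal
#'   (default none; limited-access highways are commonly excluded because
#'   they do not indicate residential development).
#' @return A `density` [raster_layer()] in km/km^2.
#' @export
compute_line_density <- function(network, spec, radius = 0,
                                 exclude_classes = integer()) {
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  segs <- network_segments(network, drop_classes = exclude_classes)
  if (nrow(segs$coords) == 0L) {
    lengths_m <- matrix(0, spec$nrows, spec$ncols)
  } else {
    lengths_m <- line_length_grid_cpp(segs$coords, spec$nrows, spec$ncols,
                                      spec$cell_size, spec$origin_x,
                                      spec$origin_y)
  }
  cell_area_m2 <- spec$cell_size^2
  if (radius == 0) {
    dens <- lengths_m / cell_area_m2 * 1000  # m/m^2 -> km/km^2
    return(raster_layer(spec, dens, kind = "density"))
  }
  # discrete disc: offsets whose center-to-center distance is <= radius
  k <- floor(radius / spec$cell_size)
  offs <- expand.grid(dr = -k:k, dc = -k:k)
  keep <- (offs$dr * spec$cell_size)^2 + (offs$dc * spec$cell_size)^2 <=
    radius^2
  offs <- offs[keep, , drop = FALSE]
  total <- matrix(0, spec$nrows, spec$ncols)
  ncells <- matrix(0, spec$nrows, spec$ncols)
  for (i in seq_len(nrow(offs))) {
    total <- total + shift_matrix(lengths_m, offs$dr[i], offs$dc[i], 0)
    ncells <- ncells + shift_matrix(matrix(1, spec$nrows, spec$ncols),
                                    offs$dr[i], offs$dc[i], 0)
  }
  dens <- total / (ncells * cell_area_m2) * 1000
  raster_layer(spec, dens, kind = "density")
}

# value of cell (r+dr, c+dc) brought to position (r, c); `fill` outside
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 - dr):min(nr, nr - dr)
  cs <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Density thresholds for urban delineation
#'
#' @param t_low Lower density threshold in km/km^2: cells at or above it
#'   that also carry an urban land-cover class are urban.
#' @param t_high Higher threshold: cells at or above it are urban
#'   regardless of land cover (captures low-density suburbs the land-cover
#'   product misses).
#' @param radius Density window radius in meters.
#' @return A list of class `density_params`.
#' @export
density_params <- function(t_low = 4, t_high = 8, radius = 300) {
  if (!(t_low > 0 && t_low < t_high))
    stop("thresholds must satisfy 0 < t_low < t_high", call. = FALSE)
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  structure(list(t_low = t_low, t_high = t_high, radius = radius),
            class = "density_params")
}

#' Classify urban extent from street density and land cover
#'
#' A cell is urban iff (its street density reaches `t_low` AND its
#' land-cover class is one of `urban_classes`) OR its density reaches
#' `t_high`.
#'
#' @param density A `density` [raster_layer()] in km/km^2.
#' @param landcover A `landcover_class` raster on the same grid.
#' @param urban_classes Vector of land-cover codes counted as urban.
#' @param params A [density_params()].
#' @return An `urban_flag` [raster_layer()].
#' @export
classify_urban_extent <- function(density, landcover, urban_classes,
                                  params = density_params()) {
  stopifnot(inherits(density, "raster_layer"), density$kind == "density",
            inherits(landcover, "raster_layer"),
            landcover$kind == "landcover_class")
  stop_if_misaligned(density, landcover)
  d <- density$values
  lc <- landcover$values
  urb <- (d >= params$t_low & lc %in% urban_classes) | d >= params$t_high
  urb[is.na(d)] <- NA
  raster_layer(density$spec, urb * 1, kind = "urban_flag")
}

#' Build a historic urban series from dated street networks
#'
#' Computes the windowed line density of each dated network, classifies the
#' urban extent against the (static) land-cover layer, and assembles the
#' dated layers into a monotone [historic_series()].
#'
#' @param networks List of >= 3 [road_network()]s with strictly increasing
#'   dates.
#' @param landcover `landcover_class` raster.
#' @param urban_classes Land-cover codes counted as urban.
#' @param params A [density_params()].
#' @param exclude_classes Road classes left out of the density signal.
#' @param quiet Suppress the monotonicity-flip log.
#' @return A [historic_series()].
#' @export
build_historic_series <- function(networks, landcover, urban_classes,
                                  params = density_params(),
                                  exclude_classes = integer(),
                                  quiet = FALSE) {
  if (length(networks) < 3L)
    stop("calibration needs street networks for >= 3 dates", call. = FALSE)
  dates <- vapply(networks, function(n) n$date, integer(1))
  layers <- lapply(networks, function(n) {
    d <- compute_line_density(n, landcover$spec, radius = params$radius,
                              exclude_classes = exclude_classes)
    classify_urban_extent(d, landcover, urban_classes, params)
  })
  historic_series(dates, layers, road_networks = networks, quiet = quiet)
}

#' Accuracy assessment against reference points
#'
#' Compares a classified urban layer with manually labelled reference
#' points. Commission error is the percentage of classified-urban points
#' whose reference label is rural; omission error is the percentage of
#' reference-urban points classified rural. An empty denominator yields
#' `NA` (undefined), never 0.
#'
#' @param classified An `urban_flag` [raster_layer()].
#' @param reference Data frame with columns `x`, `y` (map coordinates
#'   inside the grid) and `label` (`"urban"` or `"rural"`).
#' @return A list of class `accuracy_assessment` with `n_points`, the 2x2
#'   confusion `counts`, `commission_pct` and `omission_pct`.
#' @export
assess_accuracy <- function(classified, reference) {
  stopifnot(inherits(classified, "raster_layer"),
            classified$kind == "urban_flag",
            all(c("x", "y", "label") %in% names(reference)))
  lab <- as.character(reference$label)
  if (!all(lab %in% c("urban", "rural")))
    stop("reference labels must be 'urban' or 'rural'", call. = FALSE)
  rc <- xy_to_cell(classified$spec, reference$x, reference$y)
  if (anyNA(rc))
    stop("reference point(s) outside the grid: rows ",
         paste(which(is.na(rc[, 1L])), collapse = ", "), call. = FALSE)
  cls <- classified$values[rc] == 1
  ref <- lab == "urban"
  counts <- c(classified_urban_ref_urban = sum(cls & ref),
              classified_urban_ref_rural = sum(cls & !ref),
              classified_rural_ref_urban = sum(!cls & ref),
              classified_rural_ref_rural = sum(!cls & !ref))
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(
    n_points = nrow(reference),
    counts = counts,
    commission_pct = pct(counts[["classified_urban_ref_rural"]],
                         sum(cls)),
    omission_pct = pct(counts[["classified_rural_ref_urban"]],
                       sum(ref))),
    class = "accuracy_assessment")
}

#' @export
print.accuracy_assessment <- function(x, ...) {
  cat(sprintf("<accuracy_assessment> n = %d, commission %s%%, omission %s%%\n",
              x$n_points, format(x$commission_pct),
              format(x$omission_pct)))
  invisible(x)
}
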