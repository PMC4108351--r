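#' Historic urban series
#'
#' A dated sequence of observed urban extents plus the street networks they
#' were derived from; the calibration target. Urbanization is treated as
#' irreversible, so monotonicity is enforced at construction by
#' OR-accumulating each date's urban set into all later dates; the number
#' of cells flipped back to urban this way is recorded in `flips`.
#'
#' @param dates Integer years, strictly increasing, length >= 3.
#' @param urban_layers List of `urban_flag` rasters, one per date, on one
#'   shared grid.
#' @param road_networks Optional list of >= 2 dated [road_network()]s.
#' @param quiet Suppress the flipped-cell log message.
#' @return A list of class `historic_series`.
#' @export
historic_series <- function(dates, urban_layers, road_networks = NULL,
                            quiet = FALSE) {
  dates <- as.integer(dates)
  if (length(dates) < 3L)
    stop("calibration needs the urban extent at >= 3 dates", call. = FALSE)
  if (any(diff(dates) <= 0))
    stop("dates must be strictly increasing", call. = FALSE)
  if (length(urban_layers) != length(dates))
    stop("need one urban layer per date", call. = FALSE)
  for (l in urban_layers) {
    stopifnot(inherits(l, "raster_layer"), l$kind == "urban_flag")
    stop_if_misaligned(urban_layers[[1L]], l)
  }
  if (!is.null(road_networks)) {
    if (length(road_networks) < 2L)
      stop("need road networks for >= 2 dates", call. = FALSE)
    rd <- vapply(road_networks, function(n) n$date, integer(1))
    if (any(diff(rd) <= 0))
      stop("road network dates must be strictly increasing", call. = FALSE)
  }
  flips <- 0L
  for (i in seq_along(urban_layers)[-1L]) {
    prev <- urban_layers[[i - 1L]]$values
    cur <- urban_layers[[i]]$values
    flip <- prev == 1 & cur == 0
    flips <- flips + sum(flip, na.rm = TRUE)
    cur[flip] <- 1
    urban_layers[[i]]$values <- cur
  }
  if (flips > 0L && !quiet)
    message("historic series: ", flips,
            " cell-date(s) flipped back to urban to enforce monotonicity")
  structure(list(dates = dates, urban_layers = urban_layers,
                 road_networks = road_networks, flips = flips),
            class = "historic_series")
}

#' @export
print.historic_series <- function(x, ...) {
  areas <- vapply(x$urban_layers, function(l) sum(l$values, na.rm = TRUE),
                  numeric(1))
  cat("<historic_series>", format(x$urban_layers[[1L]]$spec), "\n")
  cat("  dates:", paste(x$dates, collapse = ", "), "\n")
  cat("  urban cells:", paste(areas, collapse = ", "),
      sprintf("(%d monotonicity flips)\n", x$flips))
  invisible(x)
}

#' Calibration sub-region
#'
#' A named boolean mask over the shared grid. Distinct sub-regions must be
#' disjoint; growth outside a sub-region's mask is frozen during its
#' calibration and projection.
#'
#' @param id Character identifier.
#' @param mask Logical matrix aligned to the grid.
#' @param spec The shared [grid_spec()].
#' @return A list of class `sub_region`.
#' @export
sub_region <- function(id, mask, spec) {
  stopifnot(is.matrix(mask), nrow(mask) == spec$nrows,
            ncol(mask) == spec$ncols)
  mask <- !is.na(mask) & mask
  if (!any(mask)) stop("sub-region '", id, "' has an empty mask",
                       call. = FALSE)
  structure(list(id = as.character(id), mask = mask, spec = spec),
            class = "sub_region")
}

check_disjoint <- function(subregions) {
  if (length(subregions) < 2L) return(invisible(TRUE))
  acc <- subregions[[1L]]$mask
  for (i in seq_along(subregions)[-1L]) {
    if (any(acc & subregions[[i]]$mask))
      stop("sub-region masks overlap (", subregions[[i]]$id, ")",
           call. = FALSE)
    acc <- acc | subregions[[i]]$mask
  }
  invisible(TRUE)
}
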