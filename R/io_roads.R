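#' Road network
#'
#' Dated street polylines in projected map coordinates. Each segment list
#' element is an `n x 2` matrix of vertices; `class_code` carries a
#' TIGER-style functional class per polyline (1 = limited-access highway,
#' 2 = arterial, 3 = collector, 4 = local street by the package's default
#' coding) and `weight` a positive influence weight used by road-influenced
#' growth.
#'
#' @param date Observation year.
#' @param segments List of `n x 2` coordinate matrices (n >= 2).
#' @param class_code Integer vector, one code per polyline.
#' @param weight Positive numeric vector, one weight per polyline.
#' @return An object of class `road_network`.
#' @export
road_network <- function(date, segments = list(),
                         class_code = rep.int(4L, length(segments)),
                         weight = rep.int(1, length(segments))) {
  stopifnot(is.list(segments),
            length(class_code) == length(segments),
            length(weight) == length(segments))
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    if (!is.matrix(s) || ncol(s) != 2L || nrow(s) < 2L || !all(is.finite(s)))
      stop("segment ", i, " is not a finite n x 2 polyline matrix",
           call. = FALSE)
  }
  if (length(weight) && any(weight <= 0))
    stop("road weights must be positive", call. = FALSE)
  structure(list(date = as.integer(date), segments = segments,
                 class_code = as.integer(class_code),
                 weight = as.numeric(weight)),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> year %d, %d polylines, %.2f km total\n",
              x$date, length(x$segments), total_length_m(x) / 1000))
  invisible(x)
}

#' Total polyline length of a road network in meters
#' @param network A [road_network()].
#' @return Length in meters.
#' @export
total_length_m <- function(network) {
  sum(vapply(network$segments, function(s) {
    d <- diff(s)
    sum(sqrt(rowSums(d^2)))
  }, numeric(1)))
}

#' Read a road network from GeoJSON
#'
#' Accepts a FeatureCollection of `LineString` / `MultiLineString` features.
#' The functional class is read from a `class_code` property (features
#' lacking one get `default_class`); an optional `weight` property supplies
#' per-feature weights (default 1).
#'
#' @param path Path to a GeoJSON file.
#' @param date Year to stamp the network with; if `NULL`, taken from a
#'   top-level `date` member of the file (error if absent).
#' @param default_class Class code for features without a `class_code`.
#' @return A [road_network()].
#' @export
read_roads <- function(path, date = NULL, default_class = 4L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path,
                                 call. = FALSE)
  if (is.null(date)) {
    if (is.null(gj$date)) stop("no date given and none stored in ", path,
                               call. = FALSE)
    date <- gj$date
  }
  segs <- list(); cls <- integer(); wt <- numeric()
  bad <- integer()
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    g <- f$geometry
    coords <- switch(g$type %||% "",
      LineString = list(g$coordinates),
      MultiLineString = g$coordinates,
      { bad <- c(bad, i); NULL })
    if (is.null(coords)) next
    cc <- f$properties$class_code %||% default_class
    w <- f$properties$weight %||% 1
    for (line in coords) {
      m <- do.call(rbind, lapply(line, function(p) c(p[[1L]], p[[2L]])))
      segs[[length(segs) + 1L]] <- m
      cls <- c(cls, as.integer(cc)); wt <- c(wt, as.numeric(w))
    }
  }
  if (length(bad)) {
    stop("non-line geometries in ", path, " at feature(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  road_network(date, segs, cls, wt)
}

#' Write a road network as GeoJSON
#'
#' @param network A [road_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roads <- function(network, path) {
  stopifnot(inherits(network, "road_network"))
  feats <- lapply(seq_along(network$segments), function(i) {
    s <- network$segments[[i]]
    list(type = "Feature",
         properties = list(class_code = network$class_code[i],
                           weight = network$weight[i]),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(s)),
                                              function(r) as.numeric(s[r, ]))))
  })
  obj <- list(type = "FeatureCollection", date = network$date,
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
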