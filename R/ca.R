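#' Growth coefficient set
#'
#' The five coefficients governing the cellular automaton's four annual
#' growth phases, each an integer in \[0, 100\]: `dispersion` scales the
#' number of spontaneous-growth attempts (and the length of road walks),
#' `breed` the chance that a new cell seeds a spreading center or road
#' nucleus, `spread` the per-cell probability of edge growth, and
#' `slope_resistance` / `road_gravity` the sensitivity to terrain and the
#' reach of road-influenced growth.
#'
#' @param dispersion,breed,spread,slope_resistance,road_gravity Numbers in
#'   \[0, 100\].
#' @return A named numeric vector of class `coefficient_set`.
#' @export
coefficient_set <- function(dispersion = 0, breed = 0, spread = 0,
                            slope_resistance = 0, road_gravity = 0) {
  v <- c(dispersion = dispersion, breed = breed, spread = spread,
         slope_resistance = slope_resistance, road_gravity = road_gravity)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 100))
    stop("all coefficients must lie in [0, 100]", call. = FALSE)
  structure(as.numeric(v), names = names(v), class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("<coefficient_set>",
      paste(names(x), unclass(x), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Self-modification parameters
#'
#' Feedback that accelerates or damps growth: when the annual growth rate
#' exceeds `critical_high` (percent of current urban area per year) the
#' dispersion, breed and spread coefficients are multiplied by `boom`; when
#' it falls below `critical_low` they are multiplied by `bust`. Results are
#' rounded (half to even) and clamped to \[0, 100\], with a floor of 1 for
#' any coefficient that was positive before the update.
#'
#' @param critical_high,critical_low Growth-rate thresholds in percent per
#'   year (`critical_low < critical_high`).
#' @param boom,bust Multipliers with `bust < 1 < boom`.
#' @param enabled If `FALSE`, self-modification is the identity.
#' @return A list of class `self_mod_params`.
#' @export
self_mod_params <- function(critical_high = 1.3, critical_low = 0.97,
                            boom = 1.1, bust = 0.9, enabled = TRUE) {
  if (critical_low >= critical_high)
    stop("critical_low must be below critical_high", call. = FALSE)
  if (!(bust < 1 && boom > 1))
    stop("self-modification requires bust < 1 < boom", call. = FALSE)
  structure(list(critical_high = critical_high, critical_low = critical_low,
                 boom = boom, bust = bust, enabled = isTRUE(enabled)),
            class = "self_mod_params")
}

#' Cellular-automaton state
#'
#' Bundles the four required input layers (urban extent, percent slope,
#' exclusion/resistance weights, rasterized roads) with the coefficient set
#' and current year. All layers must share one grid and contain no missing
#' cells (mask unusable cells with exclusion weight 100 instead).
#'
#' @param urban `urban_flag` raster.
#' @param slope `slope_percent` raster.
#' @param exclusion `exclusion_weight` raster (100 = never developed).
#' @param roads `road_weight` raster (0 = no road) or `NULL` for a roadless
#'   landscape.
#' @param coeffs A [coefficient_set()].
#' @param year Calendar year of the state.
#' @param critical_slope Percent slope at and above which development is
#'   impossible.
#' @param edge_neighbor_threshold Urban Moore neighbors required for edge
#'   growth (default 3).
#' @return A list of class `ca_state`.
#' @export
ca_state <- function(urban, slope, exclusion, roads = NULL, coeffs,
                     year = 0L, critical_slope = 21,
                     edge_neighbor_threshold = 3L) {
  stopifnot(inherits(urban, "raster_layer"), urban$kind == "urban_flag",
            inherits(slope, "raster_layer"), slope$kind == "slope_percent",
            inherits(exclusion, "raster_layer"),
            exclusion$kind == "exclusion_weight")
  stop_if_misaligned(urban, slope)
  stop_if_misaligned(urban, exclusion)
  if (is.null(roads)) {
    roads <- raster_layer(urban$spec, 0, kind = "road_weight")
  }
  stopifnot(inherits(roads, "raster_layer"), roads$kind == "road_weight")
  stop_if_misaligned(urban, roads)
  if (critical_slope <= 0) stop("critical_slope must be positive",
                                call. = FALSE)
  for (lyr in list(urban, slope, exclusion, roads)) {
    if (anyNA(lyr$values))
      stop("CA input layer of kind '", lyr$kind, "' contains missing ",
           "cells; set exclusion weight 100 there instead", call. = FALSE)
  }
  coeffs <- do.call(coefficient_set, as.list(coeffs))
  structure(list(urban = urban, slope = slope, exclusion = exclusion,
                 roads = roads, coeffs = coeffs, year = as.integer(year),
                 critical_slope = critical_slope,
                 edge_neighbor_threshold = as.integer(edge_neighbor_threshold)),
            class = "ca_state")
}

#' @export
print.ca_state <- function(x, ...) {
  cat(sprintf("<ca_state> year %d, %s, %d urban cells\n", x$year,
              format(x$urban$spec), sum(x$urban$values)))
  print(x$coeffs)
  invisible(x)
}

urban_int <- function(state) {
  m <- state$urban$values
  storage.mode(m) <- "integer"
  m
}

replace_urban <- function(state, m) {
  state$urban$values <- matrix(as.numeric(m), nrow(m), ncol(m))
  state
}

#' Number of spontaneous-growth attempts per year
#'
#' `round(0.005 * dispersion * sqrt(nrows^2 + ncols^2))` with round-half-to-
#' even, the diagonal-scaled dispersion value used by both spontaneous
#' growth and the road-walk length.
#'
#' @param dispersion Dispersion coefficient in \[0, 100\].
#' @param nrows,ncols Grid dimensions.
#' @return Integer attempt count.
#' @export
dispersion_value <- function(dispersion, nrows, ncols) {
  as.integer(round(0.005 * dispersion * sqrt(nrows^2 + ncols^2)))
}

#' Slope acceptance test
#'
#' Development is impossible at or above the critical slope. Below it, a
#' candidate cell is rejected with probability
#' `(slope / critical_slope)^(slope_resistance / 25)`; a zero resistance
#' always accepts below the critical slope.
#'
#' @param slope_value Percent slope of the cell.
#' @param slope_resistance Coefficient in \[0, 100\].
#' @param critical_slope Percent slope cutoff (> 0).
#' @return Logical: accept the cell?
#' @export
slope_accept <- function(slope_value, slope_resistance, critical_slope = 21) {
  if (critical_slope <= 0) stop("critical_slope must be positive",
                                call. = FALSE)
  slope_accept_cpp(slope_value, slope_resistance, critical_slope)
}

#' Attempt to urbanize one cell
#'
#' The shared acceptance gate of all four growth phases: an already-urban
#' cell is refused; otherwise the cell resists with probability
#' `exclusion/100` and must pass [slope_accept()].
#'
#' @param state A [ca_state()].
#' @param cell Length-2 integer vector `(row, col)`.
#' @return List with `accepted` (logical) and the updated `state`.
#' @export
attempt_urbanize <- function(state, cell) {
  r <- as.integer(cell[1L]); c <- as.integer(cell[2L])
  if (r < 1L || r > state$urban$spec$nrows ||
      c < 1L || c > state$urban$spec$ncols)
    stop("cell out of bounds", call. = FALSE)
  res <- attempt_urbanize_cpp(urban_int(state), state$slope$values,
                              state$exclusion$values, r, c,
                              state$coeffs[["slope_resistance"]],
                              state$critical_slope)
  list(accepted = res$accepted, state = replace_urban(state, res$urban))
}

phase_wrap <- function(state, res) {
  cells <- res$cells
  colnames(cells) <- c("row", "col")
  list(state = replace_urban(state, res$urban), cells = cells)
}

#' Spontaneous growth phase
#'
#' Draws [dispersion_value()] uniform random cells and passes each through
#' [attempt_urbanize()] independently.
#'
#' @param state A [ca_state()].
#' @return List with updated `state` and the matrix of newly urban `cells`.
#' @export
spontaneous_growth <- function(state) {
  phase_wrap(state, spontaneous_cpp(urban_int(state), state$slope$values,
                                    state$exclusion$values,
                                    as.numeric(state$coeffs),
                                    state$critical_slope))
}

#' New-spreading-center phase
#'
#' Each spontaneous cell becomes a center with probability `breed/100`; a
#' center attempts to urbanize two distinct random Moore neighbors.
#'
#' @param state A [ca_state()].
#' @param spontaneous_cells Two-column matrix of this step's spontaneous
#'   cells.
#' @return List with updated `state` and new `cells`.
#' @export
new_spreading_centers <- function(state, spontaneous_cells) {
  phase_wrap(state, spreading_cpp(urban_int(state), state$slope$values,
                                  state$exclusion$values,
                                  as.numeric(state$coeffs),
                                  state$critical_slope,
                                  cell_matrix(spontaneous_cells)))
}

#' Edge growth phase
#'
#' Every non-urban cell with at least `edge_neighbor_threshold` urban Moore
#' neighbors (counted synchronously against the start-of-phase urban set)
#' urbanizes with probability `spread/100`, then passes the
#' [attempt_urbanize()] gate.
#'
#' @param state A [ca_state()].
#' @return List with updated `state` and new `cells`.
#' @export
edge_growth <- function(state) {
  phase_wrap(state, edge_cpp(urban_int(state), state$slope$values,
                             state$exclusion$values,
                             as.numeric(state$coeffs), state$critical_slope,
                             state$edge_neighbor_threshold))
}

#' Road-influenced growth phase
#'
#' Each cell newly urbanized this step is selected with probability
#' `breed/100`; for a selected cell the nearest road cell within
#' `road_gravity/100 * (nrows + ncols)/16` cells is found, a random walk of
#' [dispersion_value()] steps (scaled by the road cell's weight) is taken
#' along Moore-connected road cells, and a random neighbor of the terminus
#' is attempted; a success forms a nucleus that attempts two further
#' neighbors.
#'
#' @param state A [ca_state()].
#' @param newly_urbanized Two-column matrix of cells urbanized by the
#'   earlier phases of this step.
#' @return List with updated `state` and new `cells`.
#' @export
road_influenced_growth <- function(state, newly_urbanized) {
  phase_wrap(state, road_cpp(urban_int(state), state$slope$values,
                             state$exclusion$values, state$roads$values,
                             as.numeric(state$coeffs), state$critical_slope,
                             cell_matrix(newly_urbanized)))
}

cell_matrix <- function(cells) {
  if (is.null(cells) || length(cells) == 0L)
    return(matrix(integer(), 0L, 2L))
  m <- as.matrix(cells)
  storage.mode(m) <- "integer"
  m
}

#' One annual growth step
#'
#' Applies the four phases in order (spontaneous, spreading centers, edge,
#' road-influenced). The per-phase counts sum to the change in urban area.
#'
#' @param state A [ca_state()].
#' @return List with the updated `state` and a one-row `stats` data frame
#'   (year, four phase counts, total, growth rate in percent of the
#'   start-of-step urban area).
#' @export
growth_step <- function(state) {
  pop0 <- sum(state$urban$values)
  res <- ca_step_cpp(urban_int(state), state$slope$values,
                     state$exclusion$values, state$roads$values,
                     as.numeric(state$coeffs), state$critical_slope,
                     state$edge_neighbor_threshold)
  state <- replace_urban(state, res$urban)
  state$year <- state$year + 1L
  counts <- res$counts
  total <- sum(counts)
  stats <- data.frame(year = state$year,
                      new_cells_spontaneous = counts[1L],
                      new_cells_spreading_center = counts[2L],
                      new_cells_edge = counts[3L],
                      new_cells_road = counts[4L],
                      total_new = total,
                      growth_rate = if (pop0 > 0) 100 * total / pop0 else 0)
  list(state = state, stats = stats)
}

#' Apply self-modification to a coefficient set
#'
#' @param coeffs A [coefficient_set()].
#' @param growth_rate Annual growth rate in percent.
#' @param params A [self_mod_params()].
#' @return The updated [coefficient_set()].
#' @export
self_modify <- function(coeffs, growth_rate, params = self_mod_params()) {
  if (!params$enabled) return(coeffs)
  mult <- if (growth_rate > params$critical_high) params$boom
          else if (growth_rate < params$critical_low) params$bust
          else return(coeffs)
  for (f in c("dispersion", "breed", "spread")) {
    pre <- coeffs[[f]]
    post <- min(100, max(0, round(pre * mult)))
    if (pre > 0 && post < 1) post <- 1
    coeffs[[f]] <- post
  }
  coeffs
}

#' Run the cellular automaton for a span of years
#'
#' Iterates [growth_step()] then [self_modify()] once per year. Snapshots
#' are deep copies of the urban layer at the requested years.
#'
#' @param initial A [ca_state()].
#' @param years Number of annual steps (>= 1).
#' @param selfmod A [self_mod_params()].
#' @param snapshot_years Calendar years (relative to `initial$year`) at
#'   which to keep urban-extent snapshots; defaults to the final year.
#' @return List of class `ca_run` with `final` state, `stats` data frame
#'   (one row per year), and named `snapshots` (urban rasters).
#' @export
run_simulation <- function(initial, years,
                           selfmod = self_mod_params(),
                           snapshot_years = NULL) {
  stopifnot(inherits(initial, "ca_state"))
  years <- as.integer(years)
  if (is.na(years) || years < 1L)
    stop("years must be a positive integer", call. = FALSE)
  if (is.null(snapshot_years)) snapshot_years <- initial$year + years
  offsets <- sort(unique(as.integer(snapshot_years) - initial$year))
  if (any(offsets < 1L) || any(offsets > years))
    stop("snapshot years must fall within the simulated span", call. = FALSE)
  res <- ca_run_cpp(urban_int(initial), initial$slope$values,
                    initial$exclusion$values, initial$roads$values,
                    as.numeric(initial$coeffs), initial$critical_slope,
                    initial$edge_neighbor_threshold, years, offsets,
                    selfmod$enabled, selfmod$critical_high,
                    selfmod$critical_low, selfmod$boom, selfmod$bust,
                    TRUE, list())
  final <- initial
  final <- replace_urban(final, res$final_urban)
  final$year <- initial$year + years
  final$coeffs <- coefficient_set(res$final_coeffs[1L], res$final_coeffs[2L],
                                  res$final_coeffs[3L], res$final_coeffs[4L],
                                  res$final_coeffs[5L])
  stats <- as.data.frame(res$stats)
  names(stats) <- c("year", "new_cells_spontaneous",
                    "new_cells_spreading_center", "new_cells_edge",
                    "new_cells_road", "growth_rate")
  stats$year <- initial$year + stats$year
  stats$total_new <- stats$new_cells_spontaneous +
    stats$new_cells_spreading_center + stats$new_cells_edge +
    stats$new_cells_road
  snaps <- lapply(res$snapshots, function(m) {
    raster_layer(initial$urban$spec, matrix(as.numeric(m), nrow(m), ncol(m)),
                 kind = "urban_flag")
  })
  names(snaps) <- as.character(initial$year + offsets)
  structure(list(final = final, stats = stats, snapshots = snaps,
                 snap_stats = res$snap_stats),
            class = "ca_run")
}

#' Rasterize a road network for the cellular automaton
#'
#' Each grid cell crossed by a polyline gets the maximum weight among the
#' polylines crossing it; other cells are 0.
#'
#' @param network A [road_network()].
#' @param spec Target [grid_spec()].
#' @return A `road_weight` [raster_layer()].
#' @export
rasterize_roads <- function(network, spec) {
  segs <- network_segments(network)
  if (nrow(segs$coords) == 0L)
    return(raster_layer(spec, 0, kind = "road_weight"))
  m <- rasterize_max_weight_cpp(segs$coords, segs$weight, spec$nrows,
                                spec$ncols, spec$cell_size, spec$origin_x,
                                spec$origin_y)
  raster_layer(spec, m, kind = "road_weight")
}

# flatten polylines to straight-segment rows (x0, y0, x1, y1) with the
# parent polyline's class and weight on each row
network_segments <- function(network, drop_classes = integer()) {
  keep <- !(network$class_code %in% drop_classes)
  coords <- matrix(numeric(), 0L, 4L)
  cls <- integer(); wt <- numeric()
  for (i in which(keep)) {
    s <- network$segments[[i]]
    n <- nrow(s) - 1L
    coords <- rbind(coords, cbind(s[seq_len(n), 1L, drop = TRUE],
                                  s[seq_len(n), 2L, drop = TRUE],
                                  s[seq_len(n) + 1L, 1L, drop = TRUE],
                                  s[seq_len(n) + 1L, 2L, drop = TRUE]))
    cls <- c(cls, rep.int(network$class_code[i], n))
    wt <- c(wt, rep.int(network$weight[i], n))
  }
  list(coords = coords, class_code = cls, weight = wt)
}
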