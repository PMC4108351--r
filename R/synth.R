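#' Land-cover legend used by the synthetic generator
#'
#' @return Named integer vector of class codes.
#' @export
landcover_legend <- function() {
  c(water = 1L, wetland = 2L, forest = 3L, agriculture = 4L,
    grassland = 5L, urban = 6L)
}

#' Parameters of the synthetic study area
#'
#' @param grid A [grid_spec()].
#' @param seed Integer RNG seed; every generator draws from a stream
#'   derived from it, so the full bundle is reproducible.
#' @param n_urban_seeds Number of initial town centers.
#' @param road_hierarchy_levels 1 = arterials only, 2 = + grid-like
#'   collectors around each center, 3 = + dendritic local streets and
#'   cul-de-sacs.
#' @param landcover_class_weights Proportions over the [landcover_legend()]
#'   classes; must sum to 1.
#' @param terrain_roughness Dimensionless amplitude of the synthetic
#'   terrain (0 = perfectly flat).
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(grid = grid_spec(100, 100, cell_size = 60),
                         seed = 1L, n_urban_seeds = 3L,
                         road_hierarchy_levels = 3L,
                         landcover_class_weights = c(
                           water = 0.05, wetland = 0.10, forest = 0.35,
                           agriculture = 0.30, grassland = 0.15,
                           urban = 0.05),
                         terrain_roughness = 1) {
  w <- landcover_class_weights[names(landcover_legend())]
  if (anyNA(w) || any(w < 0) || abs(sum(w) - 1) > 1e-6)
    stop("landcover_class_weights must cover the legend and sum to 1",
         call. = FALSE)
  if (sum(w[names(w) != "water"]) <= 0)
    warning("all weight on water: the landscape has no developable land",
            call. = FALSE)
  if (road_hierarchy_levels < 1L)
    stop("road_hierarchy_levels must be >= 1", call. = FALSE)
  if (terrain_roughness < 0)
    stop("terrain_roughness must be >= 0", call. = FALSE)
  structure(list(grid = grid, seed = as.integer(seed),
                 n_urban_seeds = as.integer(n_urban_seeds),
                 road_hierarchy_levels = as.integer(road_hierarchy_levels),
                 landcover_class_weights = w,
                 terrain_roughness = terrain_roughness),
            class = "synth_params")
}

# separable gaussian smoothing; edge-normalized so means are preserved
smooth_field <- function(m, sigma_cells) {
  op <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    K <- exp(-0.5 * (d / sigma_cells)^2)
    K / rowSums(K)
  }
  op(nrow(m)) %*% m %*% t(op(ncol(m)))
}

#' Percent slope from an elevation grid
#'
#' Central finite differences (one-sided at the border);
#' `slope = 100 * sqrt((dz/dx)^2 + (dz/dy)^2)`.
#'
#' @param elevation Numeric matrix of elevations in meters (row 1 = north).
#' @param cell_size Cell edge length in meters.
#' @return Matrix of percent slopes.
#' @export
slope_from_elevation <- function(elevation, cell_size) {
  nr <- nrow(elevation); nc <- ncol(elevation)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  if (nc >= 3L)
    gx[, 2:(nc - 1)] <- (elevation[, 3:nc] - elevation[, 1:(nc - 2)]) /
      (2 * cell_size)
  if (nc >= 2L) {
    gx[, 1L] <- (elevation[, 2L] - elevation[, 1L]) / cell_size
    gx[, nc] <- (elevation[, nc] - elevation[, nc - 1L]) / cell_size
  }
  if (nr >= 3L)
    gy[2:(nr - 1), ] <- (elevation[1:(nr - 2), ] - elevation[3:nr, ]) /
      (2 * cell_size)
  if (nr >= 2L) {
    gy[1L, ] <- (elevation[1L, ] - elevation[2L, ]) / cell_size
    gy[nr, ] <- (elevation[nr - 1L, ] - elevation[nr, ]) / cell_size
  }
  100 * sqrt(gx^2 + gy^2)
}

#' Generate a synthetic slope surface
#'
#' A spatially autocorrelated elevation field (smoothed Gaussian noise,
#' correlation length ~6 cells, amplitude `50 * terrain_roughness` m) is
#' differentiated into percent slope. Roughness 0 gives a perfectly flat
#' surface.
#'
#' @param params A [synth_params()].
#' @return A `slope_percent` [raster_layer()]; the elevation grid is kept
#'   in attribute `"elevation"`.
#' @export
generate_terrain <- function(params) {
  g <- params$grid
  if (params$terrain_roughness == 0) {
    out <- raster_layer(g, 0, kind = "slope_percent")
    attr(out, "elevation") <- matrix(0, g$nrows, g$ncols)
    return(out)
  }
  set.seed(params$seed + 101L)
  z <- smooth_field(matrix(stats::rnorm(g$nrows * g$ncols), g$nrows,
                           g$ncols), sigma_cells = 6)
  z <- z / stats::sd(z) * 50 * params$terrain_roughness
  out <- raster_layer(g, slope_from_elevation(z, g$cell_size),
                      kind = "slope_percent")
  attr(out, "elevation") <- z
  out
}

#' Draw town-center seed points
#'
#' Uniform within the central 70% of the grid so collector grids fit.
#'
#' @param params A [synth_params()].
#' @return `n_urban_seeds x 2` matrix of map coordinates.
#' @export
generate_seed_points <- function(params) {
  g <- params$grid
  set.seed(params$seed + 102L)
  w <- g$ncols * g$cell_size; h <- g$nrows * g$cell_size
  cbind(x = g$origin_x + stats::runif(params$n_urban_seeds, 0.15, 0.85) * w,
        y = g$origin_y - stats::runif(params$n_urban_seeds, 0.15, 0.85) * h)
}

#' Generate a hierarchical synthetic street network
#'
#' Emulates the fractal-like suburban street pattern: arterials connect the
#' town centers (a minimum spanning tree over the seed points), grid-like
#' collector streets surround each center, and dendritic local streets with
#' cul-de-sac branches fill in around them with density decaying away from
#' the centers.
#'
#' @param params A [synth_params()].
#' @param urban_seed_points `n x 2` matrix of center coordinates (see
#'   [generate_seed_points()]).
#' @param date Year stamped on the network.
#' @return A [road_network()] with classes 2 (arterial), 3 (collector),
#'   4 (local).
#' @export
generate_road_network <- function(params, urban_seed_points,
                                  date = 0L) {
  g <- params$grid
  set.seed(params$seed + 103L)
  cs <- g$cell_size
  xmin <- g$origin_x; xmax <- g$origin_x + g$ncols * cs
  ymin <- g$origin_y - g$nrows * cs; ymax <- g$origin_y
  clipx <- function(x) pmin(pmax(x, xmin), xmax - 1e-9)
  clipy <- function(y) pmin(pmax(y, ymin + 1e-9), ymax)
  segs <- list(); cls <- integer()
  pts <- urban_seed_points
  n <- nrow(pts)
  if (n >= 2L) {
    # Prim's MST over seed points
    d <- as.matrix(stats::dist(pts))
    in_tree <- c(TRUE, rep(FALSE, n - 1L))
    while (!all(in_tree)) {
      dd <- d[in_tree, !in_tree, drop = FALSE]
      j <- which(dd == min(dd), arr.ind = TRUE)[1L, ]
      from <- which(in_tree)[j[1L]]
      to <- which(!in_tree)[j[2L]]
      segs[[length(segs) + 1L]] <- pts[c(from, to), , drop = FALSE]
      cls <- c(cls, 2L)
      in_tree[to] <- TRUE
    }
  } else {
    segs[[1L]] <- cbind(c(xmin, xmax - 1e-9), rep(pts[1L, 2L], 2L))
    cls <- 2L
  }
  if (params$road_hierarchy_levels >= 2L) {
    spacing <- 4 * cs; half <- 12 * cs
    for (i in seq_len(n)) {
      sx <- pts[i, 1L]; sy <- pts[i, 2L]
      for (k in -3:3) {
        segs[[length(segs) + 1L]] <-
          cbind(clipx(c(sx + k * spacing, sx + k * spacing)),
                clipy(c(sy - half, sy + half)))
        cls <- c(cls, 3L)
        segs[[length(segs) + 1L]] <-
          cbind(clipx(c(sx - half, sx + half)),
                clipy(c(sy + k * spacing, sy + k * spacing)))
        cls <- c(cls, 3L)
      }
    }
  }
  if (params$road_hierarchy_levels >= 3L) {
    sd_loc <- 10 * cs
    for (i in seq_len(n)) {
      for (b in seq_len(60L)) {
        px <- pts[i, 1L] + stats::rnorm(1, sd = sd_loc)
        py <- pts[i, 2L] + stats::rnorm(1, sd = sd_loc)
        theta <- stats::runif(1, 0, 2 * pi)
        len <- 2.5 * cs
        qx <- px + len * cos(theta); qy <- py + len * sin(theta)
        segs[[length(segs) + 1L]] <- cbind(clipx(c(px, qx)),
                                           clipy(c(py, qy)))
        cls <- c(cls, 4L)
        if (stats::runif(1) < 0.5) {  # perpendicular cul-de-sac spur
          mx <- (px + qx) / 2; my <- (py + qy) / 2
          sl <- 1.5 * cs
          segs[[length(segs) + 1L]] <-
            cbind(clipx(c(mx, mx - sl * sin(theta))),
                  clipy(c(my, my + sl * cos(theta))))
          cls <- c(cls, 4L)
        }
      }
    }
  }
  wt <- c(`2` = 1.5, `3` = 1, `4` = 1)[as.character(cls)]
  road_network(date, segs, cls, as.numeric(wt))
}

#' Generate a densifying series of dated street networks
#'
#' The final-date network is built with [generate_road_network()]; earlier
#' dates contain nested subsets. Arterials exist from the first date;
#' collectors and locals are assigned construction order mostly by distance
#' from the nearest town center (nearer streets are built first), so the
#' network densifies outward over time.
#'
#' @param params A [synth_params()].
#' @param urban_seed_points Center coordinates.
#' @param dates Integer years, strictly increasing, length >= 2.
#' @return List of [road_network()]s, one per date.
#' @export
generate_road_series <- function(params, urban_seed_points, dates) {
  dates <- as.integer(dates)
  stopifnot(length(dates) >= 2L, all(diff(dates) > 0))
  full <- generate_road_network(params, urban_seed_points,
                                date = dates[length(dates)])
  set.seed(params$seed + 104L)
  d0 <- vapply(full$segments, function(s) {
    min(sqrt((s[1L, 1L] - urban_seed_points[, 1L])^2 +
             (s[1L, 2L] - urban_seed_points[, 2L])^2))
  }, numeric(1))
  frac <- 0.7 * d0 / max(d0, 1e-9) + 0.3 * stats::runif(length(d0))
  frac[full$class_code == 2L] <- 0  # arterials predate the series
  lapply(seq_along(dates), function(i) {
    keep <- frac <= i / length(dates)
    road_network(dates[i], full$segments[keep], full$class_code[keep],
                 full$weight[keep])
  })
}

#' Generate a synthetic land-cover mosaic
#'
#' Class areas match the requested weights exactly (to cell rounding).
#' Urban cells sit nearest the town centers, water occupies the low end of
#' a smooth wetness field, wetlands prefer wet *and* flat cells, and the
#' remaining vegetation classes partition a second autocorrelated field, so
#' all classes form spatially coherent patches.
#'
#' @param params A [synth_params()].
#' @param terrain Output of [generate_terrain()].
#' @param urban_seed_points Center coordinates.
#' @return A `landcover_class` [raster_layer()] with the
#'   [landcover_legend()] attached.
#' @export
generate_landcover <- function(params, terrain, urban_seed_points) {
  g <- params$grid
  stop_if_misaligned(terrain$spec, g)
  set.seed(params$seed + 105L)
  leg <- landcover_legend()
  N <- g$nrows * g$ncols
  # largest-remainder quotas
  q <- params$landcover_class_weights * N
  counts <- floor(q)
  rem <- N - sum(counts)
  if (rem > 0) {
    extra <- order(q - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  wet <- smooth_field(matrix(stats::rnorm(N), g$nrows, g$ncols), 8)
  veg <- smooth_field(matrix(stats::rnorm(N), g$nrows, g$ncols), 8)
  cx <- matrix(cell_center_x(g, col(wet)), g$nrows, g$ncols)
  cy <- matrix(cell_center_y(g, row(wet)), g$nrows, g$ncols)
  dseed <- Reduce(pmin, lapply(seq_len(nrow(urban_seed_points)), function(i)
    sqrt((cx - urban_seed_points[i, 1L])^2 +
         (cy - urban_seed_points[i, 2L])^2)))
  out <- matrix(NA_real_, g$nrows, g$ncols)
  free <- rep(TRUE, N)
  take <- function(score, n) {
    idx <- which(free)[order(score[free])][seq_len(n)]
    free[idx] <<- FALSE
    idx
  }
  out[take(dseed, counts[["urban"]])] <- leg[["urban"]]
  zwet <- (wet - mean(wet)) / stats::sd(wet)
  out[take(zwet, counts[["water"]])] <- leg[["water"]]
  slp <- terrain$values
  wscore <- zwet + 0.1 * slp  # wet and flat
  out[take(wscore, counts[["wetland"]])] <- leg[["wetland"]]
  for (cl in c("forest", "agriculture", "grassland"))
    out[take(veg, counts[[cl]])] <- leg[[cl]]
  raster_layer(g, out, kind = "landcover_class", legend = leg)
}

#' Default per-class resistance weights
#' @return Named vector of exclusion weights in \[0, 100\].
#' @export
default_resistances <- function() {
  c(water = 100, wetland = 90, forest = 0, agriculture = 0,
    grassland = 0, urban = 0)
}

#' Build the exclusion/resistance layer from land cover
#'
#' Per-cell table lookup of a resistance weight for each land-cover class:
#' 100 = fully excluded (open water by default), intermediate values =
#' proportional resistance (wetlands default 90).
#'
#' @param landcover A `landcover_class` raster with a named legend.
#' @param resistances Named vector of weights in \[0, 100\], one per legend
#'   class.
#' @return An `exclusion_weight` [raster_layer()].
#' @export
generate_exclusion <- function(landcover, resistances = default_resistances()) {
  stopifnot(inherits(landcover, "raster_layer"),
            landcover$kind == "landcover_class")
  leg <- landcover$legend
  if (is.null(leg) || is.null(names(leg)))
    stop("landcover layer needs a named legend", call. = FALSE)
  missing <- setdiff(names(leg), names(resistances))
  if (length(missing))
    stop("no resistance entry for class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(resistances < 0 | resistances > 100))
    stop("resistances must lie in [0, 100]", call. = FALSE)
  lut <- resistances[names(leg)]
  m <- matrix(lut[match(landcover$values, leg)],
              landcover$spec$nrows, landcover$spec$ncols)
  raster_layer(landcover$spec, m, kind = "exclusion_weight")
}

#' Generate a synthetic historic growth series with known coefficients
#'
#' Runs the cellular automaton forward from the first date, snapshotting
#' the urban extent at each requested date. Self-modification is off by
#' default so the generating coefficients stay constant and parameter
#' recovery has a well-defined truth; the true coefficients are attached as
#' attribute `"true_coeffs"`.
#'
#' @param initial_urban `urban_flag` raster at the first date.
#' @param roads A [road_network()] (rasterized internally) or a
#'   `road_weight` raster.
#' @param slope `slope_percent` raster.
#' @param exclusion `exclusion_weight` raster.
#' @param true_coeffs The generating [coefficient_set()].
#' @param dates Integer years, strictly increasing, length >= 3.
#' @param selfmod A [self_mod_params()] (default disabled).
#' @param base_seed RNG seed for the generating run.
#' @param road_networks Optional dated [road_network()] list stored with
#'   the series.
#' @return A [historic_series()] with attribute `"true_coeffs"`.
#' @export
generate_historic_series <- function(initial_urban, roads, slope, exclusion,
                                     true_coeffs, dates,
                                     selfmod = self_mod_params(enabled = FALSE),
                                     base_seed = 1L,
                                     road_networks = NULL) {
  dates <- as.integer(dates)
  if (length(dates) < 3L) stop("need >= 3 dates", call. = FALSE)
  if (inherits(roads, "road_network"))
    roads <- rasterize_roads(roads, initial_urban$spec)
  state <- ca_state(initial_urban, slope, exclusion, roads, true_coeffs,
                    year = dates[1L])
  set.seed(base_seed)
  run <- run_simulation(state, years = dates[length(dates)] - dates[1L],
                        selfmod = selfmod, snapshot_years = dates[-1L])
  layers <- c(list(initial_urban), unname(run$snapshots))
  out <- historic_series(dates, layers, road_networks = road_networks,
                         quiet = TRUE)
  attr(out, "true_coeffs") <- do.call(coefficient_set, as.list(true_coeffs))
  out
}

#' Geometric reference grower (radial dilation)
#'
#' A deliberately non-CA grower for testing calibration under model
#' mismatch: each year, every cell with at least one urban Moore neighbor
#' urbanizes with probability `p_dilate` (subject to full exclusion).
#'
#' @param initial_urban `urban_flag` raster at the first date.
#' @param exclusion `exclusion_weight` raster (only weight-100 cells
#'   block).
#' @param dates Integer years, length >= 3.
#' @param p_dilate Per-cell annual dilation probability.
#' @param base_seed RNG seed.
#' @return A [historic_series()].
#' @export
generate_radial_series <- function(initial_urban, exclusion, dates,
                                   p_dilate = 0.25, base_seed = 1L) {
  dates <- as.integer(dates)
  if (length(dates) < 3L) stop("need >= 3 dates", call. = FALSE)
  set.seed(base_seed)
  u <- initial_urban$values
  blocked <- exclusion$values >= 100
  layers <- list(initial_urban)
  year <- dates[1L]
  for (i in seq_along(dates)[-1L]) {
    for (y in seq_len(dates[i] - year)) {
      nb <- Reduce(`+`, lapply(list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                                    c(0, 1), c(1, -1), c(1, 0), c(1, 1)),
                               function(o) shift_matrix(u, o[1L], o[2L], 0)))
      cand <- u == 0 & nb >= 1 & !blocked
      grow <- cand & matrix(stats::runif(length(u)) < p_dilate,
                            nrow(u), ncol(u))
      u[grow] <- 1
    }
    year <- dates[i]
    layers[[i]] <- raster_layer(initial_urban$spec, u, kind = "urban_flag")
  }
  historic_series(dates, layers, quiet = TRUE)
}

#' Generate a complete synthetic study area
#'
#' Convenience wrapper tying the generators together: terrain, town-center
#' seed points, street network, land cover, exclusion layer, initial urban
#' extent (the urban land-cover cells) and the rasterized road layer.
#'
#' @param params A [synth_params()].
#' @return List of class `synth_landscape` with elements `params`,
#'   `seed_points`, `slope`, `roads` (network), `road_raster`, `landcover`,
#'   `exclusion`, `initial_urban`.
#' @export
synth_landscape <- function(params = synth_params()) {
  terrain <- generate_terrain(params)
  seeds <- generate_seed_points(params)
  roads <- generate_road_network(params, seeds)
  lc <- generate_landcover(params, terrain, seeds)
  excl <- generate_exclusion(lc)
  urb <- raster_layer(params$grid,
                      (lc$values == landcover_legend()[["urban"]]) * 1,
                      kind = "urban_flag")
  structure(list(params = params, seed_points = seeds, slope = terrain,
                 roads = roads,
                 road_raster = rasterize_roads(roads, params$grid),
                 landcover = lc, exclusion = excl, initial_urban = urb),
            class = "synth_landscape")
}
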