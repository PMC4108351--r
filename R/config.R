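#' Default run configuration
#'
#' Every tunable parameter of the pipeline with its default. Defaults follow
#' the study conditions where stated (60 m cells, 200 Monte Carlo projection
#' runs, 2010-2060 projection horizon, coarse coefficient grid
#' \{0,25,50,75,100\}) and documented plausible values elsewhere (density
#' thresholds, self-modification constants).
#'
#' @return A nested named list of defaults.
#' @export
default_config <- function() {
  list(
    cell_size = 60,
    seed = 1L,
    density = list(
      radius = 300,        # m; 0 = per-cell density only
      t_low = 4,           # km/km2; with NLCD-urban agreement
      t_high = 8,          # km/km2; urban regardless of land cover
      exclude_classes = 1L # limited-access highways: no density signal
    ),
    urban_classes = 6L,    # land-cover codes treated as urban
    ca = list(
      critical_slope = 21, # percent; slopes at/above are never developed
      edge_neighbor_threshold = 3L
    ),
    selfmod = list(
      enabled = TRUE,
      critical_high = 1.3, # % growth/yr above which coefficients boom
      critical_low = 0.97, # % growth/yr below which coefficients bust
      boom = 1.1,
      bust = 0.9
    ),
    calibration = list(
      grid_values = c(0, 25, 50, 75, 100),
      n_mc = 10L,
      refinement_rounds = 2L
    ),
    projection = list(
      monte_carlo_runs = 200L,
      start_year = 2010L,
      end_year = 2060L
    ),
    synth = list(
      nrows = 100L, ncols = 100L,
      n_urban_seeds = 3L,
      road_hierarchy_levels = 3L,
      terrain_roughness = 1,
      landcover_class_weights = c(water = 0.05, wetland = 0.10,
                                  forest = 0.35, agriculture = 0.30,
                                  grassland = 0.15, urban = 0.05)
    )
  )
}

#' Load and resolve a run configuration
#'
#' Reads a YAML configuration file, overlays it on [default_config()],
#' rejects unknown keys (typo protection), validates the result, and echoes
#' the fully resolved configuration so every run is reproducible from its
#' log.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param quiet Suppress the configuration echo.
#' @return The resolved configuration list, classed `sprawl_config`.
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    if (length(user)) cfg <- merge_config(cfg, user, "")
  }
  validate_config(cfg)
  cfg <- structure(cfg, class = "sprawl_config")
  if (!quiet) {
    message("resolved configuration:")
    message(paste0("  ", strsplit(yaml::as.yaml(unclass(cfg)),
                                  "\n")[[1L]], collapse = "\n"))
  }
  cfg
}

merge_config <- function(base, user, prefix) {
  for (k in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    if (!k %in% names(base)) {
      stop("unknown configuration key: '", full, "'", call. = FALSE)
    }
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(user[[k]]))
        stop("configuration key '", full, "' must be a mapping",
             call. = FALSE)
      base[[k]] <- merge_config(base[[k]], user[[k]], full)
    } else {
      v <- user[[k]]
      if (is.list(v)) v <- unlist(v)
      if (!is.null(names(base[[k]])) && !is.null(names(v)))
        v <- v[names(base[[k]])[names(base[[k]]) %in% names(v)]]
      base[[k]] <- v
    }
  }
  base
}

validate_config <- function(cfg) {
  with(cfg, {
    if (cell_size <= 0) stop("cell_size must be positive", call. = FALSE)
    if (density$t_low <= 0 || density$t_low >= density$t_high)
      stop("density thresholds must satisfy 0 < t_low < t_high",
           call. = FALSE)
    if (density$radius < 0) stop("density radius must be >= 0",
                                 call. = FALSE)
    if (ca$critical_slope <= 0) stop("critical_slope must be positive",
                                     call. = FALSE)
    if (selfmod$critical_low >= selfmod$critical_high)
      stop("selfmod critical_low must be below critical_high",
           call. = FALSE)
    if (selfmod$bust >= 1 || selfmod$boom <= 1)
      stop("selfmod requires bust < 1 < boom", call. = FALSE)
    if (calibration$n_mc < 1) stop("calibration n_mc must be >= 1",
                                   call. = FALSE)
    if (projection$monte_carlo_runs < 1)
      stop("monte_carlo_runs must be >= 1", call. = FALSE)
    if (projection$end_year <= projection$start_year)
      stop("projection end_year must follow start_year", call. = FALSE)
    w <- synth$landcover_class_weights
    if (any(w < 0) || abs(sum(w) - 1) > 1e-6)
      stop("landcover_class_weights must be non-negative and sum to 1",
           call. = FALSE)
  })
  invisible(cfg)
}
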