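#' Monte Carlo ensemble projection
#'
#' Runs `n_runs` independent simulations from a common initial state; run
#' `r` is seeded with `base_seed + r`, so the whole ensemble reproduces
#' from `base_seed`. Self-modification stays on by default, which lets
#' individual runs drift toward more or less aggressive growth while all
#' remain consistent with the calibrated coefficients.
#'
#' @param initial A [ca_state()] carrying the calibrated coefficients.
#' @param years Number of projected years (e.g. 50 for 2010-2060).
#' @param n_runs Ensemble size (default 200).
#' @param base_seed Integer base seed.
#' @param selfmod A [self_mod_params()].
#' @param keep_final_masks Keep each run's final urban matrix (needed by
#'   [conversion_fractions()]).
#' @return A list of class `ensemble_result`: `n_runs`, `years`
#'   (calendar years of each annual step), `count_raster` (per-cell number
#'   of runs urban by the final year), `area_series` (`n_runs x years`
#'   matrix of urban area in km^2), `initial_area_km2`, and optionally
#'   `final_masks`.
#' @export
run_ensemble <- function(initial, years, n_runs = 200L, base_seed = 1L,
                         selfmod = self_mod_params(),
                         keep_final_masks = TRUE) {
  stopifnot(inherits(initial, "ca_state"))
  n_runs <- as.integer(n_runs)
  if (n_runs < 1L) stop("n_runs must be >= 1", call. = FALSE)
  years <- as.integer(years)
  if (years < 1L) stop("years must be >= 1", call. = FALSE)
  spec <- initial$urban$spec
  a_cell <- cell_area_km2(spec)
  pop0 <- sum(initial$urban$values)
  counts <- matrix(0L, spec$nrows, spec$ncols)
  area <- matrix(NA_real_, n_runs, years)
  finals <- if (keep_final_masks) vector("list", n_runs) else NULL
  u0 <- urban_int(initial)
  for (r in seq_len(n_runs)) {
    set.seed(base_seed + r)
    res <- ca_run_cpp(u0, initial$slope$values, initial$exclusion$values,
                      initial$roads$values, as.numeric(initial$coeffs),
                      initial$critical_slope,
                      initial$edge_neighbor_threshold, years,
                      integer(0), selfmod$enabled, selfmod$critical_high,
                      selfmod$critical_low, selfmod$boom, selfmod$bust,
                      FALSE, list())
    new_per_year <- rowSums(res$stats[, 2:5, drop = FALSE])
    area[r, ] <- (pop0 + cumsum(new_per_year)) * a_cell
    counts <- counts + res$final_urban
    if (keep_final_masks) finals[[r]] <- res$final_urban
  }
  structure(list(n_runs = n_runs,
                 years = initial$year + seq_len(years),
                 count_raster = raster_layer(spec, counts, kind = "density"),
                 area_series = area,
                 initial_area_km2 = pop0 * a_cell,
                 initial_urban = initial$urban,
                 final_masks = finals),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  env <- envelope(x$area_series[, ncol(x$area_series)])
  cat(sprintf(paste0("<ensemble_result> %d runs, %d-%d; final urban area ",
                     "%.1f km2 (95%% range %.1f-%.1f)\n"),
              x$n_runs, x$years[1L], x$years[length(x$years)],
              env[["median"]], env[["p2.5"]], env[["p97.5"]]))
  invisible(x)
}

#' Per-cell urbanization probability
#'
#' @param ens An [run_ensemble()] result.
#' @return A `probability` [raster_layer()] of `count / n_runs`.
#' @export
urbanization_probability <- function(ens) {
  stopifnot(inherits(ens, "ensemble_result"))
  raster_layer(ens$count_raster$spec, ens$count_raster$values / ens$n_runs,
               kind = "probability")
}

#' Percent change between two areas
#'
#' `100 * (final - initial) / initial`, reported to the nearest integer
#' percent.
#'
#' @param initial_area,final_area Areas in the same units; `initial_area`
#'   must be positive.
#' @return Integer percent change.
#' @export
percent_change <- function(initial_area, final_area) {
  if (any(initial_area <= 0))
    stop("initial_area must be positive", call. = FALSE)
  round(100 * (final_area - initial_area) / initial_area)
}

#' Empirical 95% envelope
#'
#' 2.5th, 50th and 97.5th empirical percentiles of the per-run values,
#' using the standard linear-interpolation convention
#' (`stats::quantile()` type 7).
#'
#' @param values Numeric vector (>= 1 values).
#' @return Named vector `p2.5`, `median`, `p97.5`.
#' @export
envelope <- function(values) {
  if (!length(values)) stop("need at least one value", call. = FALSE)
  q <- stats::quantile(values, c(0.025, 0.5, 0.975), names = FALSE,
                       type = 7)
  c(p2.5 = q[1L], median = q[2L], p97.5 = q[3L])
}

#' Land-cover conversion fractions across the ensemble
#'
#' For every land-cover class, the fraction of its initially non-urban
#' cells that are urbanized by the final year, computed per run and
#' summarized by [envelope()]. A class with no initially non-urban cells
#' is reported as `NA` (undefined), never 0.
#'
#' @param landcover `landcover_class` raster at the start of the
#'   projection.
#' @param ens An [run_ensemble()] result created with
#'   `keep_final_masks = TRUE`.
#' @return A data frame of class `change_summary` with one row per legend
#'   class: initial cell count, and the 95% envelope of the converted
#'   percentage.
#' @export
conversion_fractions <- function(landcover, ens) {
  stopifnot(inherits(ens, "ensemble_result"))
  if (is.null(ens$final_masks))
    stop("ensemble was run with keep_final_masks = FALSE", call. = FALSE)
  stop_if_misaligned(landcover, ens$count_raster)
  leg <- landcover$legend
  if (is.null(leg)) leg <- sort(unique(as.vector(landcover$values)))
  u0 <- ens$initial_urban$values == 1
  rows <- lapply(seq_along(leg), function(i) {
    cls <- leg[[i]]
    init <- landcover$values == cls & !u0
    n0 <- sum(init, na.rm = TRUE)
    if (n0 == 0) {
      env <- c(p2.5 = NA_real_, median = NA_real_, p97.5 = NA_real_)
    } else {
      frac <- vapply(ens$final_masks, function(m)
        100 * sum(m[init] == 1) / n0, numeric(1))
      env <- envelope(frac)
    }
    data.frame(class = if (!is.null(names(leg))) names(leg)[i]
               else as.character(cls),
               class_code = cls, n_initial_cells = n0,
               converted_p2.5 = env[["p2.5"]],
               converted_median = env[["median"]],
               converted_p97.5 = env[["p97.5"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("change_summary", "data.frame")
  out
}

#' Urban-area change summary across the ensemble
#'
#' @param ens An [run_ensemble()] result.
#' @return One-row data frame: initial area, median final area, percent
#'   change of the median, and the 95% range of final areas (km^2).
#' @export
area_change_summary <- function(ens) {
  stopifnot(inherits(ens, "ensemble_result"))
  env <- envelope(ens$area_series[, ncol(ens$area_series)])
  data.frame(initial_area_km2 = ens$initial_area_km2,
             final_median_km2 = env[["median"]],
             percent_change = percent_change(ens$initial_area_km2,
                                             env[["median"]]),
             final_p2.5_km2 = env[["p2.5"]],
             final_p97.5_km2 = env[["p97.5"]])
}
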