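#' Lee-Sallee shape index
#'
#' Intersection-over-union of two urban extents; 1 when both are empty,
#' and 1 iff the urban sets are identical.
#'
#' @param simulated,observed `urban_flag` rasters on one grid (or plain
#'   0/1 matrices).
#' @return Index in \[0, 1\].
#' @export
lee_sallee <- function(simulated, observed) {
  if (inherits(simulated, "raster_layer")) {
    stop_if_misaligned(simulated, observed)
    simulated <- simulated$values
    observed <- observed$values
  }
  a <- simulated == 1; b <- observed == 1
  uni <- sum(a | b, na.rm = TRUE)
  if (uni == 0) return(1)
  sum(a & b, na.rm = TRUE) / uni
}

# squared Pearson correlation; 0 (not NaN) for a zero-variance series so
# degenerate runs rank last
r2_or_zero <- function(sim, obs) {
  if (length(sim) < 2L || stats::sd(sim) == 0 || stats::sd(obs) == 0)
    return(0)
  stats::cor(sim, obs)^2
}

#' Goodness-of-fit metrics for one coefficient set
#'
#' Runs the automaton from the first historic date to the last, `n_mc`
#' times with common random numbers (seed `base_seed + run`), and compares
#' run-averaged per-date statistics with the observations: `compare_pop`
#' is the min/max ratio of final urban counts, `r2_pop` / `r2_edges` /
#' `r2_clusters` are squared correlations of the post-initial per-date
#' urban, edge-cell and patch counts, and `lee_sallee` is the
#' intersection-over-union of simulated and observed urban extents,
#' averaged over runs and over all observed dates (not only the
#' endpoint). `composite` is their product.
#'
#' Run `r` draws from stream `base_seed + r - 1`, so seeding an
#' evaluation with the seed that generated a synthetic history makes run
#' 1 replay that history exactly when the candidate coefficients equal
#' the generating ones (the identical-twin, common-random-forcing
#' protocol used for parameter-recovery experiments).
#'
#' @param coeffs A [coefficient_set()].
#' @param history A [historic_series()].
#' @param layers List with `slope`, `exclusion` and `roads` rasters (as in
#'   [ca_state()]).
#' @param n_mc Monte Carlo runs per evaluation (>= 1).
#' @param base_seed Seed shared across evaluations (common random
#'   numbers).
#' @param selfmod A [self_mod_params()]; disabled by default so a history
#'   generated with fixed coefficients is scored against fixed
#'   coefficients.
#' @param mask Optional logical matrix restricting scoring (and growth,
#'   via exclusion) to a sub-region.
#' @return A list of class `fit_metrics`.
#' @export
evaluate_coefficients <- function(coeffs, history, layers, n_mc = 10L,
                                  base_seed = 1L,
                                  selfmod = self_mod_params(enabled = FALSE),
                                  mask = NULL) {
  prep <- prepare_evaluation(history, layers, n_mc = n_mc,
                             base_seed = base_seed, selfmod = selfmod,
                             mask = mask)
  evaluate_prepared(prep, coeffs)
}

# precompute everything a coefficient evaluation needs (masked initial
# urban layer, masked exclusion, observed per-date statistics) so an
# exhaustive grid search pays the cost once
prepare_evaluation <- function(history, layers, n_mc = 10L, base_seed = 1L,
                               selfmod = self_mod_params(enabled = FALSE),
                               mask = NULL) {
  if (n_mc < 1L) stop("n_mc must be >= 1", call. = FALSE)
  stopifnot(inherits(history, "historic_series"))
  dates <- history$dates
  excl <- layers$exclusion$values
  if (!is.null(mask)) excl[!mask] <- 100
  # validate layer kinds/grids once via ca_state
  state <- ca_state(history$urban_layers[[1L]], layers$slope,
                    raster_layer(layers$exclusion$spec, excl,
                                 kind = "exclusion_weight"),
                    layers$roads, coefficient_set(), year = dates[1L])
  masked <- function(m) {
    if (!is.null(mask)) m[!mask] <- 0
    storage.mode(m) <- "integer"
    m
  }
  obs_layers <- lapply(seq_along(dates)[-1L], function(i)
    masked(history$urban_layers[[i]]$values))
  obs <- vapply(obs_layers, function(m)
    c(sum(m), count_edge_cells_cpp(m), count_components_cpp(m, 1L, 8L)),
    numeric(3))
  u0m <- masked(history$urban_layers[[1L]]$values)
  obs0 <- c(sum(u0m), count_edge_cells_cpp(u0m),
            count_components_cpp(u0m, 1L, 8L))
  list(years = dates[length(dates)] - dates[1L],
       offsets = as.integer(dates[-1L] - dates[1L]),
       u0 = masked(history$urban_layers[[1L]]$values),
       slope = state$slope$values, excl = state$exclusion$values,
       roads = state$roads$values,
       critical_slope = state$critical_slope,
       edge_neighbor_threshold = state$edge_neighbor_threshold,
       obs = obs, obs0 = obs0, obs_layers = obs_layers,
       n_mc = as.integer(n_mc), base_seed = base_seed, selfmod = selfmod)
}

evaluate_prepared <- function(prep, coeffs) {
  coeffs <- do.call(coefficient_set, as.list(coeffs))
  nd <- length(prep$offsets)
  sim <- matrix(0, 3, nd)
  ls_runs <- numeric(prep$n_mc)
  for (r in seq_len(prep$n_mc)) {
    # run r reuses stream base_seed + r - 1, so run 1 of an evaluation
    # seeded with a history's generating seed replays that history exactly
    # (identical-twin protocol; see the calibration vignette section)
    set.seed(prep$base_seed + r - 1L)
    res <- ca_run_cpp(prep$u0, prep$slope, prep$excl, prep$roads,
                      as.numeric(coeffs), prep$critical_slope,
                      prep$edge_neighbor_threshold, prep$years,
                      prep$offsets, prep$selfmod$enabled,
                      prep$selfmod$critical_high, prep$selfmod$critical_low,
                      prep$selfmod$boom, prep$selfmod$bust, FALSE,
                      prep$obs_layers)
    sim <- sim + t(res$snap_stats)
    iou <- ifelse(res$overlaps[, 2L] == 0, 1,
                  res$overlaps[, 1L] / res$overlaps[, 2L])
    ls_runs[r] <- mean(iou)
  }
  sim <- sim / prep$n_mc
  ls <- mean(ls_runs)
  final_obs_pop <- prep$obs[1L, ncol(prep$obs)]
  final_sim_pop <- sim[1L, ncol(sim)]
  compare_pop <- if (final_obs_pop == 0 && final_sim_pop == 0) 1 else
    min(final_sim_pop, final_obs_pop) / max(final_sim_pop, final_obs_pop)
  # series include the (shared) initial date, so correlations are over
  # every date of the series, anchored at the common starting state
  m <- list(compare_pop = compare_pop,
            r2_pop = r2_or_zero(c(prep$obs0[1L], sim[1L, ]),
                                c(prep$obs0[1L], prep$obs[1L, ])),
            r2_edges = r2_or_zero(c(prep$obs0[2L], sim[2L, ]),
                                  c(prep$obs0[2L], prep$obs[2L, ])),
            r2_clusters = r2_or_zero(c(prep$obs0[3L], sim[3L, ]),
                                     c(prep$obs0[3L], prep$obs[3L, ])),
            lee_sallee = ls)
  m$composite <- m$compare_pop * m$r2_pop * m$r2_edges * m$r2_clusters *
    m$lee_sallee
  structure(m, class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf(paste0("<fit_metrics> composite %.4f (compare_pop %.3f, ",
                     "r2_pop %.3f, r2_edges %.3f, r2_clusters %.3f, ",
                     "lee_sallee %.3f)\n"),
              x$composite, x$compare_pop, x$r2_pop, x$r2_edges,
              x$r2_clusters, x$lee_sallee))
  invisible(x)
}

metrics_row <- function(coeffs, m, n_mc) {
  data.frame(dispersion = coeffs[[1L]], breed = coeffs[[2L]],
             spread = coeffs[[3L]], slope_resistance = coeffs[[4L]],
             road_gravity = coeffs[[5L]], compare_pop = m$compare_pop,
             r2_pop = m$r2_pop, r2_edges = m$r2_edges,
             r2_clusters = m$r2_clusters, lee_sallee = m$lee_sallee,
             composite = m$composite, n_mc = n_mc)
}

rank_table <- function(tab) {
  ord <- order(-tab$composite, tab$dispersion, tab$breed, tab$spread,
               tab$slope_resistance, tab$road_gravity)
  tab[ord, , drop = FALSE]
}

#' Calibrate coefficients for one sub-region
#'
#' Exhaustively scores every coefficient combination on the coarse grid
#' (default \{0, 25, 50, 75, 100\} on each of the five axes), then
#' optionally refines: each round re-grids around the incumbent best at
#' half the previous step. Ties in the composite score break toward the
#' lexicographically smaller coefficient vector, so results are
#' deterministic and independent of evaluation order.
#'
#' @param history A [historic_series()] (optionally pre-masked).
#' @param layers List with `slope`, `exclusion`, `roads` rasters.
#' @param grid_values Coarse-grid values for every coefficient axis.
#' @param n_mc Monte Carlo runs per coefficient set.
#' @param refinement_rounds Number of halved-step refinement rounds
#'   (>= 0).
#' @param base_seed Seed (common random numbers across combinations).
#' @param selfmod A [self_mod_params()].
#' @param mask Optional sub-region mask.
#' @param id Sub-region identifier for the result.
#' @param progress Print a line per search round.
#' @return A list of class `calibration_result` with the ranked `table`,
#'   `best` [coefficient_set()] and `refinement history`.
#' @export
calibrate_subregion <- function(history, layers,
                                grid_values = c(0, 25, 50, 75, 100),
                                n_mc = 10L, refinement_rounds = 0L,
                                base_seed = 1L,
                                selfmod = self_mod_params(enabled = FALSE),
                                mask = NULL, id = "region",
                                progress = FALSE) {
  if (!length(grid_values)) stop("empty coefficient grid", call. = FALSE)
  if (refinement_rounds < 0L) stop("refinement_rounds must be >= 0",
                                   call. = FALSE)
  prep <- prepare_evaluation(history, layers, n_mc = n_mc,
                             base_seed = base_seed, selfmod = selfmod,
                             mask = mask)
  score_grid <- function(values_per_axis) {
    combos <- expand.grid(dispersion = values_per_axis[[1L]],
                          breed = values_per_axis[[2L]],
                          spread = values_per_axis[[3L]],
                          slope_resistance = values_per_axis[[4L]],
                          road_gravity = values_per_axis[[5L]])
    do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      cf <- do.call(coefficient_set, as.list(combos[i, ]))
      m <- evaluate_prepared(prep, cf)
      metrics_row(cf, m, n_mc)
    }))
  }
  axes <- rep(list(sort(unique(grid_values))), 5L)
  tab <- rank_table(score_grid(axes))
  hist_rounds <- list(list(round = 0L, step = if (length(grid_values) > 1L)
    min(diff(sort(unique(grid_values)))) else 0,
    best = as.numeric(tab[1L, 1:5])))
  step <- hist_rounds[[1L]]$step
  if (progress) message("coarse grid: best composite ",
                        signif(tab$composite[1L], 4))
  r <- 1L
  while (r <= refinement_rounds && step > 1) {
    step <- step / 2
    best <- as.numeric(tab[1L, 1:5])
    axes <- lapply(best, function(b)
      sort(unique(pmin(100, pmax(0, round(b + c(-step, 0, step)))))))
    tab <- rank_table(rbind(tab, score_grid(axes)))
    tab <- tab[!duplicated(tab[, 1:5]), , drop = FALSE]
    hist_rounds[[r + 1L]] <- list(round = r, step = step,
                                  best = as.numeric(tab[1L, 1:5]))
    if (progress) message("refinement ", r, ": best composite ",
                          signif(tab$composite[1L], 4))
    r <- r + 1L
  }
  rownames(tab) <- NULL
  structure(list(id = id, table = tab,
                 best = do.call(coefficient_set,
                                as.list(as.numeric(tab[1L, 1:5]))),
                 refinement = hist_rounds),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>", x$id, "-",
      nrow(x$table), "coefficient sets scored\n")
  cat("  best:")
  print(x$best)
  invisible(x)
}

#' Calibrate every sub-region independently
#'
#' Each sub-region is calibrated with cells outside its mask frozen
#' (exclusion weight forced to 100) and fit statistics computed inside the
#' mask only. Masks must be pairwise disjoint and non-empty.
#'
#' @param subregions List of [sub_region()]s.
#' @param history Shared [historic_series()].
#' @param layers List with `slope`, `exclusion`, `roads` rasters.
#' @param ... Passed to [calibrate_subregion()].
#' @return Named list of `calibration_result`s.
#' @export
calibrate_all <- function(subregions, history, layers, ...) {
  check_disjoint(subregions)
  out <- lapply(subregions, function(sr)
    calibrate_subregion(history, layers, mask = sr$mask, id = sr$id, ...))
  names(out) <- vapply(subregions, `[[`, character(1), "id")
  out
}
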