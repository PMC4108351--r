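# shared fixtures: small states and landscapes built in code

flat_state <- function(nr = 20, nc = 20, coeffs = coefficient_set(),
                       urban = matrix(0, nr, nc),
                       exclusion = matrix(0, nr, nc),
                       slope = matrix(0, nr, nc),
                       roads = matrix(0, nr, nc), cell_size = 60) {
  spec <- grid_spec(nr, nc, cell_size = cell_size)
  ca_state(raster_layer(spec, urban, "urban_flag"),
           raster_layer(spec, slope, "slope_percent"),
           raster_layer(spec, exclusion, "exclusion_weight"),
           raster_layer(spec, roads, "road_weight"),
           coeffs)
}

# R flood-fill reference for connected components (independent of the
# compiled labelling)
flood_fill_labels <- function(m, target, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  k <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (lab[r0, c0] != 0L || is.na(m[r0, c0]) || m[r0, c0] != target) next
    k <- k + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- k
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      for (j in seq_len(nrow(nbrs))) {
        r <- cur[1L] + nbrs[j, 1L]; c <- cur[2L] + nbrs[j, 2L]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && lab[r, c] == 0L &&
            !is.na(m[r, c]) && m[r, c] == target) {
          lab[r, c] <- k
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# count of urban Moore neighbors per cell, pure R
moore_neighbor_counts <- function(u) {
  nr <- nrow(u); nc <- ncol(u)
  out <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    out[rs, cs] <- out[rs, cs] + u[rs + dr, cs + dc]
  }
  out
}

# small synthetic landscape + CA-generated history for calibration and
# projection tests
small_study <- function(seed = 1, nr = 50, nc = 50,
                        truth = coefficient_set(25, 50, 75, 0, 25),
                        dates = c(2000, 2003, 2006, 2009)) {
  p <- synth_params(grid = grid_spec(nr, nc, 60), seed = seed)
  L <- synth_landscape(p)
  B <- seed * 1000L
  h <- generate_historic_series(L$initial_urban, L$roads, L$slope,
                                L$exclusion, truth, dates = dates,
                                base_seed = B)
  list(landscape = L, history = h, truth = truth, base_seed = B,
       layers = list(slope = L$slope, exclusion = L$exclusion,
                     roads = L$road_raster))
}
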