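test_that("lee_sallee is an intersection-over-union with sane limits", {
  spec <- grid_spec(4, 4, 60)
  a <- raster_layer(spec, 0, "urban_flag")
  b <- raster_layer(spec, 0, "urban_flag")
  expect_equal(lee_sallee(a, b), 1)            # both empty
  a$values[1:2, 1] <- 1
  b$values[3:4, 4] <- 1
  expect_equal(lee_sallee(a, b), 0)            # disjoint
  expect_equal(lee_sallee(a, a), 1)            # identical
  # |A & B| = 2, |A | B| = 8 by construction
  a$values[] <- 0; b$values[] <- 0
  a$values[1:4] <- 1; b$values[3:8] <- 1
  expect_equal(lee_sallee(a, b), 2 / 8)
  expect_equal(lee_sallee(a, b), lee_sallee(b, a))
})

test_that("an exact replay of the generating run scores lee_sallee 1", {
  st <- small_study(seed = 23, nr = 40, nc = 40)
  m <- evaluate_coefficients(st$truth, st$history, st$layers, n_mc = 1,
                             base_seed = st$base_seed)
  expect_equal(m$lee_sallee, 1)
  expect_equal(m$compare_pop, 1)
  expect_equal(m$composite, m$compare_pop * m$r2_pop * m$r2_edges *
                 m$r2_clusters * m$lee_sallee)
})

test_that("degenerate simulated series score zero correlation, not NaN", {
  st <- small_study(seed = 23, nr = 40, nc = 40)
  m <- evaluate_coefficients(coefficient_set(), st$history, st$layers,
                             n_mc = 2, base_seed = 5)
  expect_equal(m$r2_pop, 0)
  expect_equal(m$r2_clusters, 0)
  expect_equal(m$composite, 0)
  expect_false(anyNA(unlist(m)))
})

test_that("fit metrics on a hand-built history match direct formulas", {
  # all-zero coefficients are deterministic: the simulation stays at the
  # initial extent, so every metric reduces to closed-form arithmetic
  spec <- grid_spec(6, 6, 60)
  u0 <- matrix(0, 6, 6); u0[3:4, 3:4] <- 1             # 4 cells
  u1 <- u0; u1[2, 3:4] <- 1                            # 6 cells
  u2 <- u1; u2[5, 3:4] <- 1                            # 8 cells
  h <- historic_series(c(2000, 2001, 2002),
                       list(raster_layer(spec, u0, "urban_flag"),
                            raster_layer(spec, u1, "urban_flag"),
                            raster_layer(spec, u2, "urban_flag")))
  layers <- list(slope = raster_layer(spec, 0, "slope_percent"),
                 exclusion = raster_layer(spec, 0, "exclusion_weight"),
                 roads = NULL)
  m <- evaluate_coefficients(coefficient_set(), h, layers, n_mc = 3,
                             base_seed = 1)
  expect_equal(m$compare_pop, 4 / 8)
  # IoU of the static 4-cell block with u1 (6 cells) and u2 (8 cells)
  expect_equal(m$lee_sallee, mean(c(4 / 6, 4 / 8)))
  expect_equal(m$r2_pop, 0)   # constant simulated series
  expect_equal(m$composite, 0)
})

test_that("single-point grids and deterministic ranking behave", {
  st <- small_study(seed = 29, nr = 30, nc = 30)
  cal <- calibrate_subregion(st$history, st$layers, grid_values = 50,
                             n_mc = 2, base_seed = st$base_seed)
  expect_equal(nrow(cal$table), 1L)
  expect_equal(as.numeric(cal$best), rep(50, 5))

  cal2 <- calibrate_subregion(st$history, st$layers,
                              grid_values = c(0, 50, 100), n_mc = 2,
                              base_seed = st$base_seed)
  cal3 <- calibrate_subregion(st$history, st$layers,
                              grid_values = c(0, 50, 100), n_mc = 2,
                              base_seed = st$base_seed)
  expect_identical(cal2$table, cal3$table)
  expect_true(all(diff(cal2$table$composite) <= 0))
})

test_that("composite ties break toward the lexicographically smaller vector", {
  # a history with no growth gives every coefficient set composite 0
  spec <- grid_spec(10, 10, 60)
  u <- matrix(0, 10, 10); u[5, 5] <- 1
  flat <- raster_layer(spec, u, "urban_flag")
  h <- historic_series(c(2000, 2001, 2002), list(flat, flat, flat))
  layers <- list(slope = raster_layer(spec, 0, "slope_percent"),
                 exclusion = raster_layer(spec, matrix(
                   ifelse(u == 1, 0, 100), 10, 10), "exclusion_weight"),
                 roads = NULL)
  cal <- calibrate_subregion(h, layers, grid_values = c(0, 50), n_mc = 1,
                             base_seed = 1)
  expect_equal(max(cal$table$composite), 0)
  expect_equal(as.numeric(cal$best), rep(0, 5))
})

test_that("coarse-grid calibration recovers the generating coefficients", {
  st <- small_study(seed = 37, nr = 60, nc = 60)
  cal <- calibrate_subregion(st$history, st$layers, n_mc = 5,
                             base_seed = st$base_seed)
  expect_true(max(abs(as.numeric(cal$best) - as.numeric(st$truth))) <= 25)
})

test_that("refinement halves the step around the incumbent", {
  st <- small_study(seed = 41, nr = 30, nc = 30,
                    truth = coefficient_set(20, 40, 60, 0, 20))
  cal <- calibrate_subregion(st$history, st$layers,
                             grid_values = c(0, 50, 100), n_mc = 2,
                             refinement_rounds = 2,
                             base_seed = st$base_seed)
  expect_length(cal$refinement, 3L)
  expect_equal(cal$refinement[[2L]]$step, 25)
  expect_equal(cal$refinement[[3L]]$step, 12.5)
  expect_gte(cal$table$composite[1L],
             max(calibrate_subregion(st$history, st$layers,
                                     grid_values = c(0, 50, 100),
                                     n_mc = 2, base_seed =
                                       st$base_seed)$table$composite))
})

test_that("sub-regions calibrate independently with frozen surroundings", {
  p <- synth_params(grid = grid_spec(50, 50, 60), seed = 43,
                    n_urban_seeds = 2)
  L <- synth_landscape(p)
  left <- matrix(FALSE, 50, 50); left[, 1:25] <- TRUE
  expect_error(sub_region("empty", matrix(FALSE, 50, 50), p$grid),
               "empty")
  expect_error(check_disjoint(list(sub_region("a", left, p$grid),
                                   sub_region("b", left, p$grid))),
               "overlap")

  right <- !left
  regions <- list(sub_region("west", left, p$grid),
                  sub_region("east", right, p$grid))
  truth <- coefficient_set(25, 50, 75, 0, 25)
  h <- generate_historic_series(L$initial_urban, L$roads, L$slope,
                                L$exclusion, truth,
                                dates = c(2000, 2003, 2006, 2009),
                                base_seed = 7000)
  layers <- list(slope = L$slope, exclusion = L$exclusion,
                 roads = L$road_raster)
  # one all-covering sub-region reproduces plain calibration
  whole <- list(sub_region("all", left | right, p$grid))
  ca <- calibrate_all(whole, h, layers, grid_values = c(25, 75),
                      n_mc = 2, base_seed = 7000)
  cb <- calibrate_subregion(h, layers, grid_values = c(25, 75), n_mc = 2,
                            base_seed = 7000)
  expect_equal(ca$all$table$composite, cb$table$composite)
  expect_named(ca, "all")
})
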