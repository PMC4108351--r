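test_that("coefficients and self-modification parameters are validated", {
  expect_error(coefficient_set(dispersion = 101), "\\[0, 100\\]")
  expect_error(coefficient_set(breed = -1), "\\[0, 100\\]")
  expect_error(self_mod_params(critical_high = 0.5, critical_low = 0.9),
               "below")
  expect_error(self_mod_params(boom = 0.9), "bust < 1 < boom")
})

test_that("attempt_urbanize refuses urban and fully excluded cells", {
  u <- matrix(0, 5, 5); u[3, 3] <- 1
  e <- matrix(0, 5, 5); e[2, 2] <- 100
  st <- flat_state(5, 5, urban = u, exclusion = e)
  for (i in 1:25) {
    expect_false(attempt_urbanize(st, c(3, 3))$accepted)
    expect_false(attempt_urbanize(st, c(2, 2))$accepted)
  }
  res <- attempt_urbanize(st, c(1, 1))
  expect_true(res$accepted)
  expect_equal(res$state$urban$values[1, 1], 1)
  expect_error(attempt_urbanize(st, c(0, 1)), "bounds")
})

test_that("partial exclusion rejects at the stated rate", {
  e <- matrix(50, 5, 5)
  st <- flat_state(5, 5, exclusion = e)
  set.seed(99)
  acc <- mean(vapply(1:10000, function(i)
    attempt_urbanize(st, c(3, 3))$accepted, logical(1)))
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("slope acceptance follows the power-law lookup", {
  expect_error(slope_accept(5, 50, critical_slope = 0), "positive")
  set.seed(7)
  for (i in 1:20) {
    expect_true(slope_accept(0, runif(1, 0, 100)))   # flat always accepts
    expect_false(slope_accept(21, runif(1, 0, 100), 21))  # boundary rejects
    expect_false(slope_accept(30, 0, 21))
    expect_true(slope_accept(20.9, 0, 21))           # zero resistance accepts
  }
  # at half the critical slope, rejection = (1/2)^(resistance/25)
  set.seed(21)
  rej <- mean(!vapply(1:10000, function(i) slope_accept(10.5, 50, 21),
                      logical(1)))
  expect_lt(abs(rej - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
})

test_that("the dispersion value follows the diagonal formula", {
  expect_equal(dispersion_value(50, 100, 100), 35L)  # 35.36 rounds to 35
  expect_equal(dispersion_value(0, 100, 100), 0L)
  expect_equal(dispersion_value(100, 50, 50), 35L)   # 35.36 again
})

test_that("spontaneous growth draws the right number of attempts", {
  st <- flat_state(100, 100, coeffs = coefficient_set(dispersion = 0))
  set.seed(1)
  expect_equal(nrow(spontaneous_growth(st)$cells), 0L)

  st50 <- flat_state(100, 100, coeffs = coefficient_set(dispersion = 50))
  set.seed(1)
  res <- spontaneous_growth(st50)
  # flat unexcluded empty grid: every distinct attempt succeeds
  expect_lte(nrow(res$cells), 35L)
  expect_gte(nrow(res$cells), 30L)  # a few collisions possible
  expect_equal(sum(res$state$urban$values), nrow(res$cells))

  blocked <- flat_state(20, 20, coeffs = coefficient_set(dispersion = 100),
                        exclusion = matrix(100, 20, 20))
  set.seed(2)
  expect_equal(nrow(spontaneous_growth(blocked)$cells), 0L)
})

test_that("spreading centers breed two-neighbor nuclei at rate breed/100", {
  st <- flat_state(20, 20, coeffs = coefficient_set(breed = 0))
  set.seed(3)
  expect_equal(nrow(new_spreading_centers(st, cbind(10, 10))$cells), 0L)

  st100 <- flat_state(20, 20, coeffs = coefficient_set(breed = 100))
  for (i in 1:20) {
    res <- new_spreading_centers(st100, cbind(10, 10))
    expect_equal(nrow(res$cells), 2L)  # two distinct neighbors, both free
    expect_true(all(abs(res$cells[, 1] - 10) <= 1))
    expect_true(all(abs(res$cells[, 2] - 10) <= 1))
  }

  # expected new cells ~ 2 * (breed/100) * n_centers on an open landscape
  st40 <- flat_state(50, 50, coeffs = coefficient_set(breed = 40))
  centers <- as.matrix(expand.grid(row = seq(5, 45, 4), col = seq(5, 45, 4)))
  set.seed(11)
  totals <- vapply(1:200, function(i)
    nrow(new_spreading_centers(st40, centers)$cells), numeric(1))
  n <- nrow(centers)
  se <- sqrt(4 * 0.4 * 0.6 * n / 200)
  expect_lt(abs(mean(totals) - 2 * 0.4 * n), 3 * se)
})

test_that("edge growth matches the neighborhood-count oracle", {
  st <- flat_state(7, 7, coeffs = coefficient_set(spread = 0))
  st$urban$values[3:5, 3:5] <- 1
  set.seed(5)
  expect_equal(nrow(edge_growth(st)$cells), 0L)

  # spread = 100, flat, no exclusion: exactly the cells with >= 3 urban
  # Moore neighbors urbanize
  u <- matrix(0, 7, 7); u[3:5, 3:5] <- 1; u[1, 1] <- 1
  st100 <- flat_state(7, 7, coeffs = coefficient_set(spread = 100),
                      urban = u)
  set.seed(6)
  res <- edge_growth(st100)
  expected <- moore_neighbor_counts(u) >= 3 & u == 0
  got <- matrix(FALSE, 7, 7); got[res$cells] <- TRUE
  expect_identical(got, expected)

  # a single isolated urban cell never triggers edge growth
  lone <- flat_state(9, 9, coeffs = coefficient_set(spread = 100))
  lone$urban$values[5, 5] <- 1
  for (i in 1:10) expect_equal(nrow(edge_growth(lone)$cells), 0L)
})

test_that("road-influenced growth needs gravity, roads, and stays near them", {
  roads <- matrix(0, 30, 30); roads[15, ] <- 1
  new_cells <- cbind(12:14, 10)
  st0 <- flat_state(30, 30, coeffs = coefficient_set(dispersion = 50,
                                                     breed = 100,
                                                     road_gravity = 0),
                    roads = roads)
  set.seed(7)
  expect_equal(nrow(road_influenced_growth(st0, new_cells)$cells), 0L)

  noroads <- flat_state(30, 30, coeffs = coefficient_set(dispersion = 50,
                                                         breed = 100,
                                                         road_gravity = 100))
  expect_equal(nrow(road_influenced_growth(noroads, new_cells)$cells), 0L)

  stg <- flat_state(30, 30, coeffs = coefficient_set(dispersion = 50,
                                                     breed = 100,
                                                     road_gravity = 100),
                    roads = roads)
  set.seed(8)
  for (i in 1:100) {
    cells <- road_influenced_growth(stg, new_cells)$cells
    if (nrow(cells)) expect_true(all(abs(cells[, 1] - 15) <= 2))
  }
})

test_that("a growth step conserves counts and is a fixed point at zero", {
  st <- flat_state(20, 20)
  st$urban$values[10, 10] <- 1
  set.seed(9)
  res <- growth_step(st)
  expect_identical(res$state$urban$values, st$urban$values)
  expect_equal(res$stats$total_new, 0)

  # conservation audit on 100 random states
  for (i in 1:100) {
    set.seed(i)
    u <- matrix(rbinom(2500, 1, 0.2), 50, 50)
    e <- matrix(sample(c(0, 0, 0, 50, 100), 2500, TRUE), 50, 50)
    s <- matrix(runif(2500, 0, 30), 50, 50)
    r <- matrix(rbinom(2500, 1, 0.05), 50, 50)
    cf <- coefficient_set(sample(0:100, 1), sample(0:100, 1),
                          sample(0:100, 1), sample(0:100, 1),
                          sample(0:100, 1))
    st <- flat_state(50, 50, coeffs = cf, urban = u, exclusion = e,
                     slope = s, roads = r)
    res <- growth_step(st)
    delta <- sum(res$state$urban$values) - sum(u)
    expect_equal(res$stats$total_new, delta)
    expect_equal(res$stats$new_cells_spontaneous +
                 res$stats$new_cells_spreading_center +
                 res$stats$new_cells_edge + res$stats$new_cells_road,
                 delta)
    expect_true(all(res$state$urban$values >= u))
  }
})

test_that("growth steps are deterministic given the seed", {
  st <- flat_state(30, 30, coeffs = coefficient_set(50, 50, 50, 25, 25))
  st$urban$values[14:16, 14:16] <- 1
  set.seed(123); a <- growth_step(st)
  set.seed(123); b <- growth_step(st)
  expect_identical(a$state$urban$values, b$state$urban$values)
  expect_identical(a$stats, b$stats)
})

test_that("self-modification booms, busts, clamps and floors", {
  cf <- coefficient_set(50, 50, 50, 50, 50)
  p <- self_mod_params()
  expect_identical(self_modify(cf, 10, self_mod_params(enabled = FALSE)),
                   cf)
  boomed <- self_modify(cf, 2, p)   # above critical_high = 1.3
  expect_equal(as.numeric(boomed), c(55, 55, 55, 50, 50))
  busted <- self_modify(cf, 0.5, p) # below critical_low = 0.97
  expect_equal(as.numeric(busted), c(45, 45, 45, 50, 50))
  mid <- self_modify(cf, 1.1, p)    # between thresholds: unchanged
  expect_identical(mid, cf)
  top <- self_modify(coefficient_set(100, 100, 100, 0, 0), 2, p)
  expect_equal(as.numeric(top)[1:3], c(100, 100, 100))
  tiny <- self_modify(coefficient_set(1, 1, 1, 0, 0), 0.1,
                      self_mod_params(bust = 0.2))
  expect_equal(as.numeric(tiny)[1:3], c(1, 1, 1))  # floor once positive
})

test_that("a long run matches a step-by-step reference loop exactly", {
  L <- synth_landscape(synth_params(grid = grid_spec(100, 100, 60),
                                    seed = 17))
  st <- ca_state(L$initial_urban, L$slope, L$exclusion, L$road_raster,
                 coefficient_set(25, 50, 60, 25, 25), year = 2010)
  sm <- self_mod_params()
  set.seed(31)
  run <- run_simulation(st, 51, selfmod = sm)
  # reference loop: one growth step then self-modification per year
  set.seed(31)
  ref <- st
  for (y in 1:51) {
    stp <- growth_step(ref)
    ref <- stp$state
    ref$coeffs <- self_modify(ref$coeffs, stp$stats$growth_rate, sm)
  }
  expect_identical(run$final$urban$values, ref$urban$values)
  expect_equal(run$final$coeffs, ref$coeffs)
  expect_true(all(diff(c(0, cumsum(run$stats$total_new))) >= 0))
})

test_that("run_simulation validates years and keeps urban area monotone", {
  st <- flat_state(20, 20, coeffs = coefficient_set(50, 50, 50, 0, 0))
  st$urban$values[10, 10] <- 1
  expect_error(run_simulation(st, 0), "positive")
  set.seed(12)
  run <- run_simulation(st, 10, snapshot_years = c(3, 7, 10))
  areas <- vapply(run$snapshots, function(l) sum(l$values), numeric(1))
  expect_true(all(diff(areas) >= 0))
  expect_named(run$snapshots, c("3", "7", "10"))
})

test_that("mean phase output responds monotonically to its coefficient", {
  u <- matrix(0, 25, 25); u[11:14, 11:14] <- 1
  mean_edge <- function(spread) {
    st <- flat_state(25, 25, coeffs = coefficient_set(spread = spread),
                     urban = u)
    mean(vapply(1:100, function(i) nrow(edge_growth(st)$cells), numeric(1)))
  }
  set.seed(44)
  e <- vapply(c(10, 40, 70, 100), mean_edge, numeric(1))
  expect_true(all(diff(e) > 0))

  mean_spont <- function(disp) {
    st <- flat_state(25, 25, coeffs = coefficient_set(dispersion = disp))
    mean(vapply(1:100, function(i) nrow(spontaneous_growth(st)$cells),
                numeric(1)))
  }
  set.seed(45)
  s <- vapply(c(0, 30, 60, 90), mean_spont, numeric(1))
  expect_true(all(diff(s) > 0))
})
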