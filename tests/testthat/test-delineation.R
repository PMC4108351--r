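test_that("line density conserves network length at radius 0", {
  spec <- grid_spec(40, 40, cell_size = 60)
  set.seed(8)
  segs <- lapply(1:20, function(i) {
    cbind(runif(2, 100, 2300), runif(2, 100, 2300))
  })
  net <- road_network(2000, segs)
  d <- compute_line_density(net, spec, radius = 0)
  total_km <- sum(d$values) * cell_area_km2(spec)
  expect_equal(total_km, total_length_m(net) / 1000, tolerance = 1e-6)
})

test_that("a 100 m segment spanning exactly one 100 m cell gives 10 km/km2", {
  spec <- grid_spec(3, 3, cell_size = 100, origin_x = 0, origin_y = 300)
  net <- road_network(2000, list(cbind(c(100, 200), c(150, 150))))
  d <- compute_line_density(net, spec, radius = 0)
  expect_equal(d$values[2, 2], 10)
  expect_equal(sum(d$values != 0), 1L)
})

test_that("empty networks give all-zero density", {
  spec <- grid_spec(5, 5, cell_size = 60)
  expect_true(all(compute_line_density(road_network(2000), spec,
                                       radius = 0)$values == 0))
})

test_that("windowed density of a straight line matches numeric integration", {
  # fine grid so the discrete disc approximates the 300 m circular window
  cs <- 10; n <- 121
  spec <- grid_spec(n, n, cell_size = cs, origin_x = 0, origin_y = n * cs)
  yline <- 545                     # 5.5 cells above the center row line
  net <- road_network(2000, list(cbind(c(-5000, 5000 + n * cs),
                                       c(yline, yline))))
  d <- compute_line_density(net, spec, radius = 300)
  # oracle: integrate the line numerically over the same discrete disc
  k <- floor(300 / cs)
  offs <- expand.grid(dr = -k:k, dc = -k:k)
  offs <- offs[(offs$dr * cs)^2 + (offs$dc * cs)^2 <= 300^2, ]
  for (cell in list(c(61, 61), c(50, 40))) {
    cxy <- c((cell[2] - 0.5) * cs, (n - cell[1] + 0.5) * cs)
    xs <- seq(cxy[1] - 400, cxy[1] + 400, by = 0.05)
    inside <- vapply(seq_len(nrow(offs)), function(i) {
      rc <- c(cell[1] + offs$dr[i], cell[2] + offs$dc[i])
      xlo <- (rc[2] - 1) * cs; xhi <- rc[2] * cs
      ylo <- (n - rc[1]) * cs; yhi <- (n - rc[1] + 1) * cs
      if (yline < ylo || yline >= yhi) return(0)
      sum(xs >= xlo & xs < xhi) * 0.05
    }, numeric(1))
    oracle <- sum(inside) / (nrow(offs) * cs^2) * 1000
    expect_equal(d$values[cell[1], cell[2]], oracle, tolerance = 0.01)
  }
})

test_that("the urban classifier follows its two-threshold rule exactly", {
  # exhaustive truth table over density strata x land-cover urbanness
  spec <- grid_spec(2, 3, cell_size = 60)
  params <- density_params(t_low = 4, t_high = 8)
  dens <- raster_layer(spec, matrix(c(2, 2, 6, 6, 9, 9), 2, 3),
                       "density")
  lc <- raster_layer(spec, matrix(c(6, 3, 6, 3, 6, 3), 2, 3),
                     "landcover_class", legend = landcover_legend())
  urb <- classify_urban_extent(dens, lc, urban_classes = 6L, params)
  expect_equal(urb$values, matrix(c(0, 0, 1, 0, 1, 1), 2, 3))
})

test_that("zero density is never urban; t_high rescues unmapped suburbs", {
  spec <- grid_spec(4, 4, cell_size = 60)
  lc <- raster_layer(spec, 6, "landcover_class",
                     legend = landcover_legend())
  zero <- raster_layer(spec, 0, "density")
  expect_equal(sum(classify_urban_extent(zero, lc, 6L)$values), 0)
  high <- raster_layer(spec, 9, "density")
  rural_lc <- raster_layer(spec, 3, "landcover_class",
                           legend = landcover_legend())
  expect_equal(sum(classify_urban_extent(high, rural_lc, 6L)$values), 16)
})

test_that("classification is monotone in density and in thresholds", {
  expect_error(density_params(t_low = 8, t_high = 8), "t_low < t_high")
  spec <- grid_spec(10, 10, cell_size = 60)
  leg <- landcover_legend()
  for (i in 1:50) {
    set.seed(i)
    dens <- raster_layer(spec, matrix(runif(100, 0, 12), 10, 10),
                         "density")
    lc <- raster_layer(spec, matrix(sample(leg, 100, TRUE), 10, 10),
                       "landcover_class", legend = leg)
    u1 <- classify_urban_extent(dens, lc, 6L,
                                density_params(t_low = 4, t_high = 8))
    # lowering t_low never shrinks the urban set
    u2 <- classify_urban_extent(dens, lc, 6L,
                                density_params(t_low = 2, t_high = 8))
    expect_true(all(u2$values >= u1$values))
    # raising one cell's density never de-urbanizes it
    dens2 <- dens
    dens2$values[5, 5] <- dens2$values[5, 5] + 5
    u3 <- classify_urban_extent(dens2, lc, 6L,
                                density_params(t_low = 4, t_high = 8))
    expect_true(all(u3$values >= u1$values))
  }
})

test_that("historic delineation is monotone and logs de-densification flips", {
  spec <- grid_spec(3, 3, cell_size = 100, origin_x = 0, origin_y = 300)
  lc <- raster_layer(spec, 3, "landcover_class", legend = landcover_legend())
  seg <- cbind(c(100, 200), c(150, 150))
  full <- road_network(2000, list(seg, seg, seg, seg))  # 40 km/km2 in cell
  decayed <- road_network(2006, list(seg))              # 10 km/km2: below t_high? no, above
  p <- density_params(t_low = 4, t_high = 8, radius = 0)

  expect_error(build_historic_series(list(full, decayed), lc, 6L, p),
               ">= 3 dates")

  same <- lapply(c(2000, 2006, 2009), function(y)
    road_network(y, list(seg, seg, seg, seg)))
  hs <- build_historic_series(same, lc, 6L, p, quiet = TRUE)
  expect_equal(hs$flips, 0L)
  expect_identical(hs$urban_layers[[1L]]$values,
                   hs$urban_layers[[3L]]$values)

  # a cell urban at date 1 but sub-threshold later stays urban, flip logged
  gone <- road_network(2006, list(cbind(c(100, 140), c(150, 150))))  # 4 km/km2 < t_high, rural lc
  still_gone <- road_network(2009, list(cbind(c(100, 120), c(150, 150))))
  expect_message(
    hs2 <- build_historic_series(list(full, gone, still_gone), lc, 6L,
                                 density_params(t_low = 4, t_high = 8,
                                                radius = 0)),
    "flipped")
  expect_equal(hs2$flips, 2L)
  expect_equal(hs2$urban_layers[[3L]]$values[2, 2], 1)
})

test_that("accuracy assessment computes commission and omission from points", {
  spec <- grid_spec(20, 20, cell_size = 60)
  u <- matrix(0, 20, 20); u[1:10, ] <- 1
  cls <- raster_layer(spec, u, "urban_flag")

  # perfect agreement
  set.seed(4)
  pts <- data.frame(x = runif(50, 0, 1200), y = runif(50, 0, 1200))
  rc <- xy_to_cell(spec, pts$x, pts$y)
  pts$label <- ifelse(cls$values[rc] == 1, "urban", "rural")
  acc <- assess_accuracy(cls, pts)
  expect_equal(acc$commission_pct, 0)
  expect_equal(acc$omission_pct, 0)

  # 90 agree-urban + 10 classified-urban-but-rural -> commission 10%,
  # padded to the 272-point sample size used per sub-region
  ux <- runif(100, 0, 1200); uy <- runif(100, 610, 1200)  # classified urban
  rx <- runif(172, 0, 1200); ry <- runif(172, 0, 590)     # classified rural
  pts2 <- data.frame(x = c(ux, rx), y = c(uy, ry),
                     label = c(rep("urban", 90), rep("rural", 10),
                               rep("rural", 172)))
  acc2 <- assess_accuracy(cls, pts2)
  expect_equal(acc2$n_points, 272L)
  expect_equal(sum(acc2$counts), 272)
  expect_equal(acc2$commission_pct, 10)
  expect_equal(acc2$omission_pct, 0)

  # empty denominators are undefined, not zero
  none <- raster_layer(spec, 0, "urban_flag")
  acc3 <- assess_accuracy(none, data.frame(x = 30, y = 30,
                                           label = "rural"))
  expect_true(is.na(acc3$commission_pct))
  expect_true(is.na(acc3$omission_pct))

  expect_error(assess_accuracy(cls, data.frame(x = -5, y = 10,
                                               label = "urban")),
               "outside")
})
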