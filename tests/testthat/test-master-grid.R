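test_that("grid construction tiles snapped extents exactly", {
  g <- make_grid_spec(0, 0, 1, 1, 3)
  expect_equal(g$n_rows, 1200L)
  expect_equal(g$n_cols, 1200L)
  expect_equal(cell_size(g), 1 / 1200)

  glob <- global_grid_spec()
  expect_equal(glob$n_cols, 432000L)          # 360 degrees x 1200 cells
  expect_equal(glob$n_rows, 172800L)

  # windows of the global lattice stay aligned with each other
  w <- make_grid_spec(30.0005, 0.0005, 30.01, 0.01, 3)
  k <- (w$origin_lon - (-180)) * 1200
  expect_equal(k, round(k))

  expect_error(make_grid_spec(0, 0, 1, 1, -3), "positive")
  expect_error(make_grid_spec(0, 0, 1, 1, 7), "divide")
  expect_error(make_grid_spec(1, 0, 0, 1, 3), "inverted")
  expect_error(make_grid_spec(0, 1, 1, 0, 3), "inverted")
})

test_that("published display constants are reproduced", {
  k <- grid_constants(global_grid_spec())
  expect_identical(k$cell_size_printed, "0.00083333333")
  expect_equal(k$south_edge_printed, -59.9999994)
  expect_equal(k$nodata, -99999)
})

test_that("terrestrial fraction equals exhaustive fine-cell counting", {
  grid <- tiny_grid(1)                        # one target cell
  fine <- make_grid_spec(grid$origin_lon, grid$origin_lat - cell_size(grid),
                         grid$origin_lon + cell_size(grid), grid$origin_lat,
                         0.3)                 # 10x10 subdivision
  m <- matrix(0, 10, 10); m[1:5, 1:5] <- 1    # 25 of 100 terrestrial
  lc <- covariate_raster(m, fine, categorical = TRUE)
  expect_equal(terrestrial_fraction(lc, 1, grid)$values[1, 1], 0.25)

  lc_all <- covariate_raster(matrix(1, 10, 10), fine, categorical = TRUE)
  expect_equal(terrestrial_fraction(lc_all, 1, grid)$values[1, 1], 1)

  # random 30x30 fine block against brute-force counting
  set.seed(42)
  g3 <- tiny_grid(3)
  fine3 <- make_grid_spec(g3$origin_lon, g3$origin_lat - 3 * cell_size(g3),
                          g3$origin_lon + 3 * cell_size(g3), g3$origin_lat,
                          0.3)
  codes <- matrix(sample(c(10, 40, 210), 900, replace = TRUE), 30, 30)
  tf <- terrestrial_fraction(covariate_raster(codes, fine3, categorical = TRUE),
                             c(10, 40), g3)
  for (i in 1:3) for (j in 1:3) {
    blk <- codes[(i - 1) * 10 + 1:10, (j - 1) * 10 + 1:10]
    expect_equal(tf$values[i, j], sum(blk %in% c(10, 40)) / 100)
  }
  expect_true(all(tf$values >= 0 & tf$values <= 1))

  # misaligned fine raster is rejected
  off <- make_grid_spec(g3$origin_lon, g3$origin_lat - 2 * cell_size(g3),
                        g3$origin_lon + 2 * cell_size(g3), g3$origin_lat, 0.3)
  expect_error(terrestrial_fraction(
    covariate_raster(matrix(1, 20, 20), off), 1, g3), "aligned")
})

test_that("landmass threshold rule is inclusive and monotone", {
  g <- tiny_grid(2)
  fr <- covariate_raster(matrix(c(0.25, 0.2499, 0.8, 0.1), 2, 2), g)
  lm <- landmass_mask(fr, 0.25)
  expect_equal(lm$values[1, 1], 1)            # exactly at threshold: land
  expect_true(is.na(lm$values[2, 1]))         # just below: ocean
  # raising the threshold never converts ocean to land
  lm50 <- landmass_mask(fr, 0.50)
  expect_true(all(is.na(lm$values) <= is.na(lm50$values)))
  expect_error(landmass_mask(fr, 0), "threshold")
  expect_error(landmass_mask(fr, 1.2), "threshold")
})

test_that("cell areas match the spherical quadrangle closed form", {
  g <- make_grid_spec(0, -30, 0.01, 30, 3)
  a <- cell_area_profile(g)
  expect_true(all(a > 0))
  expect_equal(a, rev(a))                     # symmetry about the equator
  expect_true(all(diff(a[1:(length(a) / 2)]) > 0))  # grows toward equator
  # equator row against the closed form evaluated independently
  R <- 6371.0072
  cs <- (1 / 1200) * pi / 180
  expect_equal(a[length(a) / 2 + 1], R^2 * cs * (sin(cs) - sin(0)),
               tolerance = 1e-12)
  # full band area: row sum x columns vs the band closed form
  glob <- global_grid_spec()
  band <- sum(cell_area_profile(glob)) * glob$n_cols
  closed <- 2 * pi * R^2 * (sin(84 * pi / 180) - sin(-60 * pi / 180))
  expect_lt(abs(band - closed) / closed, 0.001)
})
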