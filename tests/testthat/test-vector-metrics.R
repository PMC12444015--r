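test_that("centroid-based gridding allocates whole buildings to one cell", {
  g <- tiny_grid(10)
  cs <- cell_size(g)
  # one building wholly inside cell (5, 5)
  inner <- deg_rect(g$origin_lon + 4.2 * cs, g$origin_lat - 4.8 * cs,
                    g$origin_lon + 4.7 * cs, g$origin_lat - 4.2 * cs)
  m1 <- bcb_metrics(footprint_set(list(inner)), g)
  expect_equal(m1$count[5, 5], 1)
  expect_equal(m1$total_area[5, 5],
               geo_polygon_area_m2(inner$lon, inner$lat))
  expect_equal(sum(m1$count), 1)

  # a building straddling cells (5,5)/(5,6) with its centroid in (5,5)
  strad <- deg_rect(g$origin_lon + 4.3 * cs, g$origin_lat - 4.8 * cs,
                    g$origin_lon + 5.2 * cs, g$origin_lat - 4.2 * cs)
  m2 <- bcb_metrics(footprint_set(list(strad)), g)
  expect_equal(m2$count[5, 5], 1)
  expect_equal(m2$count[5, 6], 0)              # nothing in the other cell
  expect_equal(m2$total_area[5, 6], 0)

  # random sets against an independently coded centroid-assignment tally
  for (seed in c(2, 9)) {
    cfg <- fixture_config(seed = seed, n = 30, n_buildings = 60)
    fs <- gen_vectors(cfg)$ms
    got <- bcb_metrics(fs, cfg$grid)
    want_count <- matrix(0, 30, 30)
    for (p in fs$polygons) {
      x <- p$lon; y <- p$lat
      x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
      cr <- x * y2 - x2 * y; a <- sum(cr) / 2
      cx <- sum((x + x2) * cr) / (6 * a); cy <- sum((y + y2) * cr) / (6 * a)
      cc <- floor((cx - cfg$grid$origin_lon) / cell_size(cfg$grid)) + 1
      rr <- floor((cfg$grid$origin_lat - cy) / cell_size(cfg$grid)) + 1
      want_count[rr, cc] <- want_count[rr, cc] + 1
    }
    expect_equal(got$count, want_count)
    expect_equal(sum(got$count), length(fs$polygons))
    # density x cell area returns the count exactly
    area_km2 <- matrix(cell_area_profile(cfg$grid), 30, 30)
    expect_equal(got$density * area_km2, got$count, tolerance = 1e-12)
  }
})

test_that("intersection-based gridding conserves area across cells", {
  g <- tiny_grid(10)
  cs <- cell_size(g)
  # wholly-contained building: PIB equals BCB
  inner <- deg_rect(g$origin_lon + 4.2 * cs, g$origin_lat - 4.8 * cs,
                    g$origin_lon + 4.7 * cs, g$origin_lat - 4.2 * cs)
  fs1 <- footprint_set(list(inner))
  expect_equal(pib_metrics(fs1, g)$total_area, bcb_metrics(fs1, g)$total_area)

  # an axis-aligned square split 50/50 across two cells
  half <- deg_rect(g$origin_lon + 4.7 * cs, g$origin_lat - 4.8 * cs,
                   g$origin_lon + 5.3 * cs, g$origin_lat - 4.2 * cs)
  mp <- pib_metrics(footprint_set(list(half)), g)
  expect_equal(mp$count[5, 5], 1)
  expect_equal(mp$count[5, 6], 1)              # counted in both cells
  expect_equal(mp$total_area[5, 5], mp$total_area[5, 6], tolerance = 1e-9)

  # conservation and count domination on random sets
  for (seed in c(4, 15)) {
    cfg <- fixture_config(seed = seed, n = 30, n_buildings = 60)
    fs <- gen_vectors(cfg)$ms
    tot <- sum(vapply(fs$polygons,
                      function(p) geo_polygon_area_m2(p$lon, p$lat),
                      numeric(1)))
    mpib <- pib_metrics(fs, cfg$grid)
    mbcb <- bcb_metrics(fs, cfg$grid)
    expect_lt(abs(sum(mpib$total_area) - tot) / tot, 1e-6)
    expect_lt(abs(sum(mbcb$total_area) - tot) / tot, 1e-6)
    # PIB marks every cell BCB marks (and usually more)
    expect_true(all((mpib$count > 0) >= (mbcb$count > 0)))
    expect_gte(sum(mpib$count), sum(mbcb$count))
  }

  # cv is NoData below two observations, defined above
  two <- footprint_set(list(inner, inner))
  m2 <- bcb_metrics(two, g)
  expect_equal(m2$cv_area[5, 5], 0)            # identical buildings
  expect_true(is.na(bcb_metrics(fs1, g)$cv_area[5, 5]))
})

test_that("road gridding conserves network length and flags presence", {
  g <- tiny_grid(10)
  cs <- cell_size(g)
  # one straight west-east road crossing the middle row
  road <- cbind(c(g$origin_lon + 0.2 * cs, g$origin_lon + 9.8 * cs),
                c(g$origin_lat - 5.5 * cs, g$origin_lat - 5.5 * cs))
  rs <- road_set(list(road))
  m <- road_cell_metrics(rs, g)
  expect_true(all(m$presence[6, 2:9] == 1))
  expect_true(all(m$count[6, 2:9] == 1))
  expect_equal(sum(m$presence), 10)
  tot <- geo_line_length_m(road[, 1], road[, 2])
  expect_lt(abs(sum(m$length_m) - tot) / tot, 1e-9)
  # interior cells carry exactly one cell-width of road
  one_cell_m <- haversine_km(g$origin_lat - 5.5 * cs, g$origin_lon,
                             g$origin_lat - 5.5 * cs, g$origin_lon + cs) * 1000
  expect_equal(m$length_m[6, 5], one_cell_m, tolerance = 1e-6)

  # random networks: total length conserved, density consistent
  for (seed in c(3, 21)) {
    cfg <- fixture_config(seed = seed, n = 40, n_roads = 10)
    rs2 <- gen_vectors(cfg)$roads
    tot2 <- sum(vapply(rs2$lines,
                       function(l) geo_line_length_m(l[, 1], l[, 2]),
                       numeric(1)))
    m2 <- road_cell_metrics(rs2, cfg$grid)
    expect_lt(abs(sum(m2$length_m) - tot2) / tot2, 1e-6)
    area_km2 <- matrix(cell_area_profile(cfg$grid), 40, 40)
    expect_equal(m2$density, m2$length_m / area_km2)
  }

  # the empty network yields all-zero layers, not NoData
  m0 <- road_cell_metrics(road_set(list()), g)
  expect_true(all(m0$length_m == 0) && all(m0$presence == 0))
  land <- landmass_mask(covariate_raster(matrix(1, 10, 10), g), 0.25)
  d0 <- distance_to_roads(road_set(list()), g, land)
  expect_true(all(d0$values == 0))             # zero-filled by policy
  # degenerate features are dropped with a message
  expect_message(road_cell_metrics(road_set(list(road[c(1, 1), ])), g),
                 "degenerate")
})

test_that("distance to roads sits on the presence raster", {
  g <- tiny_grid(10)
  cs <- cell_size(g)
  road <- cbind(c(g$origin_lon + 0.2 * cs, g$origin_lon + 9.8 * cs),
                c(g$origin_lat - 5.5 * cs, g$origin_lat - 5.5 * cs))
  land <- landmass_mask(covariate_raster(matrix(1, 10, 10), g), 0.25)
  d <- distance_to_roads(road_set(list(road)), g, land)
  expect_equal(d$values[6, 5], 0)              # on-road cells report zero
  pres <- road_cell_metrics(road_set(list(road)), g)$presence > 0
  expect_lt(max(abs(d$values - oracle_min_distance(g, pres))), 1e-9)
  # adding roads never increases distances
  road2 <- cbind(c(g$origin_lon + 2 * cs, g$origin_lon + 2 * cs),
                 c(g$origin_lat - 0.2 * cs, g$origin_lat - 9.8 * cs))
  d2 <- distance_to_roads(road_set(list(road, road2)), g, land)
  expect_true(all(d2$values <= d$values + 1e-12))
})
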