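test_that("evidence combination takes the per-cell maximum, clipped", {
  g <- tiny_grid(5)
  cell_m2 <- matrix(cell_area_profile(g) * 1e6, 5, 5)
  pm <- covgrid:::new_cell_metrics(g, "PIB")
  pm$total_area[2, 2] <- 300
  pm <- covgrid:::finalise_cell_metrics(pm)
  wf <- covariate_raster(matrix(0, 5, 5), g)
  ev <- evidence_surface(list(pm), wf, g)
  expect_equal(ev[2, 2], 300)                 # footprint area, no settlement
  wf$values[3, 3] <- 1
  ev2 <- evidence_surface(list(pm), wf, g)
  expect_equal(ev2[3, 3], cell_m2[3, 3])      # full fraction: full cell area
  expect_true(all(ev2 <= cell_m2))
  # max rule against a per-cell exhaustive comparison
  set.seed(2)
  wf$values <- matrix(runif(25, 0, 0.001), 5, 5)
  pm$total_area <- matrix(runif(25, 0, 500), 5, 5)
  ev3 <- evidence_surface(list(pm), wf, g)
  expect_equal(ev3, pmin(pmax(pm$total_area, wf$values * cell_m2), cell_m2))
})

test_that("missing cells are zero-or-NoData with positive evidence", {
  s <- matrix(c(150, 0, NA, 0), 2, 2)
  ev <- matrix(c(300, 300, 300, 0), 2, 2)
  miss <- find_missing(s, ev)
  expect_equal(miss, matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  # a cell that already reports surface is never modified downstream
  expect_false(miss[1, 1])
})

test_that("surface fusion assigns the evidence at every epoch, nowhere else", {
  cfg <- fixture_config(seed = 5, n = 40, ghsl_hole_fraction = 0.2)
  bs <- gen_built_stack(cfg)
  ev <- evidence_surface(list(), bs$wsf_fraction, cfg$grid)
  miss <- find_missing(bs$stack$S[["2030"]], ev)
  expect_equal(miss, bs$truth$holes_with_evidence)
  fused <- fuse_surface(bs$stack, ev, miss)
  for (ep in c("2015", "2020", "2025", "2030")) {
    expect_equal(fused$S[[ep]][miss], ev[miss])           # all years filled
    expect_equal(fused$S[[ep]][!miss], bs$stack$S[[ep]][!miss])
    expect_true(all(fused$S[[ep]] >= bs$stack$S[[ep]]))   # monotone
  }
  # idempotence: the second pass finds nothing to do
  ev2 <- evidence_surface(list(), bs$wsf_fraction, cfg$grid)
  again <- fuse_surface(fused, ev2)
  expect_identical(again$S, fused$S)
  # no holes: fusion is a no-op
  cfg0 <- fixture_config(seed = 5, n = 40, ghsl_hole_fraction = 0)
  bs0 <- gen_built_stack(cfg0)
  ev0 <- evidence_surface(list(), bs0$wsf_fraction, cfg0$grid)
  expect_identical(fuse_surface(bs0$stack, ev0)$S, bs0$stack$S)
})

test_that("kernel height regression equals the direct weighted mean", {
  g <- tiny_grid(30)
  H <- matrix(0, 30, 30)
  H[15, 16] <- 7
  expect_equal(nw_height(15, 15, H, g), 7)    # single donor: weights cancel
  H[15, 14] <- 4; H[15, 16] <- 8
  expect_equal(nw_height(15, 15, H, g), 6)    # equidistant donors: midpoint

  # scattered donors against the Gaussian weighted-mean formula
  set.seed(44)
  H2 <- matrix(0, 30, 30)
  donors <- cbind(sample(30, 12), sample(30, 12))
  H2[donors] <- runif(12, 3, 30)
  for (cell in list(c(10, 10), c(20, 25))) {
    got <- nw_height(cell[1], cell[2], H2, g, bandwidth = 500,
                     search_radius = 5000)
    d <- geosphere::distHaversine(
      c(cell_center_lon(g, cell[2]), cell_center_lat(g, cell[1])),
      cbind(cell_center_lon(g, donors[, 2]), cell_center_lat(g, donors[, 1])),
      r = 6371008.8)
    keep <- d <= 5000
    w <- exp(-0.5 * (d[keep] / 500)^2)
    expect_equal(got, sum(w * H2[donors][keep]) / sum(w), tolerance = 1e-9)
  }
  # fallbacks: window mean, then the configured default
  H3 <- matrix(0, 30, 30)
  expect_equal(nw_height(15, 15, H3, g), 5)   # no donors anywhere: default
  expect_error(nw_height(1, 1, H2, g, bandwidth = 0), "positive")
  expect_error(nw_height(1, 1, H2, g, bandwidth = 10, search_radius = 5),
               "search_radius")
})

test_that("volume fusion writes imputed height times evidence at all epochs", {
  cfg <- fixture_config(seed = 6, n = 40)
  bs <- gen_built_stack(cfg)
  ev <- evidence_surface(list(), bs$wsf_fraction, cfg$grid)
  fused <- fuse_volume(fuse_surface(bs$stack, ev), ev)
  h <- attr(fused, "imputed_height")
  miss <- find_missing(bs$stack$V[["2030"]], ev)
  idx <- which(miss)
  expect_gt(length(idx), 0)
  for (ep in c("2015", "2020", "2025", "2030")) {
    expect_equal(fused$V[[ep]][idx], h[idx] * ev[idx])
    # V/S at added cells equals the imputed height, epoch-constant
    expect_lt(max(abs(fused$V[[ep]][idx] / fused$S[[ep]][idx] - h[idx])), 1e-9)
    expect_equal(fused$V[[ep]][!miss], bs$stack$V[[ep]][!miss])
  }
  # worked product example: 300 m2 at 7 m gives 2100 m3
  expect_equal(7 * 300, 2100)
})

test_that("non-residential fusion uses only tagged footprints", {
  cfg <- fixture_config(seed = 7, n = 40)
  bs <- gen_built_stack(cfg)
  vec <- gen_vectors(cfg)
  fused <- nonresidential_fusion(bs$stack, vec$osm)
  for (ep in c("2015", "2020", "2025", "2030")) {
    expect_true(all(fused$nonres_S[[ep]] >= bs$stack$nonres_S[[ep]]))
    expect_true(all(fused$nonres_V[[ep]] >= bs$stack$nonres_V[[ep]]))
  }
  # untagged buildings contribute nothing
  untagged <- vec$osm
  untagged$building_type <- rep("residential", length(untagged$polygons))
  fused0 <- nonresidential_fusion(bs$stack, untagged)
  expect_identical(fused0$nonres_S, bs$stack$nonres_S)
  expect_error(nonresidential_fusion(bs$stack, vec$ms), "tags")
})

test_that("built derivatives report presence and on-feature zero distance", {
  cfg <- fixture_config(seed = 9, n = 30)
  bs <- gen_built_stack(cfg)
  land <- landmass_mask(covariate_raster(matrix(1, 30, 30), cfg$grid), 0.25)
  der <- built_derivatives(bs$stack, land)
  s <- bs$stack$S[["2020"]]
  expect_equal(der$presence[["2020"]]$values, (s > 0) * 1)
  d <- der$distance[["2020"]]$values
  expect_true(all(d[s > 0] == 0))
  expect_lt(max(abs(d - oracle_min_distance(cfg$grid, s > 0))), 1e-9)
})
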