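test_that("geodesic point buffers have the right radius and area", {
  b <- buffer_point(10, 45)                    # default radius: 70 m
  expect_gte(length(b$lon), 64)
  d <- geosphere::distGeo(c(10, 45), cbind(b$lon, b$lat))
  expect_true(all(abs(d - 70) / 70 < 0.001))   # equidistant within 0.1%
  area <- geo_polygon_area_m2(b$lon, b$lat)
  expect_lt(abs(area - pi * 70^2) / (pi * 70^2), 0.005)
  expect_error(buffer_point(Inf, 0), "finite")
  expect_error(buffer_point(0, 0, radius_m = -1), "positive")
})

test_that("rasterisation is cumulative in the status year", {
  g <- tiny_grid(12)
  cs <- cell_size(g)
  rect <- function(r0, r1, c0, c1) list(
    lon = g$origin_lon + c(c0 - 1, c1, c1, c0 - 1) * cs,
    lat = g$origin_lat - c(r0 - 1, r0 - 1, r1, r1) * cs)
  pa <- protected_areas(
    list(rect(2, 5, 2, 5), rect(4, 8, 4, 8)),
    iucn_group = c("cat1", "cat1"), marine = c(FALSE, FALSE),
    status_year = c(2018, 2015))
  m2015 <- cumulative_rasterize(pa, 2015, g)
  m2018 <- cumulative_rasterize(pa, 2018, g)
  expect_false(any(m2015$feature[2, 2]))       # registered later: absent
  expect_true(m2018$feature[2, 2])             # present from 2018 on
  expect_true(m2015$feature[6, 6])
  # nesting over years, and overlap counts once
  expect_true(all(m2015$feature <= m2018$feature))
  expect_equal(max(m2018$feature), 1)

  # random rectangles against a point-in-polygon scan of cell centres
  skip_if_not_installed("sp")
  set.seed(13)
  for (rep in 1:5) {
    w <- g$origin_lon + sort(runif(2, 0, 12 * cs))
    s <- g$origin_lat - 12 * cs + sort(runif(2, 0, 12 * cs))
    poly <- list(lon = c(w[1], w[2], w[2], w[1]),
                 lat = c(s[1], s[1], s[2], s[2]))
    m <- cumulative_rasterize(
      protected_areas(list(poly), "cat1", FALSE, 2015), 2015, g)
    for (i in 1:12) for (j in 1:12) {
      want <- sp::point.in.polygon(cell_center_lon(g, j),
                                   cell_center_lat(g, i),
                                   poly$lon, poly$lat) > 0
      expect_equal(unname(m$feature[i, j]), unname(want))
    }
  }
})

test_that("marine areas contribute only their onshore cells", {
  g <- tiny_grid(10)
  cs <- cell_size(g)
  land_v <- matrix(NA_real_, 10, 10); land_v[, 1:5] <- 1  # coast at col 5/6
  lm <- landmass_mask(covariate_raster((!is.na(land_v)) * 1, g), 0.25)
  rect <- function(c0, c1) list(
    lon = g$origin_lon + c(c0 - 1, c1, c1, c0 - 1) * cs,
    lat = g$origin_lat - c(0, 0, 10, 10) * cs)
  offshore <- cumulative_rasterize(
    protected_areas(list(rect(8, 10)), "cat1", TRUE, 2015), 2015, g)
  straddling <- cumulative_rasterize(
    protected_areas(list(rect(4, 7)), "cat1", TRUE, 2015), 2015, g)
  terr <- feature_mask(matrix(FALSE, 10, 10), g)
  m_off <- merge_marine_terrestrial(terr, offshore, lm)
  expect_false(any(m_off$feature))             # wholly offshore: nothing
  m_str <- merge_marine_terrestrial(terr, straddling, lm)
  expect_true(all(which(m_str$feature, arr.ind = TRUE)[, 2] <= 5))
  expect_true(any(m_str$feature[, 4:5]))
  # merge equals the set union clipped to land
  terr2 <- cumulative_rasterize(
    protected_areas(list(rect(1, 2)), "cat1", FALSE, 2015), 2015, g)
  m2 <- merge_marine_terrestrial(terr2, straddling, lm)
  expect_equal(m2$feature,
               (terr2$feature | straddling$feature) & !is.na(land_v))
})

test_that("the annual suite yields 16 nested mosaics and monotone distances", {
  cfg <- fixture_config(seed = 8, n = 40, n_protected = 10)
  vec <- gen_vectors(cfg)
  land <- landmass_mask(covariate_raster(matrix(1, 40, 40), cfg$grid), 0.25)
  suite <- protected_distance_suite(vec$protected, 2015:2022, cfg$grid, land)
  expect_named(suite$presence, c("cat1", "cat2to6"))
  n_mosaics <- sum(vapply(suite$presence, length, integer(1)))
  expect_equal(n_mosaics, 16L)                 # 2 groups x 8 years
  for (grp in names(suite$presence)) {
    yrs <- names(suite$presence[[grp]])
    for (k in seq_along(yrs)[-1]) {
      a <- suite$presence[[grp]][[yrs[k - 1]]]$feature
      b <- suite$presence[[grp]][[yrs[k]]]$feature
      expect_true(all(a <= b))                 # presence grows with year
      # off the protected areas, edge distances can only shrink as new
      # areas register (inside them the edge can move away, so the check
      # is restricted to non-presence cells)
      da <- suite$distance[[grp]][[yrs[k - 1]]]$values
      db <- suite$distance[[grp]][[yrs[k]]]$values
      off <- !is.na(da) & !is.na(db) & !b
      expect_true(all(da[off] >= db[off] - 1e-12))
    }
  }
  # a year with no areas at all follows the NoData policy
  none <- protected_areas(list(), character(0), logical(0), integer(0))
  s0 <- protected_distance_suite(none, 2015, cfg$grid, land)
  expect_true(all(is.na(s0$distance$cat1[["2015"]]$values)))
})
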