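test_that("resampling is the identity on already-aligned input", {
  g <- tiny_grid(6)
  r <- covariate_raster(matrix(rnorm(36), 6, 6), g)
  for (m in c("bilinear", "nearest")) {
    expect_equal(resample_to_grid(r, g, m)$values, r$values)
  }
  rc <- covariate_raster(matrix(sample(1:3, 36, TRUE), 6, 6), g,
                         categorical = TRUE)
  expect_equal(resample_to_grid(rc, g, "nearest")$values, rc$values)
  expect_error(resample_to_grid(rc, g, "bilinear"), "categorical")
})

test_that("bilinear interpolates the enclosing cell centres", {
  # target centre halfway between source centres holding 2 and 4
  src_g <- make_grid_spec(30, 0.05 - 12 / 3600, 30 + 12 / 3600, 0.05, 6)
  src <- covariate_raster(matrix(c(2, 2, 4, 4), 2, 2), src_g)  # cols 2|4
  tgt <- make_grid_spec(30, 0.05 - 12 / 3600, 30 + 12 / 3600, 0.05, 12)
  expect_equal(resample_to_grid(src, tgt, "bilinear")$values[1, 1], 3)

  # random coarse source against pointwise evaluation of the surface
  set.seed(11)
  sg <- make_grid_spec(30, 0.05 - 120 / 3600, 30 + 120 / 3600, 0.05, 30)
  sv <- matrix(rnorm(16), 4, 4)
  src2 <- covariate_raster(sv, sg)
  tg <- make_grid_spec(30 + 30 / 3600, 0.05 - 75 / 3600,
                       30 + 45 / 3600, 0.05 - 60 / 3600, 3)
  got <- resample_to_grid(src2, tg, "bilinear")$values
  cs <- cell_size(sg)
  for (i in seq_len(tg$n_rows)) for (j in seq_len(tg$n_cols)) {
    u <- (cell_center_lon(tg, j) - sg$origin_lon) / cs - 0.5
    v <- (sg$origin_lat - cell_center_lat(tg, i)) / cs - 0.5
    j0 <- floor(u); i0 <- floor(v); wu <- u - j0; wv <- v - i0
    want <- (1 - wv) * ((1 - wu) * sv[i0 + 1, j0 + 1] + wu * sv[i0 + 1, j0 + 2]) +
      wv * ((1 - wu) * sv[i0 + 2, j0 + 1] + wu * sv[i0 + 2, j0 + 2])
    expect_equal(got[i, j], want)
  }
})

test_that("fraction_average aggregates an integer subdivision exactly", {
  g <- tiny_grid(2)
  fine <- make_grid_spec(g$origin_lon, g$origin_lat - 2 * cell_size(g),
                         g$origin_lon + 2 * cell_size(g), g$origin_lat, 1)
  m <- matrix(runif(36) < 0.5, 6, 6) * 1
  got <- resample_to_grid(covariate_raster(m, fine), g, "fraction_average")
  expect_equal(got$values[1, 1], mean(m[1:3, 1:3]))
  expect_equal(got$values[2, 2], mean(m[4:6, 4:6]))
})

test_that("mosaicking reconstructs a tiled field", {
  g <- tiny_grid(8)
  field <- matrix(rnorm(64), 8, 8)
  cs <- cell_size(g)
  tile <- function(rows, cols) {
    tg <- make_grid_spec(g$origin_lon + (min(cols) - 1) * cs,
                         g$origin_lat - max(rows) * cs,
                         g$origin_lon + max(cols) * cs,
                         g$origin_lat - (min(rows) - 1) * cs, 3)
    covariate_raster(field[rows, cols, drop = FALSE], tg)
  }
  m <- mosaic(list(tile(1:4, 1:4), tile(1:4, 5:8), tile(5:8, 1:4),
                   tile(5:8, 5:8)))
  expect_equal(m$values, field)
  expect_true(same_grid(m$grid, g))
  expect_false(anyNA(m$values))               # no NoData at interior seams
  expect_equal(mosaic(list(tile(1:8, 1:8)))$values, field)  # identity
  bad_g <- make_grid_spec(30, 0, 30.01, 0.01, 6)
  bad <- covariate_raster(matrix(0, bad_g$n_rows, bad_g$n_cols), bad_g)
  expect_error(mosaic(list(tile(1:4, 1:4), bad)), "resolution")
})

test_that("mean gap filling iterates the 8-neighbour mean to closure", {
  g <- tiny_grid(3)
  land <- covariate_raster(matrix(1, 3, 3), g)
  v <- matrix(c(2, NA, 4, NA, NA, NA, NA, NA, NA), 3, 3)
  v[2, 2] <- NA; v[1, 2] <- NA
  v <- matrix(NA_real_, 3, 3); v[1, 1] <- 2; v[3, 1] <- 4
  filled <- fill_coastal_gaps_mean(covariate_raster(v, g), land)
  expect_equal(filled$values[2, 1], 3)        # neighbours {2, 4}
  expect_false(anyNA(filled$values))
  expect_equal(filled$values[1, 1], 2)        # valid cells untouched
  expect_equal(filled$values[3, 1], 4)

  r_full <- covariate_raster(matrix(rnorm(9), 3, 3), g)
  expect_equal(fill_coastal_gaps_mean(r_full, land)$values, r_full$values)

  # two-cell-deep strip: second pass reproduces the hand-simulated means
  g6 <- tiny_grid(6)
  land_v <- matrix(NA_real_, 6, 6); land_v[1, ] <- 1   # land: top row only
  land6 <- covariate_raster(land_v, g6)
  v6 <- matrix(NA_real_, 6, 6)
  v6[1, 1] <- 1; v6[1, 6] <- 4
  got <- fill_coastal_gaps_mean(covariate_raster(v6, g6), land6)
  expect_equal(got$values[1, ], c(1, 1, 1, 4, 4, 4))
  expect_true(all(is.na(got$values[2:6, ])))  # ocean never gains values

  # a landmass component with no valid cell anywhere is an error
  lonely <- covariate_raster(matrix(NA_real_, 3, 3), g)
  expect_error(fill_coastal_gaps_mean(lonely, land), "unfillable")
})

test_that("majority gap filling takes the modal neighbour, ties to the smallest code", {
  g <- tiny_grid(2)
  land <- covariate_raster(matrix(1, 2, 2), g)
  v <- matrix(c(40, 40, 11, NA), 2, 2)
  got <- fill_coastal_gaps_majority(covariate_raster(v, g, categorical = TRUE), land)
  expect_equal(got$values[2, 2], 40)          # {40, 40, 11} -> 40

  v2 <- matrix(c(40, NA, 11, NA), 2, 2)
  v2 <- matrix(c(40, 11, NA, NA), 2, 2)       # neighbours {40, 11}: tie
  got2 <- fill_coastal_gaps_majority(covariate_raster(v2, g, categorical = TRUE), land)
  expect_equal(got2$values[1, 2], 11)         # smallest class code wins

  # random categorical gaps against an exhaustive neighbourhood tally
  set.seed(5)
  g8 <- tiny_grid(8)
  land8 <- covariate_raster(matrix(1, 8, 8), g8)
  v8 <- matrix(sample(c(11, 40, 210), 64, TRUE), 8, 8)
  holes <- matrix(runif(64) < 0.15, 8, 8)
  v8h <- v8; v8h[holes] <- NA
  got8 <- fill_coastal_gaps_majority(covariate_raster(v8h, g8, categorical = TRUE),
                                     land8)
  first_pass <- which(holes, arr.ind = TRUE)
  for (k in seq_len(nrow(first_pass))) {
    i <- first_pass[k, 1]; j <- first_pass[k, 2]
    nb <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= 8 && jj >= 1 && jj <= 8 && !is.na(v8h[ii, jj]))
        nb <- c(nb, v8h[ii, jj])
    }
    if (length(nb) > 0) {                     # first-pass-fillable cells
      tab <- table(nb)
      expect_equal(got8$values[i, j],
                   min(as.numeric(names(tab)[tab == max(tab)])))
    }
  }
})

test_that("annual climate aggregation follows the stated rules", {
  g <- tiny_grid(2)
  mk <- function(x) covariate_raster(matrix(x, 2, 2), g, year = 2020)
  months <- replicate(12, mk(12), simplify = FALSE)
  expect_equal(annual_precipitation(months)$values[1, 1], 120)  # mean x 10
  expect_equal(annual_precipitation(replicate(12, mk(0), simplify = FALSE))$values[1, 1], 0)
  expect_error(annual_precipitation(months[1:11]), "12")

  set.seed(9)
  rand <- replicate(12, mk(runif(4, 0, 200)), simplify = FALSE)
  want <- Reduce(`+`, lapply(rand, function(r) r$values)) / 12 * 10
  expect_equal(annual_precipitation(rand)$values, want)
  # permuting months leaves the annual value unchanged
  expect_equal(annual_precipitation(rand[sample(12)])$values, want)

  expect_equal(annual_temperature(list(mk(280), mk(290)))$values[1, 1], 285)
  expect_equal(annual_temperature(list(mk(300)))$values, matrix(300, 2, 2))
  # scattered NoData: masked mean over available months
  a <- mk(280); a$values[1, 1] <- NA
  b <- mk(290)
  got <- annual_temperature(list(a, b))
  expect_equal(got$values[1, 1], 290)
  expect_equal(got$values[2, 2], 285)
  c_ <- mk(1); c_$values[] <- NA
  expect_true(is.na(annual_temperature(list(c_))$values[1, 1]))
})

test_that("slope is zero on flat terrain and arctan(g) on a meridian ramp", {
  g <- tiny_grid(10)
  flat <- covariate_raster(matrix(100, 10, 10), g)
  expect_equal(slope_from_dem(flat)$values, matrix(0, 10, 10))

  dy <- 6371.0088 * 1000 * cell_size(g) * pi / 180
  grad <- 0.1                                  # rise per metre, northward
  ramp <- covariate_raster(matrix(rep(-grad * dy * (1:10), 10), 10, 10), g)
  s <- slope_from_dem(ramp)
  expect_equal(s$values[5, 5], atan(grad) * 180 / pi, tolerance = 1e-9)
  expect_true(all(s$values >= 0 & s$values < 90))
  expect_error(slope_from_dem(covariate_raster(matrix(NA_real_, 2, 2),
                                               tiny_grid(2))), "NoData")
})
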