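# Seeded synthetic-fixture generators. They emulate, at window scale,
# every input the harmonisation pipeline consumes: a coherent coastline
# with inland water, a 22-class land-cover mosaic, an elevation field
# with coastal gaps, radiance grids with injected spikes at flare and
# volcano sites, building footprints (some straddling cell edges by
# construction), road networks, protected areas, and a built stack with
# deliberate coverage holes. Every generator is a pure function of its
# configuration, and ground-truth side channels (hole sets, spike
# locations) are emitted for oracle tests only - pipeline code never
# reads them.

#' Fixture configuration
#'
#' @param seed Integer seed; all generators derive their randomness from
#'   it (each generator uses a distinct fixed offset so the outputs are
#'   independent of generation order).
#' @param n Window size in cells (n x n); default 120 (~0.1 degrees),
#'   chosen so brute-force oracles stay in the seconds range.
#' @param origin_lon,origin_lat Window origin, snapped to the global
#'   lattice; defaults straddle the equator.
#' @param res_arcsec Cell size in arc-seconds; default 3.
#' @param land_fraction Target terrestrial share of the window.
#' @param n_buildings,n_roads,n_protected,n_sites Feature counts.
#' @param spike_magnitude Radiance multiplier for injected spikes.
#' @param ghsl_hole_fraction Share of truly built cells zeroed in the
#'   built stack to create known missing cells.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1, n = 120, origin_lon = 30,
                           origin_lat = 0.05, res_arcsec = 3,
                           land_fraction = 0.65, n_buildings = 150,
                           n_roads = 12, n_protected = 12, n_sites = 5,
                           spike_magnitude = 100, ghsl_hole_fraction = 0.15) {
  stopifnot(n >= 8, land_fraction >= 0, land_fraction <= 1,
            n_buildings >= 0, n_roads >= 0, n_protected >= 0, n_sites >= 0,
            ghsl_hole_fraction >= 0, ghsl_hole_fraction <= 1)
  cs <- res_arcsec / 3600
  grid <- make_grid_spec(origin_lon, origin_lat - n * cs,
                         origin_lon + n * cs, origin_lat, res_arcsec)
  structure(list(seed = as.integer(seed), n = as.integer(n), grid = grid,
                 land_fraction = land_fraction, n_buildings = n_buildings,
                 n_roads = n_roads, n_protected = n_protected,
                 n_sites = n_sites, spike_magnitude = spike_magnitude,
                 ghsl_hole_fraction = ghsl_hole_fraction),
            class = "fixture_config")
}

# internal: run code under a local RNG state seeded with seed + offset
with_fixture_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  force(code)
}

# internal: label 8-connected components of a logical matrix (0 = background)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- ((cur - 1L) %% nr) + 1L
      j <- ((cur - 1L) %/% nr) + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          k <- (jj - 1L) * nr + ii
          lab[k] <- nxt
          queue <- c(queue, k)
        }
      }
    }
  }
  lab
}

# internal: smooth correlated random field via iterated 3x3 box blur
smooth_field <- function(nr, nc, passes = 8) {
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  for (i in seq_len(passes)) {
    p <- matrix(0, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- m
    # replicate edges so the blur does not drain towards the border
    p[1, ] <- p[2, ]; p[nr + 2, ] <- p[nr + 1, ]
    p[, 1] <- p[, 2]; p[, nc + 2] <- p[, nc + 1]
    m <- (p[1:nr, 1:nc] + p[1:nr, 2:(nc + 1)] + p[1:nr, 3:(nc + 2)] +
          p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 2:(nc + 1)] + p[2:(nr + 1), 3:(nc + 2)] +
          p[3:(nr + 2), 1:nc] + p[3:(nr + 2), 2:(nc + 1)] + p[3:(nr + 2), 3:(nc + 2)]) / 9
  }
  m
}

#' Generate the landscape fixtures
#'
#' Produces, deterministically under the seed: a fine-resolution (factor
#' 3 subdivision) 22-class land-cover mosaic whose terrestrial share
#' hits the configured land fraction, a fine binary permanent-water
#' raster (ocean plus inland blobs), and an elevation raster on the
#' master window whose own coastline deliberately disagrees with the
#' land-cover coastline, leaving coastal NoData gaps for the fill step.
#'
#' @param cfg A `fixture_config`.
#' @return List with `fine_landcover`, `fine_water` (fine-grid
#'   `covariate_raster`s), `dem` (master-grid raster with gaps), and
#'   `fine_grid`.
#' @export
gen_landscape <- function(cfg) {
  with_fixture_seed(cfg$seed, 101, {
    grid <- cfg$grid
    f <- 3L
    fine <- make_grid_spec(grid$origin_lon,
                           grid$origin_lat - grid$n_rows * cell_size(grid),
                           grid$origin_lon + grid$n_cols * cell_size(grid),
                           grid$origin_lat, grid$res_arcsec / f)
    nrf <- fine$n_rows; ncf <- fine$n_cols
    elev_field <- smooth_field(nrf, ncf, 10)
    # land = upper quantile of the field, so the share is hit exactly on
    # the fine lattice
    land_fine <- if (cfg$land_fraction >= 1) {
      matrix(TRUE, nrf, ncf)
    } else if (cfg$land_fraction <= 0) {
      matrix(FALSE, nrf, ncf)
    } else {
      elev_field >= stats::quantile(elev_field, 1 - cfg$land_fraction)
    }
    # inland water blobs from an independent field
    water_field <- smooth_field(nrf, ncf, 10)
    inland_water <- water_field >= stats::quantile(water_field, 0.92)
    fine_water <- (!land_fine) | (land_fine & inland_water)
    # land cover: land cells draw from the 21 non-water classes laid out
    # by quantile bands of a third field; the water class (210) marks
    # the ocean. Inland water blobs keep their land class: they sit on
    # the landmass and are described by the separate water raster.
    class_field <- smooth_field(nrf, ncf, 6)
    src_codes <- setdiff(default_reclass_map()$src, 210)
    bands <- stats::quantile(class_field, seq(0, 1, length.out = length(src_codes) + 1))
    lc <- matrix(src_codes[pmin(findInterval(class_field, bands, all.inside = TRUE),
                                length(src_codes))], nrf, ncf)
    lc[!land_fine] <- 210
    # elevation on the master window; its own coastline is the land field
    # aggregated with a stricter threshold, so gaps appear on the coast
    elev_coarse <- block_aggregate(elev_field, f, mean)
    land_frac_coarse <- block_aggregate(matrix(as.numeric(land_fine), nrf), f, mean)
    dem_vals <- 20 + 450 * (elev_coarse - min(elev_coarse)) /
      max(1e-12, diff(range(elev_coarse)))
    dem_full <- dem_vals
    dem_vals[land_frac_coarse < 0.5] <- NA_real_
    # elevation sources cover every real island somewhere: guarantee at
    # least one valid cell per landmass component (25% coastline rule)
    comp <- label_components(land_frac_coarse >= 0.25)
    for (k in seq_len(max(comp, 0))) {
      cells <- which(comp == k)
      if (length(cells) > 0 && all(is.na(dem_vals[cells]))) {
        top <- cells[which.max(land_frac_coarse[cells])]
        dem_vals[top] <- dem_full[top]
      }
    }
    list(
      fine_landcover = covariate_raster(lc, fine, units = "class",
                                        semantics = "landcover_source",
                                        categorical = TRUE),
      fine_water = covariate_raster(matrix(as.numeric(fine_water), nrf), fine,
                                    units = "binary",
                                    semantics = "permanent_water"),
      dem = covariate_raster(dem_vals, grid, units = "m", semantics = "elevation"),
      fine_grid = fine
    )
  })
}

# internal: a rotated rectangle polygon around (lon, lat), metres sides
rect_polygon <- function(lon, lat, w_m, h_m, angle_rad) {
  m_per_deg <- EARTH_RADIUS_KM * 1000 * pi / 180
  coslat <- cos(lat * pi / 180)
  hw <- w_m / 2; hh <- h_m / 2
  cx <- c(-hw, hw, hw, -hw); cy <- c(-hh, -hh, hh, hh)
  xr <- cx * cos(angle_rad) - cy * sin(angle_rad)
  yr <- cx * sin(angle_rad) + cy * cos(angle_rad)
  list(lon = lon + xr / (m_per_deg * coslat), lat = lat + yr / m_per_deg)
}

# internal: one random footprint set within the window
gen_footprints <- function(grid, n, with_tags = FALSE) {
  if (n == 0) return(footprint_set(list(), numeric(0),
                                   if (with_tags) character(0) else NULL))
  cs <- cell_size(grid)
  w <- grid$origin_lon; e <- w + grid$n_cols * cs
  nn <- grid$origin_lat; s <- nn - grid$n_rows * cs
  pad <- 2 * cs
  lon <- stats::runif(n, w + pad, e - pad)
  lat <- stats::runif(n, s + pad, nn - pad)
  # force ~30% of centres close to a cell edge so footprints straddle
  snap <- seq_len(n) %% 10 < 3
  lon[snap] <- w + (round((lon[snap] - w) / cs) + 0.02) * cs
  polys <- lapply(seq_len(n), function(i) {
    rect_polygon(lon[i], lat[i], stats::runif(1, 8, 30),
                 stats::runif(1, 8, 30), stats::runif(1, 0, pi))
  })
  tags <- NULL
  if (with_tags) {
    tags <- sample(c("residential", "house", "public", "industrial",
                     "outbuilding", "apartments"), n, replace = TRUE)
  }
  footprint_set(polys, confidence = stats::runif(n, 0.5, 1),
                building_type = tags)
}

#' Generate the vector fixtures
#'
#' Building footprints for two imagery-derived sources plus a tagged
#' OSM-style set, random-walk road polylines, and protected areas with
#' status years spanning 2010-2022, roughly 20% of which are point
#' records (to exercise geodesic buffering) and a quarter marine.
#'
#' @param cfg A `fixture_config`.
#' @return List with `ms`, `google`, `osm` (`footprint_set`s), `roads`
#'   (`road_set`), `protected` (`protected_areas`), and `truth`
#'   (side-channel counts for oracle tests).
#' @export
gen_vectors <- function(cfg) {
  with_fixture_seed(cfg$seed, 202, {
    grid <- cfg$grid
    cs <- cell_size(grid)
    w <- grid$origin_lon; e <- w + grid$n_cols * cs
    nn <- grid$origin_lat; s <- nn - grid$n_rows * cs
    ms <- gen_footprints(grid, cfg$n_buildings)
    google <- gen_footprints(grid, max(0, round(cfg$n_buildings * 0.8)))
    osm <- gen_footprints(grid, max(0, round(cfg$n_buildings * 0.4)),
                          with_tags = TRUE)
    lines <- lapply(seq_len(cfg$n_roads), function(i) {
      k <- sample(3:6, 1)
      x <- numeric(k); y <- numeric(k)
      x[1] <- stats::runif(1, w, e); y[1] <- stats::runif(1, s, nn)
      for (j in 2:k) {
        x[j] <- min(max(x[j - 1] + stats::rnorm(1, 0, 8 * cs), w), e)
        y[j] <- min(max(y[j - 1] + stats::rnorm(1, 0, 8 * cs), s), nn)
      }
      cbind(x, y)
    })
    n_pa <- cfg$n_protected
    geoms <- list(); marine <- logical(0); yrs <- integer(0)
    if (n_pa > 0) {
      is_point <- stats::runif(n_pa) < 0.2
      for (i in seq_len(n_pa)) {
        cx <- stats::runif(1, w, e); cy <- stats::runif(1, s, nn)
        if (is_point[i]) {
          geoms[[i]] <- c(cx, cy)
        } else {
          half_w <- stats::runif(1, 3, 15) * cs
          half_h <- stats::runif(1, 3, 15) * cs
          th <- stats::runif(1, 0, pi / 2)
          geoms[[i]] <- list(
            lon = cx + c(-half_w, half_w, half_w, -half_w) * cos(th) -
              c(-half_h, -half_h, half_h, half_h) * sin(th),
            lat = cy + c(-half_w, half_w, half_w, -half_w) * sin(th) +
              c(-half_h, -half_h, half_h, half_h) * cos(th))
        }
      }
      marine <- stats::runif(n_pa) < 0.25
      yrs <- sample(2010:2022, n_pa, replace = TRUE)
    }
    pa <- protected_areas(geoms,
                          iucn_group = if (n_pa > 0)
                            sample(c("cat1", "cat2to6"), n_pa, replace = TRUE,
                                   prob = c(0.3, 0.7)) else character(0),
                          marine = marine, status_year = yrs)
    list(ms = ms, google = google, osm = osm,
         roads = road_set(lines), protected = pa,
         truth = list(n_ms = length(ms$polygons),
                      n_google = length(google$polygons),
                      n_osm = length(osm$polygons),
                      n_roads = length(lines), n_protected = n_pa))
  })
}

#' Generate annual radiance fixtures with injected spikes
#'
#' A lognormal radiance background correlated with a settlement-like
#' field, repeated per year with small multiplicative jitter, plus
#' spikes of `spike_magnitude` times the local background injected at
#' `n_sites` random cells; the site coordinates are recorded in a site
#' list (kind alternating flare/volcano).
#'
#' @param cfg A `fixture_config`.
#' @param years Integer vector of years; default 2015:2023.
#' @return List with `grids` (named list of `covariate_raster`s),
#'   `sites` (data frame lon/lat/kind), and `truth` (spike cells and
#'   their background values).
#' @export
gen_radiance <- function(cfg, years = 2015:2023) {
  with_fixture_seed(cfg$seed, 303, {
    grid <- cfg$grid
    nr <- grid$n_rows; nc <- grid$n_cols
    settle <- smooth_field(nr, nc, 8)
    base <- exp(0.8 * (settle - mean(settle)) / stats::sd(settle))
    n_sites <- cfg$n_sites
    rows <- integer(0); cols <- integer(0)
    if (n_sites > 0) {
      cells <- sample(nr * nc, n_sites)
      rows <- ((cells - 1) %% nr) + 1
      cols <- ((cells - 1) %/% nr) + 1
    }
    grids <- lapply(years, function(y) {
      v <- base * exp(stats::rnorm(1, 0, 0.05))
      if (n_sites > 0) v[cbind(rows, cols)] <- cfg$spike_magnitude * base[cbind(rows, cols)]
      covariate_raster(v, grid, units = "nW/cm2/sr", year = y,
                       semantics = "ntl_radiance_source")
    })
    names(grids) <- as.character(years)
    sites <- data.frame(
      lon = cell_center_lon(grid, cols),
      lat = cell_center_lat(grid, rows),
      kind = if (n_sites > 0)
        rep_len(c("flare", "volcano"), n_sites) else character(0))
    list(grids = grids, sites = sites,
         truth = list(spike_rows = rows, spike_cols = cols,
                      background = base))
  })
}

#' Generate monthly climate fixtures
#'
#' Monthly precipitation (mm) and daytime land-surface temperature (K)
#' rasters on a coarser lattice-aligned grid (factor 5, emulating the
#' coarser native resolution of climate sources), twelve months per
#' year, deterministic under the seed. Temperature carries scattered
#' NoData to exercise the masked annual mean.
#'
#' @param cfg A `fixture_config` (window size must divide by 5).
#' @param years Integer vector of years; default 2015:2023.
#' @return List with `precip[[year]]` and `temp[[year]]`, each a list of
#'   12 monthly `covariate_raster`s on the coarse grid.
#' @export
gen_climate <- function(cfg, years = 2015:2023) {
  with_fixture_seed(cfg$seed, 505, {
    grid <- cfg$grid
    f <- 5L
    if (grid$n_rows %% f != 0 || grid$n_cols %% f != 0)
      stop("window size must be a multiple of ", f, " for the climate fixture")
    coarse <- make_grid_spec(grid$origin_lon,
                             grid$origin_lat - grid$n_rows * cell_size(grid),
                             grid$origin_lon + grid$n_cols * cell_size(grid),
                             grid$origin_lat, grid$res_arcsec * f)
    nr <- coarse$n_rows; nc <- coarse$n_cols
    base_p <- 60 + 40 * smooth_field(nr, nc, 4)
    base_t <- 295 + 8 * smooth_field(nr, nc, 4)
    season <- sin(2 * pi * (1:12) / 12)
    precip <- list(); temp <- list()
    for (y in years) {
      py <- lapply(1:12, function(m) {
        v <- pmax(base_p * (1 + 0.5 * season[m]) +
                    matrix(stats::rnorm(nr * nc, 0, 5), nr, nc), 0)
        covariate_raster(v, coarse, units = "mm", year = y,
                         semantics = "monthly_precipitation")
      })
      ty <- lapply(1:12, function(m) {
        v <- base_t + 5 * season[m] + matrix(stats::rnorm(nr * nc, 0, 0.5), nr, nc)
        v[matrix(stats::runif(nr * nc) < 0.02, nr, nc)] <- NA_real_
        covariate_raster(v, coarse, units = "K", year = y,
                         semantics = "monthly_temperature")
      })
      precip[[as.character(y)]] <- py
      temp[[as.character(y)]] <- ty
    }
    list(precip = precip, temp = temp, coarse_grid = coarse)
  })
}

#' Generate the built-stack fixture with known holes
#'
#' Derives a "true" built field from a settlement-like surface, builds
#' the four-epoch surface/volume stack and single-epoch height layer
#' from it, then zeroes a configured fraction of truly built cells
#' across all epochs (surface, volume, height) to create known missing
#' cells. A settlement-fraction raster covering most built cells -
#' including some holes - provides the fusion evidence. The hole set is
#' returned as ground truth for recovery tests and is never read by
#' pipeline code.
#'
#' @param cfg A `fixture_config`.
#' @return List with `stack` (`built_stack`), `wsf_fraction`
#'   (`covariate_raster`), and `truth` (logical matrices `holes` and
#'   `holes_with_evidence`, plus the intact stack).
#' @export
gen_built_stack <- function(cfg) {
  with_fixture_seed(cfg$seed, 404, {
    grid <- cfg$grid
    nr <- grid$n_rows; nc <- grid$n_cols
    cell_m2 <- matrix(cell_area_profile(grid) * 1e6, nr, nc)
    field <- smooth_field(nr, nc, 8)
    built <- field >= stats::quantile(field, 0.85)
    intensity <- (field - stats::quantile(field, 0.85)) /
      max(1e-12, max(field) - stats::quantile(field, 0.85))
    S_true <- ifelse(built, pmin(pmax(intensity, 0.05), 1) * 0.6 * cell_m2, 0)
    H_true <- ifelse(built, 3 + 25 * pmax(intensity, 0), 0)
    growth <- c("2015" = 0.85, "2020" = 0.93, "2025" = 1, "2030" = 1)
    S <- lapply(growth, function(g) S_true * g)
    V <- lapply(growth, function(g) S_true * g * H_true)
    nonres_cells <- built & (smooth_field(nr, nc, 6) > 0.3)
    nres_S <- lapply(growth, function(g) ifelse(nonres_cells, 0.4 * S_true * g, 0))
    nres_V <- lapply(growth, function(g) ifelse(nonres_cells, 0.4 * S_true * g * H_true, 0))
    holes <- matrix(FALSE, nr, nc)
    built_idx <- which(built)
    if (cfg$ghsl_hole_fraction > 0 && length(built_idx) > 0) {
      k <- round(cfg$ghsl_hole_fraction * length(built_idx))
      holes[sample(built_idx, k)] <- TRUE
    }
    H <- H_true; H[holes] <- 0
    punch <- function(lst) lapply(lst, function(m) { m[holes] <- 0; m })
    stack <- built_stack(punch(S), punch(V), H,
                         nonres_S = punch(nres_S), nonres_V = punch(nres_V),
                         grid = grid)
    # settlement evidence covers ~70% of built cells, holes included
    covered <- built & (stats::runif(nr * nc) < 0.7)
    wsf <- ifelse(covered, S_true / cell_m2, 0)
    list(stack = stack,
         wsf_fraction = covariate_raster(wsf, grid, units = "fraction",
                                         semantics = "settlement_fraction"),
         truth = list(holes = holes,
                      holes_with_evidence = holes & covered,
                      S_true = S_true, H_true = H_true, built = built))
  })
}
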