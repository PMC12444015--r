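# Protected areas: geodesic point buffering, cumulative annual
# rasterisation per IUCN group, marine/terrestrial merge, and distance
# covariates.

#' Construct a protected-area record list
#'
#' @param geometries List of geometries: polygons as `list(lon, lat)` or
#'   points as length-2 numeric vectors `c(lon, lat)`.
#' @param iucn_group Character vector, `"cat1"` (strict nature reserves
#'   and wilderness areas) or `"cat2to6"` (all other categories).
#'   Records with unknown or unassigned category should be passed as
#'   `"cat2to6"` upstream (the default treatment, logged by the reader).
#' @param marine Logical vector; TRUE for marine protected areas.
#' @param status_year Integer vector of registration years.
#' @return An object of class `protected_areas` (a data-frame-like list).
#' @export
protected_areas <- function(geometries, iucn_group, marine, status_year) {
  n <- length(geometries)
  stopifnot(length(iucn_group) == n, length(marine) == n,
            length(status_year) == n)
  if (!all(iucn_group %in% c("cat1", "cat2to6")))
    stop("iucn_group must be 'cat1' or 'cat2to6'")
  structure(list(geometries = geometries, iucn_group = iucn_group,
                 marine = marine, status_year = as.integer(status_year)),
            class = "protected_areas")
}

#' Geodesic buffer around a point
#'
#' Point records stand proxy for their protected area through a geodesic
#' circle of the stated radius (default 70 m) on the WGS84 ellipsoid,
#' discretised with `n_vertices` vertices.
#'
#' @param lon,lat Point coordinates in degrees.
#' @param radius_m Buffer radius in metres; default 70.
#' @param n_vertices Number of polygon vertices; default 64.
#' @return A polygon `list(lon, lat)`.
#' @export
buffer_point <- function(lon, lat, radius_m = 70, n_vertices = 64) {
  if (!is.finite(lon) || !is.finite(lat)) stop("non-finite point coordinates")
  if (radius_m <= 0) stop("radius must be positive")
  azi <- seq(0, 360, length.out = n_vertices + 1)[-(n_vertices + 1)]
  p <- geosphere::geodesic(cbind(lon, lat), azi, radius_m)
  list(lon = p[, 1], lat = p[, 2])
}

# internal: coerce a geometry record to a polygon (buffering points)
pa_polygon <- function(g, buffer_radius_m = 70) {
  if (is.list(g) && !is.null(g$lon)) return(g)
  if (is.numeric(g) && length(g) == 2)
    return(buffer_point(g[1], g[2], buffer_radius_m))
  NULL
}

#' Cumulative presence raster of protected areas up to a year
#'
#' A cell is a feature iff its centre falls inside any protected area
#' whose status year is less than or equal to `year` (the annual
#' datasets are cumulative: the 2015 layer contains areas registered
#' from the first record up to and including 2015). Point records are
#' buffered to polygons first. Overlapping areas yield a single
#' presence. An empty selection returns an empty (all-FALSE) mask.
#'
#' @param areas A `protected_areas` object (optionally pre-filtered by
#'   group or marine flag).
#' @param year Reference year.
#' @param grid Target `grid_spec`.
#' @param buffer_radius_m Radius for point records; default 70 m.
#' @return A `feature_mask`.
#' @export
cumulative_rasterize <- function(areas, year, grid, buffer_radius_m = 70) {
  feat <- matrix(FALSE, grid$n_rows, grid$n_cols)
  sel <- which(areas$status_year <= year)
  cs <- cell_size(grid)
  for (i in sel) {
    poly <- pa_polygon(areas$geometries[[i]], buffer_radius_m)
    if (is.null(poly)) {
      message("dropping protected area #", i, " with missing/irreparable geometry")
      next
    }
    bb <- bbox_cells(grid, poly$lon, poly$lat)
    if (is.null(bb)) next
    rows <- bb$r0:bb$r1; cols <- bb$c0:bb$c1
    px <- rep(cell_center_lon(grid, cols), each = length(rows))
    py <- rep(cell_center_lat(grid, rows), times = length(cols))
    inside <- point_in_poly(px, py, poly$lon, poly$lat)
    if (any(inside)) {
      sub <- feat[rows, cols, drop = FALSE]
      sub[matrix(inside, nrow = length(rows))] <- TRUE
      feat[rows, cols] <- sub
    }
  }
  feature_mask(feat, grid)
}

#' Merge terrestrial and marine presence, clipped to the landmass
#'
#' The union of the terrestrial and marine presence masks intersected
#' with the landmass: marine protected areas can straddle into
#' terrestrial terrain along coastlines and contribute exactly their
#' onshore cells; everything offshore is removed.
#'
#' @param terr,marine `feature_mask` objects on the same grid.
#' @param landmass Landmass raster on the same grid.
#' @return A `feature_mask` restricted to land.
#' @export
merge_marine_terrestrial <- function(terr, marine, landmass) {
  if (!same_grid(terr$grid, marine$grid) ||
      !same_grid(terr$grid, landmass$grid))
    stop("grid mismatch between terrestrial, marine and landmass layers")
  land <- land_logical(landmass)
  feature_mask((terr$feature | marine$feature) & land, terr$grid,
               domain = land)
}

#' Annual protected-area distance covariates per IUCN group
#'
#' For every year and each of the two IUCN groups: cumulative
#' rasterisation of the terrestrial and marine subsets, merge and clip
#' to the landmass, then great-circle distance to the closest protected
#' area boundary. Eight years and two groups yield sixteen presence
#' mosaics before the distance step. Years with no areas follow the
#' empty-feature policy (NoData by default).
#'
#' @param areas A `protected_areas` object.
#' @param years Integer vector of years (default 2015:2022).
#' @param grid Target `grid_spec`.
#' @param landmass Landmass raster.
#' @param empty Empty-feature policy, `"nodata"` (default) or `"zero"`.
#' @return List with `presence[[group]][[year]]` (`feature_mask`) and
#'   `distance[[group]][[year]]` (`covariate_raster`, km).
#' @export
protected_distance_suite <- function(areas, years = 2015:2022, grid, landmass,
                                     empty = c("nodata", "zero")) {
  empty <- match.arg(empty)
  groups <- c("cat1", "cat2to6")
  presence <- list(); distance <- list()
  for (grp in groups) {
    gi <- areas$iucn_group == grp
    pres_y <- list(); dist_y <- list()
    for (y in years) {
      terr_sel <- which(gi & !areas$marine)
      mar_sel <- which(gi & areas$marine)
      sub <- function(sel) protected_areas(areas$geometries[sel],
                                           areas$iucn_group[sel],
                                           areas$marine[sel],
                                           areas$status_year[sel])
      terr <- cumulative_rasterize(sub(terr_sel), y, grid)
      mar <- cumulative_rasterize(sub(mar_sel), y, grid)
      merged <- merge_marine_terrestrial(terr, mar, landmass)
      r <- distance_or_policy(merged, empty = empty, boundary = TRUE)
      r$year <- y
      r$semantics <- sprintf("distance_to_protected_%s", grp)
      pres_y[[as.character(y)]] <- merged
      dist_y[[as.character(y)]] <- r
    }
    presence[[grp]] <- pres_y
    distance[[grp]] <- dist_y
  }
  list(presence = presence, distance = distance)
}
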