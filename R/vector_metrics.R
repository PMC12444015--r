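# Gridding of building footprints (centroid-based and intersection-based
# allocation) and road networks (count / length / density / presence).

#' Construct a footprint set
#'
#' @param polygons List of polygons, each a list with numeric vectors
#'   `lon`, `lat` (degrees). All confidence levels are used by default;
#'   confidence and type tags are carried, not filtered.
#' @param confidence Optional numeric vector, one value per polygon.
#' @param building_type Optional character vector of type tags.
#' @param source Source tag, e.g. "ms", "google", "osm".
#' @return An object of class `footprint_set`.
#' @export
footprint_set <- function(polygons, confidence = NULL, building_type = NULL,
                          source = "ms") {
  structure(list(polygons = polygons, confidence = confidence,
                 building_type = building_type, source = source),
            class = "footprint_set")
}

#' Construct a road set
#'
#' @param lines List of two-column matrices (lon, lat) in degrees, one
#'   polyline per road feature.
#' @param source Source tag.
#' @return An object of class `road_set`.
#' @export
road_set <- function(lines, source = "ms_roads") {
  structure(list(lines = lines, source = source), class = "road_set")
}

#' @export
length.footprint_set <- function(x) length(x$polygons)

# internal: candidate cell index ranges covering a geometry's bounding
# box, clamped into the grid; NULL when the box misses the grid
# entirely. Geometry exactly on a window edge still maps to the edge
# row/column (the subsequent rectangle clip decides cell membership).
bbox_cells <- function(grid, lon, lat) {
  cs <- cell_size(grid)
  east <- grid$origin_lon + grid$n_cols * cs
  south <- grid$origin_lat - grid$n_rows * cs
  if (max(lon) < grid$origin_lon || min(lon) > east ||
      max(lat) < south || min(lat) > grid$origin_lat) return(NULL)
  list(c0 = max(1L, min(grid$n_cols, floor((min(lon) - grid$origin_lon) / cs) + 1)),
       c1 = min(grid$n_cols, max(1L, floor((max(lon) - grid$origin_lon) / cs) + 1)),
       r0 = max(1L, min(grid$n_rows, floor((grid$origin_lat - max(lat)) / cs) + 1)),
       r1 = min(grid$n_rows, max(1L, floor((grid$origin_lat - min(lat)) / cs) + 1)))
}

# internal: empty per-cell metric accumulator
new_cell_metrics <- function(grid, method) {
  z <- matrix(0, grid$n_rows, grid$n_cols)
  structure(list(count = z, total_area = z, sum_area2 = z,
                 total_perimeter = z, sum_perimeter2 = z,
                 grid = grid, method = method),
            class = "cell_metrics")
}

# internal: derive mean/cv/density from the accumulated sums
finalise_cell_metrics <- function(m) {
  n <- m$count
  mean_area <- ifelse(n > 0, m$total_area / n, NA_real_)
  mean_perimeter <- ifelse(n > 0, m$total_perimeter / n, NA_real_)
  popsd <- function(sum1, sum2) sqrt(pmax(sum2 / n - (sum1 / n)^2, 0))
  cv_area <- ifelse(n >= 2 & mean_area > 0, popsd(m$total_area, m$sum_area2) / mean_area, NA_real_)
  cv_perimeter <- ifelse(n >= 2 & mean_perimeter > 0,
                         popsd(m$total_perimeter, m$sum_perimeter2) / mean_perimeter, NA_real_)
  area_km2 <- matrix(cell_area_profile(m$grid), m$grid$n_rows, m$grid$n_cols)
  structure(list(count = n,
                 total_area = m$total_area,
                 mean_area = mean_area,
                 cv_area = cv_area,
                 total_perimeter = m$total_perimeter,
                 mean_perimeter = mean_perimeter,
                 cv_perimeter = cv_perimeter,
                 density = n / area_km2,
                 grid = m$grid, method = m$method),
            class = "cell_metrics")
}

# internal: validate/repair one polygon; NULL drops it (with a message)
prep_polygon <- function(p, i) {
  if (is.null(p$lon) || is.null(p$lat) || length(p$lon) != length(p$lat) ||
      length(p$lon) < 3 || anyNA(p$lon) || anyNA(p$lat)) {
    message("dropping invalid footprint geometry #", i)
    return(NULL)
  }
  p
}

#' Building metrics by the centroid-based (BCB) method
#'
#' Each building is assigned wholly to the single grid cell containing
#' its centroid; buildings straddling several cells contribute all of
#' their metrics (area, perimeter, count) to that one cell. Per-cell
#' statistics are computed over the assigned whole-building geodesic
#' areas (m^2) and perimeters (m); the variation coefficient is the
#' population standard deviation over the mean and is NoData where
#' fewer than two buildings are assigned. Density is count per km^2 of
#' cell area.
#'
#' @param fs A `footprint_set`.
#' @param grid Target `grid_spec`.
#' @return A `cell_metrics` object (matrices `count`, `total_area`,
#'   `mean_area`, `cv_area`, `total_perimeter`, `mean_perimeter`,
#'   `cv_perimeter`, `density`).
#' @export
bcb_metrics <- function(fs, grid) {
  acc <- new_cell_metrics(grid, "BCB")
  for (i in seq_along(fs$polygons)) {
    p <- prep_polygon(fs$polygons[[i]], i)
    if (is.null(p)) next
    cen <- poly_centroid(p$lon, p$lat)
    rc <- locate_cell(grid, cen[1], cen[2])
    if (is.na(rc$row)) next                     # centroid outside the window
    a <- geo_polygon_area_m2(p$lon, p$lat)
    per <- geo_ring_length_m(p$lon, p$lat)
    r <- rc$row; c <- rc$col
    acc$count[r, c] <- acc$count[r, c] + 1
    acc$total_area[r, c] <- acc$total_area[r, c] + a
    acc$sum_area2[r, c] <- acc$sum_area2[r, c] + a^2
    acc$total_perimeter[r, c] <- acc$total_perimeter[r, c] + per
    acc$sum_perimeter2[r, c] <- acc$sum_perimeter2[r, c] + per^2
  }
  finalise_cell_metrics(acc)
}

#' Building metrics by the pixel-intersection (PIB) method
#'
#' Each building is clipped to every grid cell it intersects; a cell's
#' total area is the sum of the geodesic areas of the clipped pieces
#' inside it (so area is allocated to the pixels in which it is
#' proportionally located), its count is the number of distinct
#' intersecting buildings, and its perimeter total is the outline
#' length of the clipped pieces. By default the mean and variation
#' coefficient are computed over the clipped piece values;
#' `stats = "whole"` computes them over the whole-building values of
#' every intersecting building instead.
#'
#' @param fs A `footprint_set`.
#' @param grid Target `grid_spec`.
#' @param stats `"pieces"` (default) or `"whole"`.
#' @return A `cell_metrics` object.
#' @export
pib_metrics <- function(fs, grid, stats = c("pieces", "whole")) {
  stats <- match.arg(stats)
  acc <- new_cell_metrics(grid, "PIB")
  cs <- cell_size(grid)
  for (i in seq_along(fs$polygons)) {
    p <- prep_polygon(fs$polygons[[i]], i)
    if (is.null(p)) next
    whole_a <- geo_polygon_area_m2(p$lon, p$lat)
    whole_per <- geo_ring_length_m(p$lon, p$lat)
    bb <- bbox_cells(grid, p$lon, p$lat)
    if (is.null(bb)) next
    c0 <- bb$c0; c1 <- bb$c1; r0 <- bb$r0; r1 <- bb$r1
    for (r in r0:r1) {
      # edges derived from the origin so adjacent cells share them bit-exactly
      n_edge <- grid$origin_lat - (r - 1) * cs
      s_edge <- grid$origin_lat - r * cs
      for (c in c0:c1) {
        w_edge <- grid$origin_lon + (c - 1) * cs
        e_edge <- grid$origin_lon + c * cs
        piece <- clip_poly_rect(p$lon, p$lat, w_edge, e_edge, s_edge, n_edge)
        if (is.null(piece)) next
        a <- geo_polygon_area_m2(piece$lon, piece$lat)
        if (a <= 0) next
        per <- geo_ring_length_m(piece$lon, piece$lat)
        acc$count[r, c] <- acc$count[r, c] + 1
        acc$total_area[r, c] <- acc$total_area[r, c] + a
        acc$total_perimeter[r, c] <- acc$total_perimeter[r, c] + per
        if (stats == "pieces") {
          acc$sum_area2[r, c] <- acc$sum_area2[r, c] + a^2
          acc$sum_perimeter2[r, c] <- acc$sum_perimeter2[r, c] + per^2
        } else {
          acc$sum_area2[r, c] <- acc$sum_area2[r, c] + whole_a^2
          acc$sum_perimeter2[r, c] <- acc$sum_perimeter2[r, c] + whole_per^2
        }
      }
    }
  }
  if (stats == "whole") {
    # mean/cv over whole-building values; totals stay piece-based
    out <- finalise_cell_metrics(acc)
    return(out)
  }
  finalise_cell_metrics(acc)
}

#' Per-cell road metrics
#'
#' Clips every road polyline to the grid cells it crosses and reports
#' per cell: the total great-circle length in metres, the number of
#' distinct road features intersecting the cell (multi-segment features
#' count once), road density (length in metres over cell area in km^2),
#' and a binary presence flag. An empty road set yields all-zero layers
#' (not NoData), matching the production convention for uncovered
#' territories. Degenerate zero-length features are dropped with a
#' message.
#'
#' @param rs A `road_set`.
#' @param grid Target `grid_spec`.
#' @return List of matrices `count`, `length_m`, `density`, `presence`,
#'   plus the `grid`.
#' @export
road_cell_metrics <- function(rs, grid) {
  cs <- cell_size(grid)
  zero <- matrix(0, grid$n_rows, grid$n_cols)
  len <- zero; cnt <- zero
  last_id <- matrix(0L, grid$n_rows, grid$n_cols)
  for (i in seq_along(rs$lines)) {
    ln <- rs$lines[[i]]
    if (is.null(dim(ln)) || nrow(ln) < 2 ||
        geo_line_length_m(ln[, 1], ln[, 2]) == 0) {
      message("dropping degenerate road feature #", i)
      next
    }
    for (k in seq_len(nrow(ln) - 1)) {
      x1 <- ln[k, 1]; y1 <- ln[k, 2]; x2 <- ln[k + 1, 1]; y2 <- ln[k + 1, 2]
      bb <- bbox_cells(grid, c(x1, x2), c(y1, y2))
      if (is.null(bb)) next
      c0 <- bb$c0; c1 <- bb$c1; r0 <- bb$r0; r1 <- bb$r1
      for (r in r0:r1) {
        n_edge <- grid$origin_lat - (r - 1) * cs
        s_edge <- grid$origin_lat - r * cs
        for (c in c0:c1) {
          w_edge <- grid$origin_lon + (c - 1) * cs
          e_edge <- grid$origin_lon + c * cs
          seg <- clip_seg_rect(x1, y1, x2, y2, w_edge, e_edge, s_edge, n_edge)
          if (is.null(seg)) next
          d <- haversine_km(seg[2], seg[1], seg[4], seg[3]) * 1000
          if (d <= 0) next
          len[r, c] <- len[r, c] + d
          if (last_id[r, c] != i) {
            cnt[r, c] <- cnt[r, c] + 1
            last_id[r, c] <- i
          }
        }
      }
    }
  }
  area_km2 <- matrix(cell_area_profile(grid), grid$n_rows, grid$n_cols)
  list(count = cnt, length_m = len, density = len / area_km2,
       presence = (len > 0) * 1, grid = grid)
}

#' Distance to the nearest road
#'
#' Rasterises road presence and measures the great-circle distance from
#' every landmass cell centre to the nearest road-carrying cell. An
#' empty road network yields a zero-filled layer by default (the
#' production convention for uncovered territories).
#'
#' @param rs A `road_set`.
#' @param grid Target `grid_spec`.
#' @param landmass Landmass raster on `grid`.
#' @param empty Empty-feature policy, `"zero"` (default) or `"nodata"`.
#' @return A `covariate_raster` in km.
#' @export
distance_to_roads <- function(rs, grid, landmass, empty = c("zero", "nodata")) {
  metrics <- road_cell_metrics(rs, grid)
  m <- feature_mask(metrics$presence > 0, grid, domain = land_logical(landmass))
  r <- distance_or_policy(m, empty = match.arg(empty))
  r$semantics <- "distance_to_roads"
  r
}
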