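# Distance-to-feature transforms: the shared kernel behind the land
# cover, protected-area, water, road and built-surface distance
# covariates. Distances are great-circle, cell centre to cell centre.

#' Great-circle (haversine) distance in km
#'
#' Vectorised haversine on the sphere with mean Earth radius 6371.0088 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees (vectors recycle).
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad / 2
  dlam <- (lon2 - lon1) * rad / 2
  a <- sin(dphi)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam)^2
  2 * EARTH_RADIUS_KM * asin(pmin(sqrt(a), 1))
}

#' Construct a binary feature mask
#'
#' @param feature Logical (or 0/1) matrix of feature cells.
#' @param grid A `grid_spec`.
#' @param domain Logical matrix of cells for which distances are
#'   reported (typically the landmass); default everywhere.
#' @return An object of class `feature_mask`.
#' @export
feature_mask <- function(feature, grid, domain = NULL) {
  if (!is.matrix(feature)) stop("feature must be a matrix")
  feature <- matrix(as.logical(feature), nrow = nrow(feature))
  feature[is.na(feature)] <- FALSE
  if (nrow(feature) != grid$n_rows || ncol(feature) != grid$n_cols)
    stop("feature dimensions do not match the grid")
  if (is.null(domain)) domain <- matrix(TRUE, grid$n_rows, grid$n_cols)
  domain <- matrix(as.logical(domain), nrow = nrow(domain))
  domain[is.na(domain)] <- FALSE
  structure(list(feature = feature, domain = domain, grid = grid),
            class = "feature_mask")
}

# internal: feature cells 8-adjacent to a non-feature cell (cells on the
# grid edge count as adjacent to the outside)
boundary_of <- function(feature) {
  nr <- nrow(feature); nc <- ncol(feature)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- feature
  non <- !pad
  adj <- matrix(FALSE, nr, nc)
  for (o in list(c(0, 0), c(0, 1), c(0, 2), c(1, 0), c(1, 2),
                 c(2, 0), c(2, 1), c(2, 2))) {
    adj <- adj | non[(1 + o[1]):(nr + o[1]), (1 + o[2]):(nc + o[2]), drop = FALSE]
  }
  feature & adj
}

# internal kernel: minimum great-circle distance (km) from every cell of
# `grid` flagged in `ask` (logical matrix) to any (frow, fcol) feature
# cell. Works row by row so only n_cols x n_feat temporaries exist.
min_distance_km <- function(grid, ask, frow, fcol) {
  rad <- pi / 180
  lat_f <- cell_center_lat(grid, frow) * rad
  lon_f <- cell_center_lon(grid, fcol) * rad
  cos_f <- cos(lat_f)
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  lon_c <- cell_center_lon(grid, seq_len(grid$n_cols)) * rad
  lat_c <- cell_center_lat(grid, seq_len(grid$n_rows)) * rad
  nf <- length(lat_f)
  chunk <- max(1L, floor(4e6 / nf))          # cap temporary size
  for (r in seq_len(grid$n_rows)) {
    cols <- which(ask[r, ])
    if (length(cols) == 0) next
    sdphi2 <- sin((lat_c[r] - lat_f) / 2)^2
    cc <- cos(lat_c[r]) * cos_f
    for (s in split(cols, ceiling(seq_along(cols) / chunk))) {
      # a-matrix: length(s) x nf
      sl <- sin(outer(lon_c[s], lon_f, `-`) / 2)^2
      a <- sweep(sl, 2, cc, `*`)
      a <- sweep(a, 2, sdphi2, `+`)
      amin <- do.call(pmin, c(as.data.frame(a), list(na.rm = FALSE)))
      out[r, s] <- 2 * EARTH_RADIUS_KM * asin(pmin(sqrt(amin), 1))
    }
  }
  out
}

#' Distance to the nearest feature cell
#'
#' For every domain cell, the minimum great-circle distance in km from
#' its centre to the centre of any feature cell. Cells inside features
#' report 0; cells outside the domain are NoData. The implementation
#' restricts the candidate set to feature-boundary cells (the nearest
#' feature cell seen from outside a feature is always on its boundary),
#' which is exact and keeps the scan small.
#'
#' @param mask A `feature_mask` with at least one feature cell.
#' @return A `covariate_raster` in km.
#' @export
distance_to_features <- function(mask) {
  if (!any(mask$feature)) stop("empty feature set: no feature cells")
  grid <- mask$grid
  cand <- boundary_of(mask$feature)
  idx <- which(cand, arr.ind = TRUE)
  ask <- mask$domain & !mask$feature
  out <- min_distance_km(grid, ask, idx[, 1], idx[, 2])
  out[mask$domain & mask$feature] <- 0
  covariate_raster(out, grid, units = "km", semantics = "distance_to_features")
}

#' Distance to the nearest feature boundary
#'
#' Restricts the feature set to its boundary cells (feature cells
#' 8-adjacent to a non-feature cell; the grid edge counts as outside)
#' before computing distances, so that interior cells of large features
#' report their distance to the edge. Boundary cells report 0.
#'
#' @param mask A `feature_mask` with at least one feature cell.
#' @return A `covariate_raster` in km.
#' @export
distance_to_boundary <- function(mask) {
  if (!any(mask$feature)) stop("empty feature set: no feature cells")
  grid <- mask$grid
  bnd <- boundary_of(mask$feature)
  idx <- which(bnd, arr.ind = TRUE)
  ask <- mask$domain & !bnd
  out <- min_distance_km(grid, ask, idx[, 1], idx[, 2])
  out[mask$domain & bnd] <- 0
  covariate_raster(out, grid, units = "km", semantics = "distance_to_boundary")
}

# internal: distance layer with the empty-feature policy applied.
# "nodata": all-NoData layer on the domain; "zero": zero-filled domain.
distance_or_policy <- function(mask, empty = c("nodata", "zero"),
                               boundary = FALSE) {
  empty <- match.arg(empty)
  if (any(mask$feature)) {
    if (boundary) distance_to_boundary(mask) else distance_to_features(mask)
  } else {
    v <- matrix(NA_real_, mask$grid$n_rows, mask$grid$n_cols)
    if (empty == "zero") v[mask$domain] <- 0
    covariate_raster(v, mask$grid, units = "km",
                     semantics = "distance_empty_feature_set")
  }
}
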