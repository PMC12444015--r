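# Geometry primitives for vector gridding. Polygons and polylines live
# in geographic coordinates (degrees); edges are straight lines in
# lon/lat space (plate carree), which matches how grid cells are defined
# and makes clipping by cell rectangles exact. Areas are evaluated on
# the sphere with a closed form that is exactly additive under such
# clipping; lengths are great-circle per edge.

#' Spherical area of a lon/lat polygon in square metres
#'
#' Treats edges as straight lines in lon/lat space and integrates the
#' spherical area element exactly: each edge contributes
#' `dlam * sin(phi_m) * sinc(dphi/2)` and the closed ring sums to the
#' signed area on the authalic sphere. Because cut points of a clip lie
#' on the straight edges, the area of a polygon equals the sum of the
#' areas of its rectangle-clipped pieces to machine precision.
#'
#' @param lon,lat Vertex coordinates in degrees (open or closed ring).
#' @return Area in m^2 (non-negative).
#' @export
geo_polygon_area_m2 <- function(lon, lat) {
  n <- length(lon)
  if (n < 3) return(0)
  if (lon[1] == lon[n] && lat[1] == lat[n]) { lon <- lon[-n]; lat <- lat[-n]; n <- n - 1 }
  if (n < 3) return(0)
  rad <- pi / 180
  lam <- lon * rad; phi <- lat * rad
  lam2 <- c(lam[-1], lam[1]); phi2 <- c(phi[-1], phi[1])
  h <- (phi2 - phi) / 2
  sinc <- ifelse(abs(h) < 1e-14, 1, sin(h) / h)
  terms <- (lam2 - lam) * sin((phi + phi2) / 2) * sinc
  abs(sum(terms)) * (EARTH_AUTHALIC_KM * 1000)^2
}

#' Great-circle length of a lon/lat polyline in metres
#'
#' @param lon,lat Vertex coordinates in degrees.
#' @return Sum of per-edge haversine distances, metres.
#' @export
geo_line_length_m <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(0)
  sum(haversine_km(lat[-n], lon[-n], lat[-1], lon[-1])) * 1000
}

#' Great-circle perimeter of a polygon in metres
#'
#' @param lon,lat Vertex coordinates in degrees (ring closed if needed).
#' @return Perimeter in metres.
#' @export
geo_ring_length_m <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(0)
  if (lon[1] != lon[n] || lat[1] != lat[n]) { lon <- c(lon, lon[1]); lat <- c(lat, lat[1]) }
  geo_line_length_m(lon, lat)
}

# internal: planar (lon/lat) shoelace centroid; falls back to the vertex
# mean for degenerate rings. Adequate for building-scale polygons.
poly_centroid <- function(lon, lat) {
  n <- length(lon)
  if (lon[1] == lon[n] && lat[1] == lat[n]) { lon <- lon[-n]; lat <- lat[-n]; n <- n - 1 }
  x2 <- c(lon[-1], lon[1]); y2 <- c(lat[-1], lat[1])
  cr <- lon * y2 - x2 * lat
  a <- sum(cr) / 2
  if (abs(a) < 1e-18) return(c(mean(lon), mean(lat)))
  c(sum((lon + x2) * cr) / (6 * a), sum((lat + y2) * cr) / (6 * a))
}

# internal: vectorised even-odd point-in-polygon (planar lon/lat)
point_in_poly <- function(px, py, vx, vy) {
  n <- length(vx)
  if (vx[1] == vx[n] && vy[1] == vy[n]) { vx <- vx[-n]; vy <- vy[-n]; n <- n - 1 }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

# internal: Sutherland-Hodgman clip of a polygon ring against the
# rectangle [w, e] x [s, n]. Returns list(lon, lat) or NULL if empty.
clip_poly_rect <- function(lon, lat, w, e, s, n) {
  np <- length(lon)
  if (lon[1] == lon[np] && lat[1] == lat[np]) { lon <- lon[-np]; lat <- lat[-np] }
  clip_one <- function(x, y, keep, tval) {
    # keep: function(x, y) -> logical inside; tval: interpolation solver
    nx <- numeric(0); ny <- numeric(0)
    m <- length(x)
    if (m == 0) return(list(x = nx, y = ny))
    inside <- keep(x, y)
    for (i in seq_len(m)) {
      j <- if (i == m) 1L else i + 1L
      if (inside[i]) { nx <- c(nx, x[i]); ny <- c(ny, y[i]) }
      if (inside[i] != inside[j]) {
        t <- tval(x[i], y[i], x[j], y[j])
        nx <- c(nx, x[i] + t * (x[j] - x[i]))
        ny <- c(ny, y[i] + t * (y[j] - y[i]))
      }
    }
    list(x = nx, y = ny)
  }
  p <- list(x = lon, y = lat)
  p <- clip_one(p$x, p$y, function(x, y) x >= w,
                function(x1, y1, x2, y2) (w - x1) / (x2 - x1))
  p <- clip_one(p$x, p$y, function(x, y) x <= e,
                function(x1, y1, x2, y2) (e - x1) / (x2 - x1))
  p <- clip_one(p$x, p$y, function(x, y) y >= s,
                function(x1, y1, x2, y2) (s - y1) / (y2 - y1))
  p <- clip_one(p$x, p$y, function(x, y) y <= n,
                function(x1, y1, x2, y2) (n - y1) / (y2 - y1))
  if (length(p$x) < 3) return(NULL)
  list(lon = p$x, lat = p$y)
}

# internal: Liang-Barsky clip of segment (x1,y1)-(x2,y2) to the
# rectangle [w,e] x [s,n]. Returns c(x1, y1, x2, y2) or NULL.
clip_seg_rect <- function(x1, y1, x2, y2, w, e, s, n) {
  dx <- x2 - x1; dy <- y2 - y1
  p <- c(-dx, dx, -dy, dy)
  q <- c(x1 - w, e - x1, y1 - s, n - y1)
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    if (p[k] == 0) {
      if (q[k] < 0) return(NULL)
    } else {
      t <- q[k] / p[k]
      if (p[k] < 0) { if (t > t1) return(NULL); if (t > t0) t0 <- t }
      else          { if (t < t0) return(NULL); if (t < t1) t1 <- t }
    }
  }
  c(x1 + t0 * dx, y1 + t0 * dy, x1 + t1 * dx, y1 + t1 * dy)
}
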