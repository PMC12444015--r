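# Shared helpers: small lattice windows and independent oracles used
# across the suite. Oracles are deliberately written as plain scans or
# calls into geosphere so they share no code path with the package
# implementations they check.

# an n x n window of the global 3" lattice near the equator
tiny_grid <- function(n = 20, origin_lon = 30, origin_lat = 0.05,
                      res_arcsec = 3) {
  cs <- res_arcsec / 3600
  make_grid_spec(origin_lon, origin_lat - n * cs, origin_lon + n * cs,
                 origin_lat, res_arcsec)
}

# brute-force oracle: per-cell minimum over ALL feature cells via
# geosphere's haversine (mean radius 6371.0088 km)
oracle_min_distance <- function(grid, feature, domain = NULL) {
  if (is.null(domain)) domain <- matrix(TRUE, nrow(feature), ncol(feature))
  lon <- cell_center_lon(grid, seq_len(grid$n_cols))
  lat <- cell_center_lat(grid, seq_len(grid$n_rows))
  fi <- which(feature, arr.ind = TRUE)
  fpts <- cbind(lon[fi[, 2]], lat[fi[, 1]])
  out <- matrix(NA_real_, nrow(feature), ncol(feature))
  for (i in seq_len(nrow(feature))) {
    for (j in seq_len(ncol(feature))) {
      if (!domain[i, j]) next
      out[i, j] <- min(geosphere::distHaversine(c(lon[j], lat[i]), fpts,
                                                r = 6371008.8)) / 1000
    }
  }
  out
}

# step-by-step simulation oracle for the radiance outlier filter,
# recomputing the population sd from scratch each iteration
oracle_filter <- function(obs, tol = 0.2) {
  popsd <- function(x) sqrt(mean((x - mean(x))^2))
  if (length(obs) < 3) return(list(retained = obs, cap = max(obs), n_removed = 0L))
  x <- obs
  sd_prev <- popsd(x)
  removed <- 0L
  while (length(x) > 1) {
    imax <- which.max(x)
    rest <- x[-imax]
    sd_new <- popsd(rest)
    if (abs(sd_prev - sd_new) < tol) break
    x <- rest
    sd_prev <- sd_new
    removed <- removed + 1L
  }
  list(retained = sort(x), cap = max(x), n_removed = removed)
}

# random sparse feature matrix with at least one feature cell
random_feature <- function(n, p = 0.02, seed = 1) {
  set.seed(seed)
  f <- matrix(runif(n * n) < p, n, n)
  if (!any(f)) f[sample(n, 1), sample(n, 1)] <- TRUE
  f
}

# a rectangle footprint in degrees (axis-aligned)
deg_rect <- function(w, s, e, n) {
  list(lon = c(w, e, e, w), lat = c(s, s, n, n))
}
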