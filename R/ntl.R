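# Nighttime-lights standardisation and the iterative outlier filter
# applied around gas-flare and volcano sites.

# internal: population standard deviation from running sums
popsd_sums <- function(s1, s2, n) sqrt(max(s2 / n - (s1 / n)^2, 0))

#' Iterative largest-observation outlier filter
#'
#' Starting from the full list, the filter repeatedly removes the
#' largest observation and recomputes the (population) standard
#' deviation of the remainder, comparing it with the previous
#' iteration's value. It stops when the standard deviations converge,
#' defined as an absolute difference of less than `tol` (default 0.2);
#' the observation removed in the converged iteration is restored, since
#' its removal changed nothing material. Lists with fewer than three
#' observations are returned unchanged.
#'
#' @param obs Numeric vector of radiance observations.
#' @param tol Convergence threshold on the std difference; default 0.2.
#' @return A list of class `filter_result` with `retained` (values kept),
#'   `cap` (max of retained), `n_removed`, and `trace` (the per-iteration
#'   standard deviations, starting with the full list's).
#' @export
iterative_outlier_filter <- function(obs, tol = 0.2) {
  if (length(obs) < 1) stop("at least one observation required")
  if (length(obs) < 3) {
    return(structure(list(retained = obs, cap = max(obs), n_removed = 0L,
                          trace = numeric(0)), class = "filter_result"))
  }
  x <- sort(obs)                       # ascending; current max is the tail
  n <- length(x)
  s1 <- sum(x); s2 <- sum(x^2)
  sd_prev <- popsd_sums(s1, s2, n)
  trace <- sd_prev
  removed <- 0L
  while (n > 1) {
    mx <- x[n]
    s1n <- s1 - mx; s2n <- s2 - mx^2
    sd_new <- popsd_sums(s1n, s2n, n - 1)
    trace <- c(trace, sd_new)
    if (abs(sd_prev - sd_new) < tol) break     # converged: restore mx
    x <- x[-n]; n <- n - 1L
    s1 <- s1n; s2 <- s2n
    sd_prev <- sd_new
    removed <- removed + 1L
  }
  structure(list(retained = x, cap = max(x), n_removed = removed,
                 trace = trace), class = "filter_result")
}

#' Apply the outlier filter around flare/volcano sites
#'
#' For each site (in input order), the valid radiance observations in
#' the square window of the given cell radius around the site's cell are
#' passed through [iterative_outlier_filter()]; window values above the
#' resulting cap are then clipped to the cap (default) or set to NoData.
#' Cells outside every window are untouched; overlapping windows are
#' processed in site order with caps applied cumulatively. Sites outside
#' the grid are dropped with a message.
#'
#' @param g Radiance `covariate_raster`.
#' @param sites Data frame with columns `lon`, `lat` (and optionally
#'   `kind` in \{"flare", "volcano"\}).
#' @param window_radius_cells Half-width of the square window in cells
#'   (>= 1); default 10.
#' @param tol Convergence threshold passed to the filter.
#' @param action `"cap"` (clip to the retained maximum, default) or
#'   `"nodata"` (remove values above the cap).
#' @return The filtered `covariate_raster`; the per-site filter results
#'   are attached as attribute `"filter_trace"`.
#' @export
apply_site_filter <- function(g, sites, window_radius_cells = 10, tol = 0.2,
                              action = c("cap", "nodata")) {
  action <- match.arg(action)
  if (window_radius_cells < 1) stop("window_radius_cells must be >= 1")
  v <- g$values
  traces <- list()
  if (nrow(sites) > 0) {
    for (i in seq_len(nrow(sites))) {
      rc <- locate_cell(g$grid, sites$lon[i], sites$lat[i])
      if (is.na(rc$row)) {
        message("dropping site #", i, " outside the grid extent")
        next
      }
      rows <- max(1, rc$row - window_radius_cells):min(g$grid$n_rows, rc$row + window_radius_cells)
      cols <- max(1, rc$col - window_radius_cells):min(g$grid$n_cols, rc$col + window_radius_cells)
      win <- v[rows, cols, drop = FALSE]
      vals <- win[!is.na(win)]
      if (length(vals) < 1) next
      res <- iterative_outlier_filter(vals, tol)
      traces[[length(traces) + 1]] <- res
      over <- !is.na(win) & win > res$cap
      if (any(over)) {
        win[over] <- if (action == "cap") res$cap else NA_real_
        v[rows, cols] <- win
      }
    }
  }
  out <- raster_like(g, v)
  attr(out, "filter_trace") <- traces
  out
}

#' Standardise an annual radiance grid to the master grid
#'
#' Bilinear resampling to the target grid, zero-filling of NoData land
#' cells at high northern latitudes (cell centres between 75 N and 84 N,
#' above the source product's coverage), and removal of everything
#' outside the landmass (ocean cells become NoData).
#'
#' @param src Source radiance `covariate_raster` (nW/cm2/sr).
#' @param grid Target `grid_spec`.
#' @param landmass Landmass raster on `grid`.
#' @return A `covariate_raster` on the master grid.
#' @export
standardise_radiance <- function(src, grid, landmass) {
  r <- resample_to_grid(src, grid, "bilinear")
  v <- r$values
  land <- land_logical(landmass)
  lat <- cell_center_lat(grid, seq_len(grid$n_rows))
  polar <- matrix(lat >= 75 & lat <= 84, grid$n_rows, grid$n_cols)
  v[land & polar & is.na(v)] <- 0
  v[!land] <- NA_real_
  covariate_raster(v, grid, units = "nW/cm2/sr", year = src$year,
                   semantics = "ntl_radiance")
}
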