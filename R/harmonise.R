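# Generic raster standardisation: resampling, mosaicking, coastal gap
# filling, climate aggregation and slope derivation.

#' Resample a raster onto a target grid
#'
#' Three methods cover the pipeline's needs: `bilinear` interpolates from
#' the four enclosing source cell centres (continuous data), `nearest`
#' copies the source cell containing each target centre (categorical
#' data), and `fraction_average` aggregates a finer binary/fractional
#' source by exact area averaging (requires an integer subdivision).
#'
#' @param src Source `covariate_raster` (same geographic CRS).
#' @param grid Target `grid_spec`.
#' @param method One of `"bilinear"`, `"nearest"`, `"fraction_average"`.
#' @return A `covariate_raster` aligned to `grid`.
#' @export
resample_to_grid <- function(src, grid,
                             method = c("bilinear", "nearest", "fraction_average")) {
  method <- match.arg(method)
  if (method == "bilinear" && isTRUE(src$categorical))
    stop("bilinear resampling is not defined for categorical rasters")
  if (same_grid(src$grid, grid))
    return(raster_like(src, src$values))
  if (method == "fraction_average") {
    f <- subdivision_factor(src$grid, grid)
    return(covariate_raster(block_aggregate(src$values, f, mean), grid,
                            units = src$units, year = src$year,
                            semantics = src$semantics))
  }
  sg <- src$grid
  cs_s <- cell_size(sg)
  lon_t <- cell_center_lon(grid, seq_len(grid$n_cols))
  lat_t <- cell_center_lat(grid, seq_len(grid$n_rows))
  if (method == "nearest") {
    col_s <- pmin(pmax(floor((lon_t - sg$origin_lon) / cs_s) + 1, 1), sg$n_cols)
    row_s <- pmin(pmax(floor((sg$origin_lat - lat_t) / cs_s) + 1, 1), sg$n_rows)
    out <- src$values[row_s, col_s, drop = FALSE]
    return(covariate_raster(out, grid, units = src$units, year = src$year,
                            semantics = src$semantics,
                            categorical = src$categorical))
  }
  # bilinear on cell-centre coordinates, clamped at the source margins
  u <- (lon_t - sg$origin_lon) / cs_s - 0.5        # 0-based centre coordinate
  v <- (sg$origin_lat - lat_t) / cs_s - 0.5
  u <- pmin(pmax(u, 0), sg$n_cols - 1)
  v <- pmin(pmax(v, 0), sg$n_rows - 1)
  j0 <- pmin(floor(u), sg$n_cols - 2); wu <- u - j0
  i0 <- pmin(floor(v), sg$n_rows - 2); wv <- v - i0
  if (sg$n_cols == 1) { j0 <- rep(0, length(u)); wu <- rep(0, length(u)) }
  if (sg$n_rows == 1) { i0 <- rep(0, length(v)); wv <- rep(0, length(v)) }
  V <- src$values
  i0 <- i0 + 1; j0 <- j0 + 1                        # back to 1-based
  W_v <- matrix(wv, grid$n_rows, grid$n_cols)
  W_u <- matrix(wu, grid$n_rows, grid$n_cols, byrow = TRUE)
  q11 <- V[i0, j0, drop = FALSE]
  q12 <- V[i0, pmin(j0 + 1, sg$n_cols), drop = FALSE]
  q21 <- V[pmin(i0 + 1, sg$n_rows), j0, drop = FALSE]
  q22 <- V[pmin(i0 + 1, sg$n_rows), pmin(j0 + 1, sg$n_cols), drop = FALSE]
  out <- (1 - W_v) * ((1 - W_u) * q11 + W_u * q12) +
    W_v * ((1 - W_u) * q21 + W_u * q22)
  covariate_raster(out, grid, units = src$units, year = src$year,
                   semantics = src$semantics)
}

#' Mosaic tiles into a single raster
#'
#' Tiles must share resolution and sit on the same lattice. The union
#' extent is assembled; where tiles overlap the earlier tile in the list
#' takes precedence (a documented, deterministic rule). Cells covered by
#' no tile are NoData.
#'
#' @param tiles List of `covariate_raster` objects.
#' @return A `covariate_raster` covering the union extent.
#' @export
mosaic <- function(tiles) {
  if (length(tiles) == 0) stop("no tiles supplied")
  if (length(tiles) == 1) return(tiles[[1]])
  res <- vapply(tiles, function(t) t$grid$res_arcsec, numeric(1))
  if (length(unique(res)) != 1) stop("tiles differ in resolution")
  w <- min(vapply(tiles, function(t) t$grid$origin_lon, numeric(1)))
  n <- max(vapply(tiles, function(t) t$grid$origin_lat, numeric(1)))
  e <- max(vapply(tiles, function(t) t$grid$origin_lon +
                    t$grid$n_cols * cell_size(t$grid), numeric(1)))
  s <- min(vapply(tiles, function(t) t$grid$origin_lat -
                    t$grid$n_rows * cell_size(t$grid), numeric(1)))
  grid <- make_grid_spec(w, s, e, n, res[1])
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  cs <- cell_size(grid)
  for (t in tiles) {
    r0 <- round((grid$origin_lat - t$grid$origin_lat) / cs)
    c0 <- round((t$grid$origin_lon - grid$origin_lon) / cs)
    rows <- (r0 + 1):(r0 + t$grid$n_rows)
    cols <- (c0 + 1):(c0 + t$grid$n_cols)
    blank <- is.na(out[rows, cols, drop = FALSE])
    sub <- out[rows, cols, drop = FALSE]
    sub[blank] <- t$values[blank]
    out[rows, cols] <- sub
  }
  covariate_raster(out, grid, units = tiles[[1]]$units,
                   year = tiles[[1]]$year, semantics = tiles[[1]]$semantics,
                   categorical = tiles[[1]]$categorical)
}

# internal: 8-neighbour shifted copies of a matrix (outside = NA)
shift8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(NA_real_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  lapply(list(c(0, 0), c(0, 1), c(0, 2), c(1, 0), c(1, 2),
              c(2, 0), c(2, 1), c(2, 2)),
         function(o) pad[(1 + o[1]):(nr + o[1]), (1 + o[2]):(nc + o[2]), drop = FALSE])
}

#' Fill coastal gaps with the neighbouring mean
#'
#' Land cells that are NoData in a continuous raster (coastline
#' inconsistencies between source and master grid) are filled
#' iteratively: each pass assigns to every unfilled land cell the mean
#' of its valid 8-neighbours (simultaneous/Jacobi update), repeating
#' until no unfilled land cell remains. Ocean cells stay NoData; valid
#' cells are never modified.
#'
#' @param r Continuous `covariate_raster`.
#' @param landmass Landmass raster on the same grid.
#' @return Filled `covariate_raster`.
#' @export
fill_coastal_gaps_mean <- function(r, landmass) {
  fill_gaps_impl(r, landmass, mode = "mean")
}

#' Fill coastal gaps with the neighbouring majority class
#'
#' Categorical variant of [fill_coastal_gaps_mean()]: unfilled land cells
#' take the modal value of their valid 8-neighbours; ties are broken by
#' the smallest class code (deterministic, documented).
#'
#' @inheritParams fill_coastal_gaps_mean
#' @return Filled categorical `covariate_raster`.
#' @export
fill_coastal_gaps_majority <- function(r, landmass) {
  fill_gaps_impl(r, landmass, mode = "majority")
}

fill_gaps_impl <- function(r, landmass, mode) {
  if (!same_grid(r$grid, landmass$grid)) stop("landmass grid mismatch")
  v <- r$values
  land <- land_logical(landmass)
  repeat {
    unfilled <- land & is.na(v)
    if (!any(unfilled)) break
    nb <- shift8(v)
    if (mode == "mean") {
      cnt <- Reduce(`+`, lapply(nb, function(x) !is.na(x)))
      tot <- Reduce(`+`, lapply(nb, function(x) ifelse(is.na(x), 0, x)))
      can <- unfilled & cnt > 0
      if (!any(can))
        stop("unfillable gap: a landmass component with no valid cells (",
             sum(unfilled), " cells, first at index ", which(unfilled)[1], ")")
      v[can] <- tot[can] / cnt[can]
    } else {
      idx <- which(unfilled)
      vals <- vapply(idx, function(k) {
        nbv <- vapply(nb, function(x) x[k], numeric(1))
        nbv <- nbv[!is.na(nbv)]
        if (length(nbv) == 0) return(NA_real_)
        tab <- table(nbv)
        cand <- as.numeric(names(tab)[tab == max(tab)])
        min(cand)                       # tie-break: smallest class code
      }, numeric(1))
      if (all(is.na(vals)))
        stop("unfillable gap: a landmass component with no valid cells (",
             sum(unfilled), " cells, first at index ", idx[1], ")")
      v[idx] <- vals
    }
  }
  v[!land] <- NA_real_
  raster_like(r, v)
}

#' Annual precipitation from monthly rasters
#'
#' Sums exactly 12 co-registered monthly rasters of one year, divides by
#' 12, and applies the catalogue scaling factor (default 10; the released
#' covariate stores mm x 10). Cells missing in any month are NoData.
#'
#' @param monthly List of 12 `covariate_raster` objects (mm).
#' @param scale Scaling factor applied to the monthly mean; default 10.
#' @return A `covariate_raster` in scaled mm.
#' @export
annual_precipitation <- function(monthly, scale = 10) {
  if (length(monthly) != 12)
    stop("annual precipitation requires exactly 12 monthly rasters (got ",
         length(monthly), ")")
  g <- monthly[[1]]$grid
  for (m in monthly) if (!same_grid(m$grid, g)) stop("monthly rasters not co-registered")
  tot <- Reduce(`+`, lapply(monthly, function(m) m$values))
  covariate_raster(tot / 12 * scale, g, units = "mm",
                   year = monthly[[1]]$year, semantics = "annual_precipitation")
}

#' Annual mean temperature from monthly composites
#'
#' Per-cell arithmetic mean over the available (non-NoData) months; a
#' cell with no valid month is NoData.
#'
#' @param monthly Non-empty list of monthly `covariate_raster`s (Kelvin).
#' @return A `covariate_raster` in Kelvin.
#' @export
annual_temperature <- function(monthly) {
  if (length(monthly) < 1) stop("at least one monthly composite required")
  g <- monthly[[1]]$grid
  for (m in monthly) if (!same_grid(m$grid, g)) stop("monthly rasters not co-registered")
  tot <- Reduce(`+`, lapply(monthly, function(m) ifelse(is.na(m$values), 0, m$values)))
  cnt <- Reduce(`+`, lapply(monthly, function(m) !is.na(m$values)))
  out <- ifelse(cnt > 0, tot / cnt, NA_real_)
  covariate_raster(matrix(out, nrow = g$n_rows), g, units = "K",
                   year = monthly[[1]]$year, semantics = "annual_temperature")
}

#' Topographic slope from an elevation raster
#'
#' Slope in degrees via the Horn 3x3 finite-difference operator on
#' geographic spacing: the east-west metre spacing is scaled by the
#' cosine of each row's latitude, the north-south spacing is constant.
#' Edge cells use one-sided differences.
#'
#' @param dem Elevation `covariate_raster` in metres on the master grid.
#' @return A `covariate_raster` of slope in degrees, `[0, 90)`.
#' @export
slope_from_dem <- function(dem) {
  v <- dem$values
  if (all(is.na(v))) stop("all-NoData elevation raster")
  g <- dem$grid
  nr <- nrow(v); nc <- ncol(v)
  cs_rad <- cell_size(g) * pi / 180
  dy <- EARTH_RADIUS_KM * 1000 * cs_rad                       # metres per row step
  lat <- cell_center_lat(g, seq_len(nr)) * pi / 180
  dx <- dy * cos(lat)                                          # metres per col step
  # central differences with one-sided fallback at edges
  east <- v[, c(2:nc, nc), drop = FALSE]
  west <- v[, c(1, 1:(nc - 1)), drop = FALSE]
  span_x <- matrix(2, nr, nc); span_x[, c(1, nc)] <- 1
  gx <- (east - west) / (span_x * dx)                          # recycles dx by row
  north <- v[c(1, 1:(nr - 1)), , drop = FALSE]
  south <- v[c(2:nr, nr), , drop = FALSE]
  span_y <- matrix(2, nr, nc); span_y[c(1, nr), ] <- 1
  gy <- (north - south) / (span_y * dy)
  # Horn smoothing: weight 1-2-1 across the transverse direction
  smooth_rows <- function(m) (m[c(1, 1:(nr - 1)), , drop = FALSE] + 2 * m +
                                m[c(2:nr, nr), , drop = FALSE]) / 4
  smooth_cols <- function(m) (m[, c(1, 1:(nc - 1)), drop = FALSE] + 2 * m +
                                m[, c(2:nc, nc), drop = FALSE]) / 4
  gx <- smooth_rows(gx)
  gy <- smooth_cols(gy)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  covariate_raster(slope, g, units = "degrees", year = dem$year,
                   semantics = "slope")
}
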