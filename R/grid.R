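# Master-grid geometry: the 3 arc-second WGS84 lattice every covariate
# aligns to. Cell size is carried as an exact arc-second integer so that
# edge positions are derived by integer arithmetic (no float drift over
# the 432000 columns of the global grid).

# Mean Earth radius (km), used for all great-circle distances.
EARTH_RADIUS_KM <- 6371.0088
# Authalic (equal-area) radius (km), used for spherical cell/polygon areas.
EARTH_AUTHALIC_KM <- 6371.0072
# Reserved sentinel for cells outside the valid domain.
NODATA_SENTINEL <- -99999

# Anchor of the global lattice: all grid edges are integer multiples of
# the resolution away from (-180 E, 84 N).
LATTICE_ANCHOR_LON <- -180
LATTICE_ANCHOR_LAT <- 84

#' Construct a grid specification
#'
#' A `grid_spec` describes a window of the global 3 arc-second master
#' lattice: its origin (west edge, north edge), resolution in arc-seconds,
#' and row/column counts. Edges are snapped outward to the global lattice
#' anchored at (-180, 84) so that every window tiles the same lattice and
#' windows of different extents stay mutually aligned.
#'
#' @param west,south,east,north Extent edges in decimal degrees.
#' @param res_arcsec Cell size in arc-seconds; must divide 3600. Default 3.
#' @return An object of class `grid_spec` with fields `origin_lon`,
#'   `origin_lat`, `res_arcsec`, `n_rows`, `n_cols`, `nodata`, `crs`.
#' @examples
#' make_grid_spec(0, 0, 1, 1)          # 1200 x 1200 cells at 3 arc-seconds
#' global_grid_spec()$n_cols            # 432000
#' @export
make_grid_spec <- function(west, south, east, north, res_arcsec = 3) {
  if (!is.numeric(res_arcsec) || length(res_arcsec) != 1 || res_arcsec <= 0)
    stop("res_arcsec must be a positive scalar")
  per_deg_chk <- 3600 / res_arcsec
  if (abs(per_deg_chk - round(per_deg_chk)) > 1e-9)
    stop("res_arcsec must divide 3600 (got ", res_arcsec, ")")
  if (east <= west) stop("inverted extent: east <= west")
  if (north <= south) stop("inverted extent: north <= south")
  per_deg <- 3600 / res_arcsec
  # snap outward onto the global lattice (integer steps from the anchor)
  kw <- floor((west - LATTICE_ANCHOR_LON) * per_deg + 1e-9)
  ke <- ceiling((east - LATTICE_ANCHOR_LON) * per_deg - 1e-9)
  kn <- floor((LATTICE_ANCHOR_LAT - north) * per_deg + 1e-9)
  ks <- ceiling((LATTICE_ANCHOR_LAT - south) * per_deg - 1e-9)
  spec <- structure(list(
    origin_lon = LATTICE_ANCHOR_LON + kw / per_deg,
    origin_lat = LATTICE_ANCHOR_LAT - kn / per_deg,
    res_arcsec = res_arcsec,
    n_rows = as.integer(ks - kn),
    n_cols = as.integer(ke - kw),
    nodata = NODATA_SENTINEL,
    crs = "EPSG:4326"
  ), class = "grid_spec")
  stopifnot(spec$n_rows >= 1, spec$n_cols >= 1)
  spec
}

#' The default global master grid
#'
#' 3 arc-seconds, spanning 180 W to 180 E and 84 N down to approximately
#' 60 S (the printed southern-edge constant is 59.9999994 S; on the exact
#' rational lattice the 172800th row edge sits at -60 exactly, and the
#' printed value is the truncated-decimal display of the same edge, see
#' [grid_constants()]).
#'
#' @return A `grid_spec` of 172800 rows by 432000 columns.
#' @export
global_grid_spec <- function() {
  make_grid_spec(-180, -59.9999994, 180, 84, 3)
}

#' Published display constants of a grid
#'
#' Reports the grid constants in the convention they are published in:
#' the cell size printed to 11 decimal places, and the southern edge as
#' derived by truncated-decimal arithmetic (north edge minus rows times
#' the printed cell size, rounded to 7 decimals) - for the default global
#' grid this yields 0.00083333333 and -59.9999994.
#'
#' @param spec A `grid_spec`.
#' @return List with `cell_size_deg` (exact), `cell_size_printed` (11 d.p.
#'   string), `south_edge_printed`, `nodata`, `crs`, `n_rows`, `n_cols`.
#' @export
grid_constants <- function(spec) {
  cs <- cell_size(spec)
  printed <- trunc(cs * 1e11) / 1e11
  list(
    cell_size_deg = cs,
    cell_size_printed = sprintf("%.11f", printed),
    south_edge_printed = round(spec$origin_lat - spec$n_rows * printed, 7),
    nodata = spec$nodata,
    crs = spec$crs,
    n_rows = spec$n_rows,
    n_cols = spec$n_cols
  )
}

#' Cell size of a grid in decimal degrees
#' @param spec A `grid_spec`.
#' @return Cell size in degrees (`res_arcsec / 3600`).
#' @export
cell_size <- function(spec) spec$res_arcsec / 3600

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "grid_spec: %d x %d cells at %s\" (%.11f deg), origin (%.7f, %.7f), %s\n",
    x$n_rows, x$n_cols, format(x$res_arcsec), cell_size(x),
    x$origin_lon, x$origin_lat, x$crs))
  invisible(x)
}

#' Cell-centre coordinates
#'
#' @param spec A `grid_spec`.
#' @param rows,cols Row / column indices (1-based; row 1 is northernmost).
#' @return Numeric vector of longitudes / latitudes in degrees.
#' @export
cell_center_lon <- function(spec, cols) spec$origin_lon + (cols - 0.5) * cell_size(spec)

#' @rdname cell_center_lon
#' @export
cell_center_lat <- function(spec, rows) spec$origin_lat - (rows - 0.5) * cell_size(spec)

#' Locate points on the grid (half-open cell convention)
#'
#' Cells are half-open: a point on a cell's west or north edge belongs to
#' that cell. Points outside the grid get NA.
#'
#' @param spec A `grid_spec`.
#' @param lon,lat Point coordinates in degrees.
#' @return List with integer vectors `row`, `col` (NA outside the grid).
#' @export
locate_cell <- function(spec, lon, lat) {
  cs <- cell_size(spec)
  col <- floor((lon - spec$origin_lon) / cs) + 1
  row <- floor((spec$origin_lat - lat) / cs) + 1
  bad <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Do two grids describe the same lattice window?
#' @param a,b `grid_spec` objects.
#' @return Logical.
#' @export
same_grid <- function(a, b) {
  isTRUE(all.equal(a$origin_lon, b$origin_lon)) &&
    isTRUE(all.equal(a$origin_lat, b$origin_lat)) &&
    a$res_arcsec == b$res_arcsec &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Integer subdivision factor between a fine and a coarse grid
#'
#' Errors unless the fine grid covers the same extent as the coarse grid
#' and its resolution is an exact integer subdivision.
#'
#' @param fine,coarse `grid_spec` objects.
#' @return The integer factor (coarse cell edge / fine cell edge).
#' @export
subdivision_factor <- function(fine, coarse) {
  f <- coarse$res_arcsec / fine$res_arcsec
  if (abs(f - round(f)) > 1e-9)
    stop("fine grid is not an integer subdivision of the target resolution")
  f <- round(f)
  ok <- isTRUE(all.equal(fine$origin_lon, coarse$origin_lon)) &&
    isTRUE(all.equal(fine$origin_lat, coarse$origin_lat)) &&
    fine$n_rows == coarse$n_rows * f && fine$n_cols == coarse$n_cols * f
  if (!ok) stop("fine raster is not aligned with the target lattice window")
  as.integer(f)
}

#' Per-row geodesic cell areas
#'
#' Area in km^2 of the spherical quadrangle bounded by each row's edge
#' parallels and one cell's meridians: `R_a^2 * dlam * (sin phi_n - sin
#' phi_s)` with the authalic radius. All cells in a row share the same
#' area on a geographic grid.
#'
#' @param spec A `grid_spec`.
#' @return Numeric vector of length `n_rows` (km^2), north to south.
#' @export
cell_area_profile <- function(spec) {
  cs <- cell_size(spec)
  lat_n <- (spec$origin_lat - (seq_len(spec$n_rows) - 1) * cs) * pi / 180
  lat_s <- lat_n - cs * pi / 180
  EARTH_AUTHALIC_KM^2 * (cs * pi / 180) * (sin(lat_n) - sin(lat_s))
}

# ---------------------------------------------------------------------------
# Covariate raster container: a grid-aligned band with semantics. NoData is
# held as NA internally; the -99999 sentinel only appears on disk.

#' Construct a covariate raster
#'
#' @param values Numeric matrix, `n_rows` x `n_cols`, row 1 northernmost.
#'   NA marks NoData.
#' @param grid A `grid_spec`.
#' @param units Unit string from the covariate catalogue (km, m, mm, ...).
#' @param year Reference year, or NULL for time-invariant layers.
#' @param semantics Catalogue key describing the layer.
#' @param categorical Logical; TRUE for class-coded rasters.
#' @return An object of class `covariate_raster`.
#' @export
covariate_raster <- function(values, grid, units = "", year = NULL,
                             semantics = "", categorical = FALSE) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("values dimensions do not match the grid (",
         nrow(values), "x", ncol(values), " vs ",
         grid$n_rows, "x", grid$n_cols, ")")
  storage.mode(values) <- "double"
  structure(list(values = values, grid = grid, units = units, year = year,
                 semantics = semantics, categorical = categorical),
            class = "covariate_raster")
}

#' @export
print.covariate_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("covariate_raster '%s'%s [%s]: %d x %d, %d valid cells\n",
              x$semantics,
              if (is.null(x$year)) "" else paste0(" (", x$year, ")"),
              x$units, nrow(v), ncol(v), sum(!is.na(v))))
  invisible(x)
}

# internal: copy a raster with new values, keeping metadata
raster_like <- function(r, values, ...) {
  dots <- list(...)
  out <- covariate_raster(values, r$grid,
                          units = if (is.null(dots$units)) r$units else dots$units,
                          year = if (is.null(dots$year)) r$year else dots$year,
                          semantics = if (is.null(dots$semantics)) r$semantics else dots$semantics,
                          categorical = if (is.null(dots$categorical)) r$categorical else dots$categorical)
  out
}

# ---------------------------------------------------------------------------
# Landmask construction

#' Terrestrial fraction of each master-grid cell
#'
#' Aggregates a finer binary/categorical land-cover raster to the target
#' grid by exact cell counting: each target cell holds the fraction of
#' fine cells inside it whose class code is in the terrestrial set.
#'
#' @param fine_landcover A `covariate_raster` on an integer-subdivision
#'   grid of `grid` (same extent).
#' @param terrestrial_codes Numeric vector of class codes counted as land.
#' @param grid Target `grid_spec`.
#' @return A `covariate_raster` of fractions in `[0, 1]`.
#' @export
terrestrial_fraction <- function(fine_landcover, terrestrial_codes, grid) {
  f <- subdivision_factor(fine_landcover$grid, grid)
  member <- matrix(as.numeric(fine_landcover$values %in% terrestrial_codes),
                   nrow = nrow(fine_landcover$values))
  covariate_raster(block_aggregate(member, f, mean), grid,
                   units = "fraction", semantics = "terrestrial_fraction")
}

# internal: aggregate an (f*R) x (f*C) matrix into R x C blocks with `fun`
block_aggregate <- function(m, f, fun = mean) {
  R <- nrow(m) / f; C <- ncol(m) / f
  stopifnot(R == round(R), C == round(C))
  # sum over f x f blocks via two matrix multiplications (fast, exact)
  if (identical(fun, mean) || identical(fun, sum)) {
    rg <- matrix(0, R, nrow(m)); rg[cbind(rep(seq_len(R), each = f), seq_len(nrow(m)))] <- 1
    cg <- matrix(0, ncol(m), C); cg[cbind(seq_len(ncol(m)), rep(seq_len(C), each = f))] <- 1
    s <- rg %*% m %*% cg
    if (identical(fun, mean)) s / f^2 else s
  } else {
    out <- matrix(NA_real_, R, C)
    for (i in seq_len(R)) for (j in seq_len(C)) {
      out[i, j] <- fun(m[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
    }
    out
  }
}

#' Landmass mask from the terrestrial fraction
#'
#' A cell belongs to the landmass iff its terrestrial fraction is at
#' least the threshold (inclusive, following the "at least 25%" rule).
#' Ocean cells carry NoData; inland water remains part of the landmass.
#'
#' @param fraction A `covariate_raster` of terrestrial fractions.
#' @param threshold Fraction in (0, 1]; default 0.25.
#' @return A `covariate_raster` with 1 on land and NA (NoData) on ocean.
#' @export
landmass_mask <- function(fraction, threshold = 0.25) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  v <- ifelse(!is.na(fraction$values) & fraction$values >= threshold, 1, NA_real_)
  covariate_raster(matrix(v, nrow = nrow(fraction$values)), fraction$grid,
                   units = "binary", semantics = "landmass")
}

# internal: logical land matrix from a landmass raster
land_logical <- function(landmass) !is.na(landmass$values)
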