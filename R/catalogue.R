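# The covariate catalogue, per-zone clipping, and grid-conformance QA.

#' Enumerate the default covariate catalogue
#'
#' The complete default catalogue of 73 gridded covariates across the
#' eight source categories, with the centroid (BCB) and intersection
#' (PIB) building-metric variants and each water-threshold presence
#' mask counted as separate datasets. Names are unique and map onto the
#' output files of [run_all()].
#'
#' @return A data frame with columns `name`, `category`, `units`,
#'   `years` (comma-separated, "" for time-invariant) and `variant`.
#' @export
enumerate_catalogue <- function() {
  row <- function(name, category, units, years = "", variant = "")
    data.frame(name = name, category = category, units = units,
               years = years, variant = variant)
  lc_years <- paste(2015:2022, collapse = ",")
  clim_years <- paste(2015:2023, collapse = ",")
  epochs <- paste(BUILT_EPOCHS, collapse = ",")
  out <- rbind(
    row("inland_water_coverage", "inland_water", "%", "2021"),
    do.call(rbind, lapply(c(25, 50, 60, 75, 80, 85, 90), function(t)
      row(sprintf("inland_water_presence_t%d", t), "inland_water",
          "binary", "2021", sprintf("%d%%", t)))),
    row("distance_to_inland_water", "inland_water", "km", "2021"),
    row("distance_to_coastline", "inland_water", "km", "2021"),
    row("elevation", "topography", "m"),
    row("slope", "topography", "degrees"),
    row("annual_temperature", "climate", "K", clim_years),
    row("annual_precipitation", "climate", "mm", clim_years),
    row("ntl_filtered", "nighttime_lights", "nW/cm2/sr",
        paste(2015:2021, collapse = ",")),
    row("ntl_unfiltered", "nighttime_lights", "nW/cm2/sr", "2022,2023"),
    do.call(rbind, lapply(LC_TARGET_CODES, function(code)
      row(sprintf("distance_to_lc%d_edge", code), "land_cover", "km",
          lc_years))),
    row("distance_to_protected_cat1", "protected_areas", "km", lc_years),
    row("distance_to_protected_cat2to6", "protected_areas", "km", lc_years),
    row("distance_to_osm_major_roads", "infrastructure", "km", "2023"),
    row("distance_to_osm_intersections", "infrastructure", "km", "2023"),
    row("distance_to_osm_waterbodies", "infrastructure", "km", "2023"),
    row("ms_roads_count", "infrastructure", "count"),
    row("ms_roads_presence", "infrastructure", "binary"),
    row("ms_roads_density", "infrastructure", "m/km2"),
    row("ms_roads_length", "infrastructure", "m"),
    row("distance_to_ms_roads", "infrastructure", "km"),
    do.call(rbind, lapply(c("ms", "google"), function(src) {
      metrics <- c(count = "count", total_area = "m2", mean_area = "m2",
                   cv_area = "ratio", total_perimeter = "m",
                   mean_perimeter = "m", cv_perimeter = "ratio",
                   density = "count/km2")
      do.call(rbind, lapply(c("bcb", "pib"), function(variant)
        do.call(rbind, lapply(names(metrics), function(m)
          row(sprintf("%s_buildings_%s_%s", src, m, variant), "built_up",
              metrics[[m]], "", toupper(variant))))))
    })),
    row("builtup_surface", "built_up", "m2", epochs),
    row("nonres_builtup_surface", "built_up", "m2", epochs),
    row("distance_to_builtup", "built_up", "km", epochs),
    row("builtup_presence", "built_up", "binary", epochs),
    row("builtup_volume", "built_up", "m3", epochs),
    row("nonres_builtup_volume", "built_up", "m3", epochs)
  )
  rownames(out) <- NULL
  out
}

#' Clip a covariate raster to a zone
#'
#' Values outside the zone become NoData and the window is cropped to
#' the zone's bounding box on the lattice (the per-country organisation
#' of the production outputs; zone rasters are caller-supplied).
#'
#' @param r A `covariate_raster`.
#' @param zone Logical matrix (or binary `covariate_raster`) on the
#'   same grid; TRUE/1 marks the zone.
#' @return The clipped `covariate_raster` (all-NoData 1x1 for an empty
#'   zone).
#' @export
clip_to_zone <- function(r, zone) {
  if (inherits(zone, "covariate_raster")) {
    if (!same_grid(zone$grid, r$grid)) stop("zone grid mismatch")
    zone <- !is.na(zone$values) & zone$values != 0
  }
  if (!all(dim(zone) == dim(r$values))) stop("zone grid mismatch")
  v <- r$values
  v[!zone] <- NA_real_
  if (!any(zone)) {
    g1 <- make_grid_spec(r$grid$origin_lon,
                         r$grid$origin_lat - cell_size(r$grid),
                         r$grid$origin_lon + cell_size(r$grid),
                         r$grid$origin_lat, r$grid$res_arcsec)
    return(covariate_raster(matrix(NA_real_, 1, 1), g1, units = r$units,
                            year = r$year, semantics = r$semantics))
  }
  rows <- range(which(apply(zone, 1, any)))
  cols <- range(which(apply(zone, 2, any)))
  cs <- cell_size(r$grid)
  g <- make_grid_spec(r$grid$origin_lon + (cols[1] - 1) * cs,
                      r$grid$origin_lat - rows[2] * cs,
                      r$grid$origin_lon + cols[2] * cs,
                      r$grid$origin_lat - (rows[1] - 1) * cs,
                      r$grid$res_arcsec)
  covariate_raster(v[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE], g,
                   units = r$units, year = r$year, semantics = r$semantics,
                   categorical = r$categorical)
}

#' Grid-conformance QA check
#'
#' Mirrors the production quality checks: the file's extent must sit on
#' the global lattice, the resolution must equal the expected
#' arc-second value, the NoData sentinel must be -99999, and the CRS
#' must be geographic WGS84.
#'
#' @param path Path to a raster written by [write_raster()].
#' @param res_arcsec Expected resolution; default 3.
#' @return Character vector of violations; empty means the file passes.
#' @export
qa_check <- function(path, res_arcsec = 3) {
  issues <- character(0)
  meta <- tryCatch(jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE),
                   error = function(e) NULL)
  r <- tryCatch(read_raster(path), error = function(e) e)
  if (inherits(r, "error"))
    return(paste0("unreadable: ", conditionMessage(r)))
  g <- r$grid
  if (g$res_arcsec != res_arcsec)
    issues <- c(issues, sprintf("resolution %s\" != expected %s\"",
                                format(g$res_arcsec), format(res_arcsec)))
  per_deg <- 3600 / g$res_arcsec
  kx <- (g$origin_lon - LATTICE_ANCHOR_LON) * per_deg
  ky <- (LATTICE_ANCHOR_LAT - g$origin_lat) * per_deg
  if (abs(kx - round(kx)) > 1e-6 || abs(ky - round(ky)) > 1e-6)
    issues <- c(issues, "extent not on the global lattice")
  if (g$nodata != NODATA_SENTINEL)
    issues <- c(issues, sprintf("NoData %s != %d", format(g$nodata), NODATA_SENTINEL))
  if (!is.null(meta)) {
    if (!identical(meta$crs, "EPSG:4326"))
      issues <- c(issues, "CRS is not geographic WGS84")
    if (!is.null(meta$nodata) && meta$nodata != NODATA_SENTINEL)
      issues <- c(issues, "sidecar NoData sentinel mismatch")
  }
  issues
}
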