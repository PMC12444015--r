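# Format I/O. Rasters travel as single-band GeoTIFF (uncompressed
# float32, WGS84 geokeys, GDAL-style NoData tag, written by the
# package's own minimal codec) with a JSON sidecar carrying the grid
# spec and layer semantics; ESRI ASCII grid (.asc) is supported as a
# plain-text alternative. Vector fixtures travel as GeoJSON.

# --- minimal GeoTIFF codec -------------------------------------------------
# Baseline TIFF, little-endian, one strip, one float32 sample per pixel,
# plus the GeoTIFF georeferencing tags (ModelPixelScale, ModelTiepoint,
# GeoKeyDirectory for geographic WGS84) and the GDAL NoData ASCII tag.

tiff_entry <- function(tag, type, count, value_raw) {
  # value_raw: exactly 4 bytes (value or offset)
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    value_raw)
}

raw4_long <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
raw4_short <- function(x) c(writeBin(as.integer(x), raw(), size = 2, endian = "little"),
                            as.raw(c(0, 0)))

write_geotiff <- function(values, grid, path, nodata = NODATA_SENTINEL) {
  nr <- nrow(values); nc <- ncol(values)
  v <- as.vector(t(values))                 # TIFF is row-major, top row first
  v[is.na(v)] <- nodata
  strip <- writeBin(as.numeric(v), raw(), size = 4, endian = "little")
  cs <- cell_size(grid)
  scale_raw <- writeBin(c(cs, cs, 0), raw(), size = 8, endian = "little")
  tie_raw <- writeBin(c(0, 0, 0, grid$origin_lon, grid$origin_lat, 0),
                      raw(), size = 8, endian = "little")
  geokeys <- as.integer(c(1, 1, 0, 3,       # version, rev, minor, key count
                          1024, 0, 1, 2,    # model type: geographic
                          1025, 0, 1, 1,    # raster type: pixel-is-area
                          2048, 0, 1, 4326))# geographic CS: WGS84
  geo_raw <- writeBin(geokeys, raw(), size = 2, endian = "little")
  nodata_str <- c(charToRaw(format(nodata, scientific = FALSE)), as.raw(0))
  if (length(nodata_str) %% 2 == 1) nodata_str <- c(nodata_str, as.raw(0))

  strip_off <- 8L
  off_scale <- strip_off + length(strip)
  off_tie <- off_scale + length(scale_raw)
  off_geo <- off_tie + length(tie_raw)
  off_nodata <- off_geo + length(geo_raw)
  off_ifd <- off_nodata + length(nodata_str)

  entries <- list(
    tiff_entry(256, 3, 1, raw4_short(nc)),              # ImageWidth
    tiff_entry(257, 3, 1, raw4_short(nr)),              # ImageLength
    tiff_entry(258, 3, 1, raw4_short(32)),              # BitsPerSample
    tiff_entry(259, 3, 1, raw4_short(1)),               # Compression: none
    tiff_entry(262, 3, 1, raw4_short(1)),               # Photometric: min-is-black
    tiff_entry(273, 4, 1, raw4_long(strip_off)),        # StripOffsets
    tiff_entry(277, 3, 1, raw4_short(1)),               # SamplesPerPixel
    tiff_entry(278, 3, 1, raw4_short(nr)),              # RowsPerStrip
    tiff_entry(279, 4, 1, raw4_long(length(strip))),    # StripByteCounts
    tiff_entry(284, 3, 1, raw4_short(1)),               # PlanarConfig
    tiff_entry(339, 3, 1, raw4_short(3)),               # SampleFormat: IEEE float
    tiff_entry(33550, 12, 3, raw4_long(off_scale)),     # ModelPixelScale
    tiff_entry(33922, 12, 6, raw4_long(off_tie)),       # ModelTiepoint
    tiff_entry(34735, 3, length(geokeys), raw4_long(off_geo)),  # GeoKeyDirectory
    tiff_entry(42113, 2, length(nodata_str), raw4_long(off_nodata)) # GDAL_NODATA
  )
  ifd <- c(writeBin(length(entries), raw(), size = 2, endian = "little"),
           do.call(c, entries),
           raw4_long(0))                                # next IFD: none
  header <- c(charToRaw("II"),
              writeBin(42L, raw(), size = 2, endian = "little"),
              raw4_long(off_ifd))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, strip, scale_raw, tie_raw, geo_raw, nodata_str, ifd), con)
  invisible(path)
}

read_geotiff <- function(path) {
  raw_all <- readBin(path, raw(), n = file.info(path)$size)
  rd <- function(off, n, size, what = "integer", signed = TRUE) {
    readBin(raw_all[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = "little", signed = signed)
  }
  if (rawToChar(raw_all[1:2]) != "II") stop("unsupported TIFF byte order in ", path)
  ifd_off <- rd(4, 1, 4)
  n_entries <- rd(ifd_off, 1, 2, signed = FALSE)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- ifd_off + 2 + (i - 1) * 12
    tag <- rd(e, 1, 2, signed = FALSE)
    type <- rd(e + 2, 1, 2, signed = FALSE)
    count <- rd(e + 4, 1, 4)
    val_off <- e + 8
    size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `11` = 4, `12` = 8)[as.character(type)]
    if (is.na(size)) next
    total <- size * count
    data_off <- if (total > 4) rd(val_off, 1, 4) else val_off
    vals <- switch(as.character(type),
                   `2` = rawToChar(raw_all[(data_off + 1):(data_off + count - 1)]),
                   `3` = rd(data_off, count, 2, signed = FALSE),
                   `4` = rd(data_off, count, 4),
                   `11` = rd(data_off, count, 4, what = "numeric"),
                   `12` = rd(data_off, count, 8, what = "numeric"),
                   rd(data_off, count, 1, signed = FALSE))
    tags[[as.character(tag)]] <- vals
  }
  nc <- tags[["256"]]; nr <- tags[["257"]]
  if (is.null(nc) || is.null(nr)) stop("not a usable TIFF: ", path)
  if (!is.null(tags[["259"]]) && tags[["259"]] != 1)
    stop("compressed TIFF not supported by this reader: ", path)
  offs <- tags[["273"]]; counts <- tags[["279"]]
  pix <- numeric(0)
  for (k in seq_along(offs)) {
    pix <- c(pix, rd(offs[k], counts[k] / 4, 4, what = "numeric"))
  }
  m <- matrix(pix, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(tags[["42113"]])) as.numeric(tags[["42113"]]) else NODATA_SENTINEL
  scale <- tags[["33550"]]; tie <- tags[["33922"]]
  list(values = m, nodata = nodata,
       origin_lon = if (!is.null(tie)) tie[4] else NA_real_,
       origin_lat = if (!is.null(tie)) tie[5] else NA_real_,
       cell_size = if (!is.null(scale)) scale[1] else NA_real_)
}

# --- grid-spec sidecars ----------------------------------------------------

#' Serialise a grid spec to JSON
#'
#' @param spec A `grid_spec`.
#' @param path Output path (`.json`).
#' @return The path, invisibly.
#' @export
write_grid_spec <- function(spec, path) {
  jsonlite::write_json(list(origin_lon = spec$origin_lon,
                            origin_lat = spec$origin_lat,
                            res_arcsec = spec$res_arcsec,
                            n_rows = spec$n_rows, n_cols = spec$n_cols,
                            nodata = spec$nodata, crs = spec$crs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grid spec from its JSON serialisation
#' @param path JSON file written by [write_grid_spec()].
#' @return A `grid_spec`.
#' @export
read_grid_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cs <- j$res_arcsec / 3600
  make_grid_spec(j$origin_lon, j$origin_lat - j$n_rows * cs,
                 j$origin_lon + j$n_cols * cs, j$origin_lat, j$res_arcsec)
}

# --- covariate raster I/O --------------------------------------------------

sidecar_path <- function(path) paste0(sub("\\.(tif|tiff|asc)$", "", path), ".json")

#' Write a covariate raster
#'
#' GeoTIFF (`.tif`, float32, WGS84 geokeys, NoData -99999 both in the
#' GDAL tag and as the sentinel pixel value) or ESRI ASCII grid
#' (`.asc`). A JSON sidecar (same stem) records the grid spec and layer
#' metadata; [read_raster()] restores them.
#'
#' @param r A `covariate_raster`.
#' @param path Output path ending in `.tif` or `.asc`.
#' @return The path, invisibly.
#' @export
write_raster <- function(r, path) {
  if (grepl("\\.asc$", path)) {
    v <- r$values
    v[is.na(v)] <- r$grid$nodata
    hdr <- c(sprintf("ncols %d", r$grid$n_cols),
             sprintf("nrows %d", r$grid$n_rows),
             sprintf("xllcorner %.12f", r$grid$origin_lon),
             sprintf("yllcorner %.12f",
                     r$grid$origin_lat - r$grid$n_rows * cell_size(r$grid)),
             sprintf("cellsize %.14f", cell_size(r$grid)),
             sprintf("NODATA_value %d", as.integer(r$grid$nodata)))
    writeLines(c(hdr, apply(v, 1, paste, collapse = " ")), path)
  } else {
    write_geotiff(r$values, r$grid, path, nodata = r$grid$nodata)
  }
  jsonlite::write_json(list(origin_lon = r$grid$origin_lon,
                            origin_lat = r$grid$origin_lat,
                            res_arcsec = r$grid$res_arcsec,
                            n_rows = r$grid$n_rows, n_cols = r$grid$n_cols,
                            nodata = r$grid$nodata, crs = r$grid$crs,
                            units = r$units, year = r$year,
                            semantics = r$semantics,
                            categorical = r$categorical),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a covariate raster written by [write_raster()]
#'
#' @param path `.tif` or `.asc` path (the JSON sidecar must sit beside it).
#' @return A `covariate_raster`.
#' @export
read_raster <- function(path) {
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
  if (grepl("\\.asc$", path)) {
    hdr <- utils::read.table(path, nrows = 6, col.names = c("k", "v"),
                             colClasses = c("character", "numeric"))
    vals <- as.matrix(utils::read.table(path, skip = 6))
    dimnames(vals) <- NULL
    h <- stats::setNames(hdr$v, tolower(hdr$k))
    cs <- h[["cellsize"]]
    grid <- make_grid_spec(h[["xllcorner"]], h[["yllcorner"]],
                           h[["xllcorner"]] + h[["ncols"]] * cs,
                           h[["yllcorner"]] + h[["nrows"]] * cs,
                           round(cs * 3600))
    nod <- h[["nodata_value"]]
    vals[vals == nod] <- NA_real_
  } else {
    t <- read_geotiff(path)
    vals <- t$values
    vals[vals == t$nodata] <- NA_real_
    res <- if (!is.null(meta)) meta$res_arcsec else round(t$cell_size * 3600)
    cs <- res / 3600
    grid <- make_grid_spec(t$origin_lon, t$origin_lat - nrow(vals) * cs,
                           t$origin_lon + ncol(vals) * cs, t$origin_lat, res)
  }
  if (!is.null(meta) && !is.null(meta$crs) && !identical(meta$crs, "EPSG:4326"))
    stop("CRS mismatch: expected geographic WGS84 (EPSG:4326), got ", meta$crs)
  covariate_raster(vals, grid,
                   units = if (!is.null(meta$units)) meta$units else "",
                   year = meta$year,
                   semantics = if (!is.null(meta$semantics)) meta$semantics else "",
                   categorical = isTRUE(meta$categorical))
}

# --- GeoJSON vector I/O ----------------------------------------------------

#' Write a footprint set as GeoJSON
#' @param fs A `footprint_set`.
#' @param path Output `.geojson` path.
#' @return The path, invisibly.
#' @export
write_footprints_geojson <- function(fs, path) {
  feats <- lapply(seq_along(fs$polygons), function(i) {
    p <- fs$polygons[[i]]
    ring <- lapply(c(seq_along(p$lon), 1), function(k) c(p$lon[k], p$lat[k]))
    props <- list()
    if (!is.null(fs$confidence)) props$confidence <- fs$confidence[i]
    if (!is.null(fs$building_type)) props$building <- fs$building_type[i]
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a footprint set from GeoJSON
#' @param path `.geojson` path with Polygon features.
#' @param source Source tag for the resulting set.
#' @return A `footprint_set`.
#' @export
read_footprints_geojson <- function(path, source = "file") {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  polys <- list(); conf <- numeric(0); types <- character(0)
  has_conf <- FALSE; has_type <- FALSE
  for (f in j$features) {
    ring <- f$geometry$coordinates[[1]]
    polys[[length(polys) + 1]] <- list(
      lon = vapply(ring, function(c) c[[1]], numeric(1)),
      lat = vapply(ring, function(c) c[[2]], numeric(1)))
    cf <- f$properties$confidence
    tp <- f$properties$building
    conf <- c(conf, if (is.null(cf)) NA_real_ else cf)
    types <- c(types, if (is.null(tp)) NA_character_ else tp)
    if (!is.null(cf)) has_conf <- TRUE
    if (!is.null(tp)) has_type <- TRUE
  }
  footprint_set(polys, confidence = if (has_conf) conf else NULL,
                building_type = if (has_type) types else NULL,
                source = source)
}

#' Write a road set as GeoJSON LineStrings
#' @param rs A `road_set`.
#' @param path Output `.geojson` path.
#' @return The path, invisibly.
#' @export
write_roads_geojson <- function(rs, path) {
  feats <- lapply(rs$lines, function(ln) {
    coords <- lapply(seq_len(nrow(ln)), function(k) c(ln[k, 1], ln[k, 2]))
    list(type = "Feature", properties = list(),
         geometry = list(type = "LineString", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a road set from GeoJSON
#' @param path `.geojson` path with LineString features.
#' @param source Source tag.
#' @return A `road_set`.
#' @export
read_roads_geojson <- function(path, source = "file") {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  lines <- lapply(j$features, function(f) {
    do.call(rbind, lapply(f$geometry$coordinates,
                          function(c) c(c[[1]], c[[2]])))
  })
  road_set(lines, source = source)
}
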