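# Land-cover reclassification: aggregate the 22 source classes into the
# nine covariate classes and derive per-class binary and distance layers.

# The nine covariate class codes and their meaning.
LC_TARGET_CODES <- c(
  cultivated = 11, woody_tree = 40, shrub = 130, herbaceous = 140,
  sparse_vegetation = 150, aquatic_vegetation = 160,
  artificial_surface = 190, bare = 200, water_snow_ice = 210
)

#' Default 22-to-9 land-cover reclassification table
#'
#' The source legend's 22 major classes grouped by legend family into
#' the nine covariate classes (cultivated 11, woody/tree 40, shrub 130,
#' herbaceous 140, sparse vegetation 150, aquatic vegetation 160,
#' artificial surface 190, bare 200, water/snow/ice 210). The
#' authoritative production mapping is not published; this default is a
#' reasoned reconstruction and is user-overridable wherever a
#' `reclass_map` is accepted (see [read_reclass_map()]).
#'
#' @return A data frame with columns `src` and `dst`.
#' @export
default_reclass_map <- function() {
  data.frame(
    src = c(10, 20, 30,                     # cropland (rainfed, irrigated, mosaic)
            40, 50, 60, 70, 80, 90, 100,   # mosaic natural & tree cover
            110,                            # mosaic herbaceous
            120,                            # shrubland
            130,                            # grassland
            140,                            # lichens and mosses
            150,                            # sparse vegetation
            160, 170, 180,                  # flooded / aquatic vegetation
            190,                            # urban
            200,                            # bare areas
            210,                            # water bodies
            220),                           # permanent snow and ice
    dst = c(11, 11, 11,
            40, 40, 40, 40, 40, 40, 40,
            140,
            130,
            140,
            150,
            150,
            160, 160, 160,
            190,
            200,
            210,
            210)
  )
}

#' Read a reclassification table from a two-column CSV
#'
#' @param path CSV file with columns `src`, `dst`.
#' @return A validated reclassification data frame.
#' @export
read_reclass_map <- function(path) {
  m <- utils::read.csv(path)
  validate_reclass_map(m)
  m
}

validate_reclass_map <- function(map) {
  if (!all(c("src", "dst") %in% names(map))) stop("reclass map needs columns src, dst")
  if (anyDuplicated(map$src)) stop("duplicate source codes in reclass map")
  bad <- setdiff(unique(map$dst), LC_TARGET_CODES)
  if (length(bad))
    stop("reclass map targets outside the nine covariate classes: ",
         paste(bad, collapse = ", "))
  invisible(map)
}

#' Reclassify a categorical land-cover raster
#'
#' Cell-wise code substitution via the mapping table; NoData is
#' preserved. Every code present in the raster must be a key of the map.
#'
#' @param lc Categorical `covariate_raster`.
#' @param map Reclassification data frame (`src`, `dst`); default
#'   [default_reclass_map()].
#' @return A categorical `covariate_raster` with nine-class codes.
#' @export
reclassify <- function(lc, map = default_reclass_map()) {
  validate_reclass_map(map)
  v <- lc$values
  present <- unique(v[!is.na(v)])
  unmapped <- setdiff(present, map$src)
  if (length(unmapped))
    stop("unmapped land-cover codes: ", paste(sort(unmapped), collapse = ", "))
  out <- matrix(map$dst[match(v, map$src)], nrow = nrow(v))
  covariate_raster(out, lc$grid, units = "class", year = lc$year,
                   semantics = "landcover_9class", categorical = TRUE)
}

#' Binary layer for one land-cover class
#'
#' @param lc9 Nine-class categorical `covariate_raster`.
#' @param code One of the nine covariate class codes.
#' @return A `feature_mask` (1 where the cell carries the class).
#' @export
class_binary <- function(lc9, code) {
  if (!code %in% LC_TARGET_CODES)
    stop("unknown covariate class code: ", code)
  feat <- !is.na(lc9$values) & lc9$values == code
  feature_mask(feat, lc9$grid, domain = !is.na(lc9$values))
}

#' Per-class distance covariates for one or more years
#'
#' Full land-cover pipeline per year: reclassify to nine classes,
#' downsample to the master grid (nearest neighbour), fill coastal gaps
#' with the neighbouring majority class, extract the nine binary layers,
#' and convert each to a continuous raster of great-circle distance to
#' the class area edge. A class absent from the window yields an
#' all-NoData layer under the default empty-feature policy.
#'
#' @param lc_by_year Named list (names = years) of categorical source
#'   rasters, possibly finer than `grid`.
#' @param grid Target `grid_spec`.
#' @param landmass Landmass raster on `grid`.
#' @param map Reclassification table.
#' @param empty Empty-feature policy, `"nodata"` (default) or `"zero"`.
#' @return Nested list: `result[[year]][[class_code]]`, each a
#'   `covariate_raster` in km.
#' @export
landcover_distance_suite <- function(lc_by_year, grid, landmass,
                                     map = default_reclass_map(),
                                     empty = c("nodata", "zero")) {
  empty <- match.arg(empty)
  out <- lapply(names(lc_by_year), function(yr) {
    lc9 <- reclassify(lc_by_year[[yr]], map)
    on_grid <- resample_to_grid(lc9, grid, "nearest")
    filled <- fill_coastal_gaps_majority(on_grid, landmass)
    layers <- lapply(LC_TARGET_CODES, function(code) {
      m <- class_binary(filled, code)
      m$domain <- land_logical(landmass)
      r <- distance_or_policy(m, empty = empty, boundary = TRUE)
      r$year <- as.integer(yr)
      r$semantics <- sprintf("distance_to_lc%d_edge", code)
      r
    })
    names(layers) <- as.character(LC_TARGET_CODES)
    layers
  })
  names(out) <- names(lc_by_year)
  out
}
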