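# Inland-water covariates: water-coverage fraction, the seven-threshold
# binary mask family, and the two water distance layers.

#' Inland water fraction per master-grid cell
#'
#' Aggregates the fine binary permanent-water raster to the master grid
#' by exact cell counting, then removes ocean and coastline cells so
#' only inland water remains (values describe the water share of each
#' landmass cell).
#'
#' @param fine_water Binary `covariate_raster` on an integer-subdivision
#'   grid (1 = permanent water).
#' @param landmass Landmass raster on the target grid.
#' @param grid Target `grid_spec`.
#' @return A `covariate_raster` of fractions on land, NoData on ocean.
#' @export
water_fraction <- function(fine_water, landmass, grid) {
  f <- subdivision_factor(fine_water$grid, grid)
  vals <- fine_water$values
  vals[is.na(vals)] <- 0
  frac <- block_aggregate(vals, f, mean)
  frac[!land_logical(landmass)] <- NA_real_
  covariate_raster(frac, grid, units = "fraction",
                   semantics = "inland_water_fraction")
}

#' Threshold family of binary inland-water masks
#'
#' One binary mask per threshold: a cell is water iff its inland-water
#' fraction is at least `threshold/100` (inclusive, consistent with the
#' landmass rule). The default list is the published seven thresholds
#' 25, 50, 60, 75, 80, 85 and 90 percent; masks are nested (a higher
#' threshold's mask is a subset of a lower one's).
#'
#' @param wf Water-fraction `covariate_raster` (from [water_fraction()]).
#' @param thresholds Strictly increasing percentages in (0, 100].
#' @return Named list of binary `covariate_raster`s ("t25", "t50", ...).
#' @export
threshold_mask_family <- function(wf, thresholds = c(25, 50, 60, 75, 80, 85, 90)) {
  if (length(thresholds) == 0) stop("empty threshold list")
  if (anyDuplicated(thresholds)) stop("duplicated thresholds")
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  if (any(thresholds <= 0 | thresholds > 100)) stop("thresholds must lie in (0, 100]")
  out <- lapply(thresholds, function(t) {
    v <- ifelse(is.na(wf$values), NA_real_,
                as.numeric(wf$values >= t / 100))
    covariate_raster(matrix(v, nrow = nrow(wf$values)), wf$grid,
                     units = "binary",
                     semantics = sprintf("inland_water_presence_t%g", t))
  })
  names(out) <- sprintf("t%g", thresholds)
  out
}

#' Distance to inland water
#'
#' Builds the inland-water mask at the stated threshold (default 75
#' percent, the published choice for this covariate, not the family
#' minimum) and measures the great-circle distance to the nearest water
#' cell for every landmass cell.
#'
#' @param wf Water-fraction `covariate_raster`.
#' @param threshold Percent threshold; default 75.
#' @param empty Policy when the window has no qualifying water cell:
#'   `"nodata"` (default) or `"zero"`.
#' @return A `covariate_raster` in km.
#' @export
distance_to_inland_water <- function(wf, threshold = 75,
                                     empty = c("nodata", "zero")) {
  domain <- !is.na(wf$values)
  feat <- !is.na(wf$values) & wf$values >= threshold / 100
  m <- feature_mask(feat, wf$grid, domain)
  r <- distance_or_policy(m, empty = match.arg(empty))
  r$semantics <- "distance_to_inland_water"
  r
}

#' Distance to the open-water coastline
#'
#' Coastline features are ocean (NoData-in-landmass) cells 8-adjacent to
#' a land cell; distances are reported on land cells. Inland water cells
#' are part of the landmass and are never coastline features.
#'
#' @param landmass Landmass raster.
#' @return A `covariate_raster` in km.
#' @export
distance_to_coastline <- function(landmass) {
  land <- land_logical(landmass)
  ocean <- !land
  # ocean cells 8-adjacent to land
  coast <- ocean & boundary_of_complement(land)
  if (!any(coast))
    stop("no ocean adjacent to land in this window; widen the window")
  m <- feature_mask(coast, landmass$grid, domain = land)
  r <- distance_to_features(m)
  r$semantics <- "distance_to_coastline"
  r
}

# internal: cells 8-adjacent to a TRUE cell of `m` (any neighbour TRUE)
boundary_of_complement <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  adj <- matrix(FALSE, nr, nc)
  for (o in list(c(0, 0), c(0, 1), c(0, 2), c(1, 0), c(1, 2),
                 c(2, 0), c(2, 1), c(2, 2))) {
    adj <- adj | pad[(1 + o[1]):(nr + o[1]), (1 + o[2]):(nc + o[2]), drop = FALSE]
  }
  adj
}
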