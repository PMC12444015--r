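# Built-up fusion: combine the multi-epoch built surface/volume stack
# with footprint- and settlement-derived evidence, imputing heights for
# added cells by Nadaraya-Watson kernel regression on nearby known
# heights.

BUILT_EPOCHS <- c(2015, 2020, 2025, 2030)

#' Construct a built-up stack
#'
#' @param S Named list of built-surface matrices (m^2 per cell), names
#'   "2015", "2020", "2025", "2030".
#' @param V Named list of built-volume matrices (m^3), same epochs.
#' @param H Mean building-height matrix (m), single epoch.
#' @param nonres_S,nonres_V Non-residential counterparts of `S` and `V`.
#' @param grid A `grid_spec`.
#' @return An object of class `built_stack`.
#' @export
built_stack <- function(S, V, H, nonres_S = NULL, nonres_V = NULL, grid) {
  need <- as.character(BUILT_EPOCHS)
  if (!all(need %in% names(S)) || !all(need %in% names(V)))
    stop("S and V must carry the four epochs ", paste(need, collapse = ", "))
  structure(list(S = S, V = V, H = H,
                 nonres_S = nonres_S, nonres_V = nonres_V, grid = grid),
            class = "built_stack")
}

#' Combine auxiliary built-surface evidence
#'
#' Per cell, the candidate built surface is the maximum over the
#' footprint-derived intersection (PIB) areas of each source and the
#' settlement fraction times the cell area, clipped to the cell area
#' (the max rule avoids double counting overlapping sources).
#'
#' @param pib_areas List of `cell_metrics` objects (their `total_area`
#'   in m^2) from the footprint sources.
#' @param wsf_fraction Settlement-fraction `covariate_raster` in `[0,1]`,
#'   or NULL.
#' @param grid Target `grid_spec`.
#' @return Matrix of candidate built surface in m^2 (0 where no source
#'   reports anything).
#' @export
evidence_surface <- function(pib_areas, wsf_fraction = NULL, grid) {
  cell_m2 <- matrix(cell_area_profile(grid) * 1e6, grid$n_rows, grid$n_cols)
  ev <- matrix(0, grid$n_rows, grid$n_cols)
  for (pm in pib_areas) {
    if (!same_grid(pm$grid, grid)) stop("PIB metrics grid mismatch")
    ev <- pmax(ev, pm$total_area)
  }
  if (!is.null(wsf_fraction)) {
    if (!same_grid(wsf_fraction$grid, grid)) stop("settlement raster grid mismatch")
    wf <- wsf_fraction$values
    wf[is.na(wf)] <- 0
    ev <- pmax(ev, wf * cell_m2)
  }
  pmin(ev, cell_m2)
}

#' Cells missing in the 2030 built layer but present in the evidence
#'
#' A cell is "missing" iff the 2030 built-surface epoch reports zero or
#' NoData there while at least one auxiliary source reports built
#' surface. Cells that already carry any built surface are never
#' modified by the fusion.
#'
#' @param s2030 Matrix of 2030 built surface (m^2).
#' @param ev Evidence matrix from [evidence_surface()].
#' @return Logical matrix of missing cells.
#' @export
find_missing <- function(s2030, ev) {
  (is.na(s2030) | s2030 == 0) & ev > 0
}

#' Fuse evidence into the built-surface stack
#'
#' For every missing cell the evidence surface is assigned to all four
#' epochs; every other cell is untouched. The fusion is monotone (never
#' decreases any surface) and idempotent (added cells are no longer
#' missing).
#'
#' @param stack A `built_stack`.
#' @param ev Evidence matrix (m^2).
#' @param missing Logical matrix from [find_missing()]; computed from
#'   the stack's 2030 surface epoch when NULL.
#' @return The fused `built_stack`.
#' @export
fuse_surface <- function(stack, ev, missing = NULL) {
  if (is.null(missing)) missing <- find_missing(stack$S[["2030"]], ev)
  for (ep in as.character(BUILT_EPOCHS)) {
    s <- stack$S[[ep]]
    s[missing] <- ev[missing]
    stack$S[[ep]] <- s
  }
  stack
}

#' Nadaraya-Watson height estimate for one cell
#'
#' Kernel-weighted mean of the known heights in the neighbourhood:
#' `h_hat = sum K(d_i/b) h_i / sum K(d_i/b)` over donor cells with
#' height > 0 within the search radius, with `d_i` the great-circle
#' distance between cell centres and a Gaussian kernel by default. When
#' no donor lies within the search radius the window mean of positive
#' heights is used; if the window holds none, the configured default
#' height.
#'
#' @param row,col Target cell indices.
#' @param H Height matrix (m); 0 or NA marks unknown.
#' @param grid A `grid_spec`.
#' @param bandwidth Kernel bandwidth in metres; default 1000.
#' @param search_radius Donor search radius in metres; default 5000.
#' @param default_height Fallback height in metres; default 5.
#' @return Estimated height in metres.
#' @export
nw_height <- function(row, col, H, grid, bandwidth = 1000,
                      search_radius = 5000, default_height = 5) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (search_radius < bandwidth) stop("search_radius must be >= bandwidth")
  cs <- cell_size(grid)
  # window big enough to contain the search radius at this latitude
  lat0 <- cell_center_lat(grid, row)
  m_per_deg <- EARTH_RADIUS_KM * 1000 * pi / 180
  half_r <- ceiling(search_radius / (m_per_deg * cs)) + 1
  half_c <- ceiling(search_radius / (m_per_deg * cos(lat0 * pi / 180) * cs)) + 1
  rows <- max(1, row - half_r):min(grid$n_rows, row + half_r)
  cols <- max(1, col - half_c):min(grid$n_cols, col + half_c)
  win <- H[rows, cols, drop = FALSE]
  donor <- which(!is.na(win) & win > 0, arr.ind = TRUE)
  if (nrow(donor) == 0) return(default_height)
  d_m <- haversine_km(lat0, cell_center_lon(grid, col),
                      cell_center_lat(grid, rows[donor[, 1]]),
                      cell_center_lon(grid, cols[donor[, 2]])) * 1000
  keep <- d_m <= search_radius
  if (!any(keep)) return(mean(win[!is.na(win) & win > 0]))
  u <- d_m[keep] / bandwidth
  w <- exp(-0.5 * u^2)
  h <- win[donor[keep, , drop = FALSE]]
  sum(w * h) / sum(w)
}

#' Fuse evidence into the built-volume stack
#'
#' Mirrors [fuse_surface()] against the 2030 volume epoch: every cell
#' missing in volume but supported by evidence receives an imputed
#' height from [nw_height()] times the evidence surface, at all four
#' epochs - so the volume/surface ratio of an added cell equals its
#' imputed height exactly.
#'
#' @param stack A `built_stack`.
#' @param ev Evidence matrix (m^2).
#' @param missing Logical matrix; computed from the 2030 volume epoch
#'   when NULL.
#' @param bandwidth,search_radius,default_height Passed to [nw_height()].
#' @return The fused `built_stack`, with the imputed-height matrix
#'   attached as attribute `"imputed_height"`.
#' @export
fuse_volume <- function(stack, ev, missing = NULL, bandwidth = 1000,
                        search_radius = 5000, default_height = 5) {
  if (is.null(missing)) missing <- find_missing(stack$V[["2030"]], ev)
  idx <- which(missing, arr.ind = TRUE)
  hmat <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  if (nrow(idx) > 0) {
    hh <- vapply(seq_len(nrow(idx)), function(k) {
      nw_height(idx[k, 1], idx[k, 2], stack$H, stack$grid,
                bandwidth, search_radius, default_height)
    }, numeric(1))
    hmat[idx] <- hh
    for (ep in as.character(BUILT_EPOCHS)) {
      v <- stack$V[[ep]]
      v[idx] <- hh * ev[idx]
      stack$V[[ep]] <- v
    }
  }
  attr(stack, "imputed_height") <- hmat
  stack
}

#' Non-residential fusion from tagged footprints
#'
#' Filters a footprint set to buildings whose type tag marks
#' non-residential use (defaults include "public", "industrial" and
#' "outbuilding"), grids them by the intersection (PIB) method, and
#' applies the same missing-cell fusion to the non-residential surface
#' and (via height imputation) volume layers.
#'
#' @param stack A `built_stack` with `nonres_S` and `nonres_V`.
#' @param osm_fs A `footprint_set` with `building_type` tags.
#' @param tag_set Character vector of non-residential tags.
#' @param bandwidth,search_radius,default_height Passed to [nw_height()].
#' @return The fused `built_stack`.
#' @export
nonresidential_fusion <- function(stack, osm_fs,
                                  tag_set = c("public", "industrial", "outbuilding"),
                                  bandwidth = 1000, search_radius = 5000,
                                  default_height = 5) {
  if (is.null(stack$nonres_S) || is.null(stack$nonres_V))
    stop("stack carries no non-residential layers")
  if (is.null(osm_fs$building_type))
    stop("footprint set carries no building_type tags")
  keep <- which(osm_fs$building_type %in% tag_set)
  sub <- footprint_set(osm_fs$polygons[keep],
                       confidence = osm_fs$confidence[keep],
                       building_type = osm_fs$building_type[keep],
                       source = osm_fs$source)
  pm <- pib_metrics(sub, stack$grid)
  ev <- evidence_surface(list(pm), NULL, stack$grid)
  miss_s <- find_missing(stack$nonres_S[["2030"]], ev)
  for (ep in as.character(BUILT_EPOCHS)) {
    s <- stack$nonres_S[[ep]]
    s[miss_s] <- ev[miss_s]
    stack$nonres_S[[ep]] <- s
  }
  miss_v <- find_missing(stack$nonres_V[["2030"]], ev)
  idx <- which(miss_v, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    hh <- vapply(seq_len(nrow(idx)), function(k) {
      nw_height(idx[k, 1], idx[k, 2], stack$H, stack$grid,
                bandwidth, search_radius, default_height)
    }, numeric(1))
    for (ep in as.character(BUILT_EPOCHS)) {
      v <- stack$nonres_V[[ep]]
      v[idx] <- hh * ev[idx]
      stack$nonres_V[[ep]] <- v
    }
  }
  stack
}

#' Presence and distance derivatives of the built surface
#'
#' Per epoch: a binary presence layer (surface > 0) and the great-circle
#' distance from each landmass cell to the nearest built cell.
#'
#' @param stack A `built_stack`.
#' @param landmass Landmass raster.
#' @param empty Empty-feature policy for the distance layers.
#' @return List with `presence[[epoch]]` and `distance[[epoch]]`
#'   `covariate_raster`s.
#' @export
built_derivatives <- function(stack, landmass, empty = c("nodata", "zero")) {
  empty <- match.arg(empty)
  land <- land_logical(landmass)
  presence <- list(); distance <- list()
  for (ep in as.character(BUILT_EPOCHS)) {
    s <- stack$S[[ep]]
    pres <- !is.na(s) & s > 0
    pv <- ifelse(land, as.numeric(pres), NA_real_)
    presence[[ep]] <- covariate_raster(matrix(pv, nrow = nrow(s)), stack$grid,
                                       units = "binary", year = as.integer(ep),
                                       semantics = "builtup_presence")
    m <- feature_mask(pres, stack$grid, domain = land)
    r <- distance_or_policy(m, empty = empty)
    r$year <- as.integer(ep)
    r$semantics <- "distance_to_builtup"
    distance[[ep]] <- r
  }
  list(presence = presence, distance = distance)
}
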