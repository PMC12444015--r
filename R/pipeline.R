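# Pipeline orchestration: chains the synthetic fixtures through every
# harmonisation stage and writes the complete covariate set, one
# GeoTIFF (+ JSON sidecar) per covariate and year. This is the backend
# of the command-line entry point in inst/scripts/covgrid-cli.R.

# internal: shared fixture context (landmask and friends)
pipeline_context <- function(cfg) {
  land <- gen_landscape(cfg)
  terr_codes <- setdiff(default_reclass_map()$src, 210)
  tf <- terrestrial_fraction(land$fine_landcover, terr_codes, cfg$grid)
  landmass <- landmass_mask(tf, 0.25)
  list(cfg = cfg, grid = cfg$grid, landscape = land,
       terrestrial = tf, landmass = landmass)
}

# internal: write one layer and append to the manifest
emit <- function(manifest, r, out_dir, name, year = NULL) {
  fname <- if (is.null(year)) sprintf("%s.tif", name)
           else sprintf("%s_%s.tif", name, year)
  path <- file.path(out_dir, fname)
  write_raster(r, path)
  rbind(manifest, data.frame(file = fname, covariate = name,
                             year = if (is.null(year)) NA_integer_
                                    else as.integer(year)))
}

mat_raster <- function(m, grid, units, year = NULL, semantics = "") {
  covariate_raster(m, grid, units = units,
                   year = if (is.null(year)) NULL else as.integer(year),
                   semantics = semantics)
}

#' Run the full harmonisation pipeline on the synthetic fixtures
#'
#' Generates every fixture input from the configuration and chains all
#' stages: landmask construction, inland-water masks and distances,
#' elevation fill and slope, climate aggregation, radiance
#' standardisation and site filtering, land-cover reclassification and
#' distance suite, protected-area rasterisation and distances, road and
#' building gridding, and built-up fusion with height imputation. One
#' GeoTIFF per covariate and year is written to `out_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param cfg A `fixture_config`; default `fixture_config(seed)`.
#' @param seed Convenience seed used when `cfg` is NULL.
#' @param stages Character vector of stages to run; default all. Valid
#'   stages: "water", "topography", "climate", "ntl", "landcover",
#'   "protected", "infrastructure", "buildings", "built".
#' @return Invisibly, the manifest data frame (file, covariate, year).
#' @export
run_all <- function(out_dir, cfg = NULL, seed = 1,
                    stages = c("water", "topography", "climate", "ntl",
                               "landcover", "protected", "infrastructure",
                               "buildings", "built")) {
  valid <- c("water", "topography", "climate", "ntl", "landcover",
             "protected", "infrastructure", "buildings", "built")
  bad <- setdiff(stages, valid)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg)) cfg <- fixture_config(seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ctx <- pipeline_context(cfg)
  grid <- ctx$grid; landmass <- ctx$landmass
  land <- land_logical(landmass)
  manifest <- data.frame(file = character(0), covariate = character(0),
                         year = integer(0))
  mask_na <- function(m) { m[!land] <- NA_real_; m }

  if ("water" %in% stages) {
    wf <- water_fraction(ctx$landscape$fine_water, landmass, grid)
    cov <- raster_like(wf, wf$values * 100, units = "%")
    cov$semantics <- "inland_water_coverage"
    manifest <- emit(manifest, cov, out_dir, "inland_water_coverage", 2021)
    fam <- threshold_mask_family(wf)
    for (nm in names(fam)) {
      manifest <- emit(manifest, fam[[nm]], out_dir,
                       sprintf("inland_water_presence_%s", nm), 2021)
    }
    manifest <- emit(manifest, distance_to_inland_water(wf), out_dir,
                     "distance_to_inland_water", 2021)
    manifest <- emit(manifest, distance_to_coastline(landmass), out_dir,
                     "distance_to_coastline", 2021)
  }

  if ("topography" %in% stages) {
    dem <- fill_coastal_gaps_mean(ctx$landscape$dem, landmass)
    manifest <- emit(manifest, dem, out_dir, "elevation")
    manifest <- emit(manifest, slope_from_dem(dem), out_dir, "slope")
  }

  if ("climate" %in% stages) {
    clim <- gen_climate(cfg)
    for (y in names(clim$precip)) {
      ann <- annual_precipitation(clim$precip[[y]])
      r <- resample_to_grid(ann, grid, "bilinear")
      r <- fill_coastal_gaps_mean(raster_like(r, mask_na(r$values)), landmass)
      manifest <- emit(manifest, r, out_dir, "annual_precipitation", y)
      ann_t <- annual_temperature(clim$temp[[y]])
      rt <- resample_to_grid(ann_t, grid, "bilinear")
      rt <- fill_coastal_gaps_mean(raster_like(rt, mask_na(rt$values)), landmass)
      manifest <- emit(manifest, rt, out_dir, "annual_temperature", y)
    }
  }

  if ("ntl" %in% stages) {
    rad <- gen_radiance(cfg)
    for (y in names(rad$grids)) {
      std <- standardise_radiance(rad$grids[[y]], grid, landmass)
      yr <- as.integer(y)
      if (yr <= 2021) {       # v2.1 years carry the flare/volcano filter
        out <- apply_site_filter(std, rad$sites)
        manifest <- emit(manifest, out, out_dir, "ntl_filtered", y)
      } else {                # v2.2 years pass through unfiltered
        manifest <- emit(manifest, std, out_dir, "ntl_unfiltered", y)
      }
    }
  }

  if ("landcover" %in% stages) {
    lc_years <- stats::setNames(
      lapply(2015:2022, function(y) {
        r <- ctx$landscape$fine_landcover
        r$year <- y
        r
      }), as.character(2015:2022))
    suite <- landcover_distance_suite(lc_years, grid, landmass)
    for (y in names(suite)) {
      for (code in names(suite[[y]])) {
        manifest <- emit(manifest, suite[[y]][[code]], out_dir,
                         sprintf("distance_to_lc%s_edge", code), y)
      }
    }
  }

  if ("protected" %in% stages) {
    vec <- gen_vectors(cfg)
    suite <- protected_distance_suite(vec$protected, 2015:2022, grid, landmass)
    for (grp in names(suite$distance)) {
      for (y in names(suite$distance[[grp]])) {
        manifest <- emit(manifest, suite$distance[[grp]][[y]], out_dir,
                         sprintf("distance_to_protected_%s", grp), y)
      }
    }
  }

  if ("infrastructure" %in% stages) {
    vec <- gen_vectors(cfg)
    # OSM-style pre-extracted layers: major roads, their intersections
    # (vertices shared by two or more roads stand in), and waterbodies
    manifest <- emit(manifest, distance_to_roads(vec$roads, grid, landmass),
                     out_dir, "distance_to_osm_major_roads", 2023)
    verts <- do.call(rbind, lapply(vec$roads$lines, function(m) m))
    ifeat <- matrix(FALSE, grid$n_rows, grid$n_cols)
    if (!is.null(verts) && nrow(verts) > 0) {
      rc <- locate_cell(grid, verts[, 1], verts[, 2])
      ok <- !is.na(rc$row)
      ifeat[cbind(rc$row[ok], rc$col[ok])] <- TRUE
    }
    ri <- distance_or_policy(feature_mask(ifeat, grid, domain = land),
                             empty = "zero")
    ri$year <- 2023L; ri$semantics <- "distance_to_osm_intersections"
    manifest <- emit(manifest, ri, out_dir, "distance_to_osm_intersections", 2023)
    wf <- water_fraction(ctx$landscape$fine_water, landmass, grid)
    rw <- distance_to_inland_water(wf)
    rw$semantics <- "distance_to_osm_waterbodies"
    manifest <- emit(manifest, rw, out_dir, "distance_to_osm_waterbodies", 2023)
    # imagery-derived road metrics
    rm_ <- road_cell_metrics(vec$roads, grid)
    manifest <- emit(manifest, mat_raster(rm_$count, grid, "count",
                                          semantics = "ms_roads_count"),
                     out_dir, "ms_roads_count")
    manifest <- emit(manifest, mat_raster(rm_$presence, grid, "binary",
                                          semantics = "ms_roads_presence"),
                     out_dir, "ms_roads_presence")
    manifest <- emit(manifest, mat_raster(rm_$density, grid, "m/km2",
                                          semantics = "ms_roads_density"),
                     out_dir, "ms_roads_density")
    manifest <- emit(manifest, mat_raster(rm_$length_m, grid, "m",
                                          semantics = "ms_roads_length"),
                     out_dir, "ms_roads_length")
    manifest <- emit(manifest, distance_to_roads(vec$roads, grid, landmass),
                     out_dir, "distance_to_ms_roads")
  }

  if ("buildings" %in% stages) {
    vec <- gen_vectors(cfg)
    for (src in c("ms", "google")) {
      fs <- vec[[src]]
      for (variant in c("bcb", "pib")) {
        cm <- if (variant == "bcb") bcb_metrics(fs, grid)
              else pib_metrics(fs, grid)
        for (m in c("count", "total_area", "mean_area", "cv_area",
                    "total_perimeter", "mean_perimeter", "cv_perimeter",
                    "density")) {
          units <- switch(m, count = "count", density = "count/km2",
                          cv_area = "ratio", cv_perimeter = "ratio",
                          total_area = "m2", mean_area = "m2", "m")
          nm <- sprintf("%s_buildings_%s_%s", src, m, variant)
          manifest <- emit(manifest,
                           mat_raster(cm[[m]], grid, units, semantics = nm),
                           out_dir, nm)
        }
      }
    }
  }

  if ("built" %in% stages) {
    vec <- gen_vectors(cfg)
    bs <- gen_built_stack(cfg)
    ev <- evidence_surface(list(pib_metrics(vec$ms, grid),
                                pib_metrics(vec$google, grid)),
                           bs$wsf_fraction, grid)
    stack <- fuse_surface(bs$stack, ev)
    stack <- fuse_volume(stack, ev)
    stack <- nonresidential_fusion(stack, vec$osm)
    deriv <- built_derivatives(stack, landmass)
    for (ep in as.character(BUILT_EPOCHS)) {
      manifest <- emit(manifest, mat_raster(mask_na(stack$S[[ep]]), grid, "m2",
                                            ep, "builtup_surface"),
                       out_dir, "builtup_surface", ep)
      manifest <- emit(manifest, mat_raster(mask_na(stack$nonres_S[[ep]]), grid,
                                            "m2", ep, "nonres_builtup_surface"),
                       out_dir, "nonres_builtup_surface", ep)
      manifest <- emit(manifest, mat_raster(mask_na(stack$V[[ep]]), grid, "m3",
                                            ep, "builtup_volume"),
                       out_dir, "builtup_volume", ep)
      manifest <- emit(manifest, mat_raster(mask_na(stack$nonres_V[[ep]]), grid,
                                            "m3", ep, "nonres_builtup_volume"),
                       out_dir, "nonres_builtup_volume", ep)
      manifest <- emit(manifest, deriv$presence[[ep]], out_dir,
                       "builtup_presence", ep)
      manifest <- emit(manifest, deriv$distance[[ep]], out_dir,
                       "distance_to_builtup", ep)
    }
  }

  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Run a single pipeline stage
#'
#' Thin wrapper over [run_all()] restricted to one stage (shared inputs
#' such as the landmask are regenerated from the same configuration, so
#' stage outputs are identical to a full run).
#'
#' @param stage One stage name; see [run_all()].
#' @param out_dir Output directory.
#' @param cfg,seed As in [run_all()].
#' @return Invisibly, the manifest data frame.
#' @export
run_stage <- function(stage, out_dir, cfg = NULL, seed = 1) {
  run_all(out_dir, cfg = cfg, seed = seed, stages = stage)
}
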