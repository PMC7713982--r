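# Synthetic landscape generator. Produces spatially autocorrelated elevation,
# climate, soil, and categorical cover rasters plus vector features (roads,
# powerlines, pipelines, towers, fire perimeters) with a known construction so
# every downstream stage of the pipeline can be exercised and checked.

#' Configuration for the synthetic landscape generator
#'
#' Defaults describe a 40 x 40 km semi-arid mountainous landscape at 100-m fine
#' grain with a 1-km model grain: a smooth elevation field (mean 2,000 m),
#' monthly climate normals driven by elevation (temperature falls with a
#' -6.5 C/km lapse rate, precipitation rises with elevation) plus smooth local
#' noise, soil property fields, categorical land cover assigned from an
#' elevation-correlated latent field (about 44% sagebrush communities overall),
#' and randomly placed linear features, towers, and fire perimeters.
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in meters
#' @param fine_cell fine raster grain, meters
#' @param coarse_cell model grain, meters
#' @param elev_mean,elev_sd,elev_smooth elevation mean (m), sd (m), and
#'   autocorrelation length (m); `elev_sd = 0` gives a flat landscape
#' @param elev_rough_sd,elev_rough_smooth sd (m) and autocorrelation length
#'   (m) of an additional short-wavelength roughness component that gives
#'   slope and ruggedness realistic local texture
#' @param lapse_rate temperature lapse rate, degrees C per km of elevation
#' @param epochs integer years of the categorical cover epochs
#' @param cover_codes cover code table, see [cover_code_table()]
#' @param cover_smooth autocorrelation length of the cover latent field, m
#' @param cover_elev_weight weight of elevation in the cover latent field (0-1)
#' @param soil_smooth,climate_smooth autocorrelation lengths (m) of the soil
#'   property fields and of the local (non-elevation) climate noise
#' @param n_secondary,n_highways,n_powerlines,n_pipelines,n_towers counts of
#'   synthetic anthropogenic features
#' @param n_fires number of fire perimeters
#' @param fire_years inclusive year range fires are drawn from
#' @param fire_radius `c(min, max)` fire perimeter radius, meters
#' @param fire_window_years look-back window for burned-area exposure
#' @return a list of class `landscape_config`
#' @export
landscape_config <- function(extent = c(0, 40000, 0, 40000),
                             fine_cell = 100, coarse_cell = 1000,
                             elev_mean = 2000, elev_sd = 350, elev_smooth = 6000,
                             elev_rough_sd = 20, elev_rough_smooth = 400,
                             lapse_rate = -6.5,
                             epochs = c(2010L, 2012L),
                             cover_codes = cover_code_table(),
                             cover_smooth = 4000, cover_elev_weight = 0.55,
                             soil_smooth = 5000, climate_smooth = 8000,
                             n_secondary = 6, n_highways = 2, n_powerlines = 3,
                             n_pipelines = 2, n_towers = 12,
                             n_fires = 6, fire_years = c(1992, 2011),
                             fire_radius = c(1500, 4000),
                             fire_window_years = 20) {
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3]) {
    stop2("landscape_config: configuration error, extent must be c(xmin, xmax, ymin, ymax) with positive width and height")
  }
  if (fine_cell <= 0 || coarse_cell <= 0) {
    stop2("landscape_config: configuration error, cell sizes must be positive")
  }
  structure(as.list(environment()), class = "landscape_config")
}

# mean monthly maximum temperature (deg C, Jan..Dec) at the reference
# elevation, and mean monthly precipitation (mm) before the elevation effect
.tmax_base <- c(2, 4, 9, 14, 20, 26, 30, 29, 23, 16, 8, 3)
.precip_base <- c(25, 25, 32, 30, 28, 18, 22, 28, 28, 30, 26, 25)

#' Generate a synthetic landscape stack
#'
#' Deterministic given `(config, seed)`. Elevation is a smoothed Gaussian
#' random field; monthly temperature normals decline with elevation (lapse
#' rate) and precipitation increases with it, each with additional smooth
#' noise, so the covariate correlations typical of mountain landscapes are
#' present. Cover classes are quantile bins of an elevation-correlated latent
#' field, re-drawn with high temporal correlation for each epoch. Linear
#' features are random jittered polylines crossing the extent; fire perimeters
#' are random star-shaped polygons with year attributes.
#'
#' @param config a `landscape_config`
#' @param seed integer seed
#' @return an object of class `landscape_stack` with components `fine`
#'   (elevation, cover per epoch, soil, monthly climate), `vectors` (polylines,
#'   towers, fires), `extent`, `fine_cell`, `coarse_cell`, `config`, `seed`
#' @export
generate_landscape <- function(config = landscape_config(), seed = 1) {
  if (!inherits(config, "landscape_config")) stop2("generate_landscape: config must come from landscape_config()")
  ext <- config$extent
  cs <- config$fine_cell
  nc <- max(2L, round((ext[2] - ext[1]) / cs))
  nr <- max(2L, round((ext[4] - ext[3]) / cs))
  gl <- function(v, name) grid_layer(v, ext[1], ext[3], cs, name = name)

  field <- function(offset, smooth_m) {
    set.seed(derive_seed(seed, offset))
    smooth_field(nr, nc, cs, smooth_m)
  }

  log_msg("simulate", "landscape %d x %d fine cells (%g m)", nr, nc, cs)
  elev_z <- if (config$elev_sd > 0) field(1, config$elev_smooth) else matrix(0, nr, nc)
  rough <- if (config$elev_sd > 0 && config$elev_rough_sd > 0) {
    config$elev_rough_sd * field(80, config$elev_rough_smooth)
  } else {
    matrix(0, nr, nc)
  }
  elev <- gl(config$elev_mean + config$elev_sd * elev_z + rough, "elevation")

  # cover: latent = elevation-correlated smooth field, classes by quantile bins
  w <- config$cover_elev_weight
  props <- c(developed = 0.02, agriculture = 0.08, grassland = 0.15,
             riparian = 0.05, low_sagebrush = 0.10,
             big_sagebrush_shrubland = 0.13, big_sagebrush_steppe = 0.13,
             mountain_sagebrush = 0.08, conifer = 0.14, barren = 0.12)
  codes <- config$cover_codes$codes
  latent1 <- w * elev_z + sqrt(1 - w^2) * field(2, config$cover_smooth)
  classify <- function(latent) {
    br <- stats::quantile(latent, probs = cumsum(props)[-length(props)])
    idx <- findInterval(latent, br) + 1L
    matrix(codes[names(props)][idx], nr, nc)
  }
  cover <- list()
  latent <- latent1
  for (k in seq_along(config$epochs)) {
    if (k > 1) latent <- 0.92 * latent + sqrt(1 - 0.92^2) * field(2 + k, config$cover_smooth)
    cover[[as.character(config$epochs[k])]] <- gl(classify(latent), paste0("cover_", config$epochs[k]))
  }

  # soils
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  soil <- list(
    clay = gl(clip(18 + 8 * field(10, config$soil_smooth), 5, 45), "clay"),
    silt = gl(clip(32 + 8 * field(11, config$soil_smooth), 10, 50), "silt"),
    awc = gl(clip(0.12 + 0.03 * field(12, config$soil_smooth), 0.01, 0.30), "awc"),
    salinity = gl(exp(-1 + 0.8 * field(13, config$soil_smooth)), "salinity"),
    soil_depth = gl(clip(80 + 35 * field(14, config$soil_smooth) - 25 * elev_z, 5, 200), "soil_depth")
  )
  soil$sand <- gl(100 - soil$clay$values - soil$silt$values, "sand")
  soil <- soil[c("clay", "silt", "sand", "awc", "salinity", "soil_depth")]

  # monthly climate normals at fine grain
  dz_km <- (elev$values - config$elev_mean) / 1000
  climate <- list(precip = vector("list", 12), tmin = vector("list", 12),
                  tmax = vector("list", 12))
  for (m in 1:12) {
    tmx <- .tmax_base[m] + config$lapse_rate * dz_km + 0.8 * field(20 + m, config$climate_smooth)
    tmn <- tmx - 13 + 1.0 * field(40 + m, config$climate_smooth)
    pr <- pmax(.precip_base[m] * (1 + 0.45 * dz_km) + 3 * field(60 + m, config$climate_smooth), 0.5)
    climate$tmax[[m]] <- gl(tmx, sprintf("tmax_%02d", m))
    climate$tmin[[m]] <- gl(tmn, sprintf("tmin_%02d", m))
    climate$precip[[m]] <- gl(pr, sprintf("precip_%02d", m))
  }

  # vector features
  set.seed(derive_seed(seed, 90))
  polyline <- function(jitter_sd = 1500) {
    horiz <- stats::runif(1) < 0.5
    tt <- seq(0, 1, length.out = 10)
    off <- cumsum(stats::rnorm(10, 0, jitter_sd / 3))
    off <- off - seq(off[1], off[length(off)], length.out = 10) # pinned ends
    if (horiz) {
      a <- stats::runif(1, ext[3], ext[4]); b <- stats::runif(1, ext[3], ext[4])
      cbind(ext[1] + tt * (ext[2] - ext[1]), clipv(a + tt * (b - a) + off, ext[3], ext[4]))
    } else {
      a <- stats::runif(1, ext[1], ext[2]); b <- stats::runif(1, ext[1], ext[2])
      cbind(clipv(a + tt * (b - a) + off, ext[1], ext[2]), ext[3] + tt * (ext[4] - ext[3]))
    }
  }
  star_polygon <- function(cx, cy, rmin, rmax, nv = 14) {
    ang <- sort(stats::runif(nv, 0, 2 * pi))
    r <- stats::runif(nv, rmin, rmax)
    cbind(cx + r * cos(ang), cy + r * sin(ang))
  }
  vectors <- list(
    roads_secondary = replicate(config$n_secondary, polyline(), simplify = FALSE),
    highways = replicate(config$n_highways, polyline(800), simplify = FALSE),
    powerlines = replicate(config$n_powerlines, polyline(1000), simplify = FALSE),
    pipelines = replicate(config$n_pipelines, polyline(1200), simplify = FALSE),
    towers = cbind(stats::runif(config$n_towers, ext[1], ext[2]),
                   stats::runif(config$n_towers, ext[3], ext[4])),
    fires = replicate(config$n_fires, {
      m <- min(config$fire_radius[2], (ext[2] - ext[1]) / 4, (ext[4] - ext[3]) / 4)
      list(xy = star_polygon(stats::runif(1, ext[1] + m, ext[2] - m),
                             stats::runif(1, ext[3] + m, ext[4] - m),
                             config$fire_radius[1], config$fire_radius[2]),
           year = sample(seq(config$fire_years[1], config$fire_years[2]), 1))
    }, simplify = FALSE)
  )

  structure(list(fine = list(elevation = elev, cover = cover, soil = soil,
                             climate = climate),
                 vectors = vectors,
                 extent = ext, fine_cell = cs, coarse_cell = config$coarse_cell,
                 config = config, seed = seed),
            class = "landscape_stack")
}

clipv <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @export
print.landscape_stack <- function(x, ...) {
  cat(sprintf("<landscape_stack> %g x %g km at %g m (model grain %g m), seed %d\n",
              (x$extent[2] - x$extent[1]) / 1000, (x$extent[4] - x$extent[3]) / 1000,
              x$fine_cell, x$coarse_cell, x$seed))
  cat(sprintf("  cover epochs: %s; %d fires; %d towers\n",
              paste(names(x$fine$cover), collapse = ", "),
              length(x$vectors$fires), nrow(x$vectors$towers)))
  invisible(x)
}

#' Write a landscape stack to disk
#'
#' Rasters as ESRI ASCII grids, vector features as GeoJSON, and the seed plus
#' configuration as YAML metadata.
#'
#' @param stack a `landscape_stack`
#' @param dir output directory (created if missing)
#' @return vector of written paths, invisibly
#' @export
write_landscape <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wg <- function(g, nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_asc(g, p, digits = 7)
    paths[[length(paths) + 1]] <<- p
  }
  wg(stack$fine$elevation, "elevation")
  for (ep in names(stack$fine$cover)) wg(stack$fine$cover[[ep]], paste0("cover_", ep))
  for (nm in names(stack$fine$soil)) wg(stack$fine$soil[[nm]], paste0("soil_", nm))
  for (vn in names(stack$fine$climate)) {
    for (m in 1:12) wg(stack$fine$climate[[vn]][[m]], sprintf("%s_%02d", vn, m))
  }
  gj <- function(obj, nm) {
    p <- file.path(dir, paste0(nm, ".geojson"))
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA)
    paths[[length(paths) + 1]] <<- p
  }
  lines_fc <- function(pls, what) {
    list(type = "FeatureCollection", features = lapply(pls, function(pl) {
      list(type = "Feature", properties = list(kind = what),
           geometry = list(type = "LineString",
                           coordinates = lapply(seq_len(nrow(pl)), function(i) pl[i, ])))
    }))
  }
  for (nm in c("roads_secondary", "highways", "powerlines", "pipelines")) {
    gj(lines_fc(stack$vectors[[nm]], nm), nm)
  }
  gj(list(type = "FeatureCollection", features = lapply(seq_len(nrow(stack$vectors$towers)), function(i) {
    list(type = "Feature", properties = list(kind = "tower"),
         geometry = list(type = "Point", coordinates = stack$vectors$towers[i, ]))
  })), "towers")
  gj(list(type = "FeatureCollection", features = lapply(stack$vectors$fires, function(f) {
    ring <- rbind(f$xy, f$xy[1, ])
    list(type = "Feature", properties = list(year = f$year),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)), function(i) ring[i, ]))))
  })), "fires")
  meta <- file.path(dir, "landscape.yml")
  cfg <- stack$config
  cfg$cover_codes <- list(codes = as.list(cfg$cover_codes$codes),
                          groups = lapply(cfg$cover_codes$groups, as.integer))
  yaml::write_yaml(list(seed = stack$seed, config = unclass(cfg)), meta)
  paths <- c(paths, meta)
  invisible(unlist(paths))
}
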