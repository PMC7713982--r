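# Engineering of the 24 environmental predictor surfaces at the model grain:
# circular-buffer land cover proportions, terrain (elevation, slope, vector
# ruggedness), soils, seasonal climate normals, burned-area fraction, and
# line/point feature densities.

#' Names of the 24 environmental predictors
#'
#' The model adds `year` and `site` as categorical predictors for a total of 26.
#' @return character vector of length 24
#' @export
predictor_names <- function() {
  c("sagebrush", "agriculture", "conifer", "developed", "grassland", "riparian",
    "elevation", "slope", "ruggedness",
    "clay", "silt", "sand", "awc", "salinity", "soil_depth",
    "precip", "tmin", "tmax",
    "burned",
    "road_secondary_density", "highway_density", "powerline_density",
    "pipeline_density", "tower_density")
}

#' Land cover code table
#'
#' Integer codes for the categorical cover raster and the class groups used as
#' predictors. The pooled sagebrush group is the union of the four sagebrush
#' community types (big sagebrush shrubland, big sagebrush steppe, low
#' sagebrush, mountain sagebrush).
#'
#' @return list with `codes` (named integer vector) and `groups`
#'   (name -> integer code set)
#' @export
cover_code_table <- function() {
  codes <- c(big_sagebrush_shrubland = 1L, big_sagebrush_steppe = 2L,
             low_sagebrush = 3L, mountain_sagebrush = 4L,
             agriculture = 5L, conifer = 6L, developed = 7L,
             grassland = 8L, riparian = 9L, barren = 10L)
  list(codes = codes,
       groups = list(sagebrush = codes[1:4],
                     agriculture = codes[["agriculture"]],
                     conifer = codes[["conifer"]],
                     developed = codes[["developed"]],
                     grassland = codes[["grassland"]],
                     riparian = codes[["riparian"]],
                     barren = codes[["barren"]]))
}

#' Proportion of in-set land cover within a circular buffer
#'
#' For each cell, the fraction of cells whose centers lie within `radius_m`
#' (inclusive) of the focal cell center that carry a code in `codes`. Nodata
#' cells are excluded from numerator and denominator; kernels are truncated at
#' the extent edge (valid-cell denominator).
#'
#' @param grid fine categorical `grid_layer`
#' @param codes integer vector of in-set class codes
#' @param radius_m buffer radius, meters (>= cell size)
#' @return `grid_layer` of fractions in \[0, 1\]
#' @export
focal_proportion <- function(grid, codes, radius_m) {
  if (radius_m < grid$cellsize) {
    stop2("focal_proportion: parameter error, radius (%g m) smaller than one cell (%g m)",
          radius_m, grid$cellsize)
  }
  k <- disc_kernel(radius_m, grid$cellsize)
  valid <- !is.na(grid$values)
  inset <- valid & (grid$values %in% codes)
  cnt <- focal_counts(list(num = inset, den = valid), k)
  p <- cnt$num / cnt$den
  p[cnt$den == 0] <- NA_real_
  grid_layer(p, grid$xmin, grid$ymin, grid$cellsize, name = "focal_proportion")
}

#' Line or point density within a circular buffer
#'
#' Per cell: total line length (meters) clipped to the circle of `radius_m`
#' around the cell center, or the count of points within the circle, divided by
#' the circle area. Line clipping is exact (segment-circle intersection).
#'
#' @param features for `type = "line"` a list of polylines (2-column matrices);
#'   for `type = "point"` a 2-column matrix of coordinates
#' @param radius_m search radius, meters (> 0)
#' @param target `grid_layer` defining the output grid
#' @param type `"line"` (length per area, m/m^2) or `"point"` (count per m^2)
#' @return `grid_layer` of densities
#' @export
feature_density <- function(features, radius_m, target,
                            type = c("line", "point")) {
  type <- match.arg(type)
  if (radius_m <= 0) stop2("feature_density: parameter error, radius must be positive")
  centers <- gl_centers(target)
  area <- pi * radius_m^2
  acc <- numeric(nrow(centers))
  if (type == "line") {
    for (pl in features) {
      if (is.null(pl) || nrow(pl) < 2) next
      for (s in seq_len(nrow(pl) - 1)) {
        acc <- acc + seg_circle_len(pl[s, ], pl[s + 1, ], centers, radius_m)
      }
    }
  } else {
    if (!is.null(features) && nrow(features) > 0) {
      for (s in seq_len(nrow(features))) {
        d2 <- (centers[, 1] - features[s, 1])^2 + (centers[, 2] - features[s, 2])^2
        acc <- acc + (d2 <= radius_m^2)
      }
    }
  }
  grid_layer(matrix(acc / area, gl_nrow(target), gl_ncol(target)),
             target$xmin, target$ymin, target$cellsize, name = "density")
}

# Horn (third-order finite difference) surface gradient; returns list of
# dz/dx, dz/dy matrices with NA on cells lacking a full 3x3 neighborhood.
horn_gradient <- function(elev) {
  z <- elev$values
  cs <- elev$cellsize
  nr <- nrow(z); nc <- ncol(z)
  sh <- function(dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + dr; cs2 <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs2 >= 1 & cs2 <= nc
    out[ok_r, ok_c] <- z[rs[ok_r], cs2[ok_c]]
    out
  }
  a <- sh(-1, -1); b <- sh(-1, 0); cc <- sh(-1, 1)
  d <- sh(0, -1);                  f <- sh(0, 1)
  g <- sh(1, -1);  h <- sh(1, 0);  i <- sh(1, 1)
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cs) # north minus south
  list(dzdx = dzdx, dzdy = dzdy)
}

#' Slope from elevation
#'
#' Horn's method on the 3x3 neighborhood; border cells are NA.
#'
#' @param elev elevation `grid_layer`, meters
#' @return `grid_layer` of slope in degrees
#' @export
slope_from_elevation <- function(elev) {
  gr <- horn_gradient(elev)
  s <- atan(sqrt(gr$dzdx^2 + gr$dzdy^2)) * 180 / pi
  grid_layer(s, elev$xmin, elev$ymin, elev$cellsize, name = "slope")
}

#' Vector ruggedness measure (VRM)
#'
#' Terrain heterogeneity in \[0, 1\] from the dispersion of unit surface-normal
#' vectors within a moving window: each cell's normal is decomposed into
#' (x, y, z) components from its slope and aspect; VRM = 1 - |sum of normals|/n
#' over the window. Flat or uniformly inclined terrain gives 0; cells without a
#' full gradient neighborhood are excluded from the window sums.
#'
#' @param elev elevation `grid_layer`
#' @param window odd window size in cells, >= 3
#' @return `grid_layer` of VRM in \[0, 1\]
#' @export
vector_ruggedness <- function(elev, window = 3) {
  if (window < 3 || window %% 2 == 0) {
    stop2("vector_ruggedness: parameter error, window must be odd and >= 3")
  }
  gr <- horn_gradient(elev)
  slope <- atan(sqrt(gr$dzdx^2 + gr$dzdy^2))
  aspect <- atan2(-gr$dzdx, gr$dzdy)  # direction of steepest descent; any
                                      # consistent convention works for VRM
  xn <- sin(slope) * sin(aspect)
  yn <- sin(slope) * cos(aspect)
  zn <- cos(slope)
  valid <- !is.na(zn)
  z0 <- function(m) { m[!valid] <- 0; m }
  k <- matrix(1, window, window)
  sums <- focal_counts(list(v = valid), k)
  X <- conv2_same(z0(xn), k)
  Y <- conv2_same(z0(yn), k)
  Z <- conv2_same(z0(zn), k)
  n <- sums$v
  vrm <- 1 - sqrt(X^2 + Y^2 + Z^2) / n
  vrm[n == 0 | !valid] <- NA_real_
  vrm <- pmin(pmax(vrm, 0), 1)
  grid_layer(matrix(vrm, nrow(elev$values)), elev$xmin, elev$ymin,
             elev$cellsize, name = "vrm")
}

#' Fraction of a circular buffer burned within a 20-year window
#'
#' Per cell: the fraction of the circle of `radius_m` around the cell center
#' covered by the union of fire perimeters whose year falls in
#' `[query_year - window_years, query_year - 1]` — the one-year lag excludes
#' fires of the query year itself. Perimeters are rasterized on `fine` and the
#' coverage fraction is evaluated there, then resampled to `target`.
#'
#' @param fires list of fires, each `list(xy = 2-column matrix, year = integer)`
#' @param query_year year for which exposure is evaluated
#' @param radius_m buffer radius, meters
#' @param target output `grid_layer` template
#' @param fine fine `grid_layer` template used for rasterization
#'   (defaults to `target`)
#' @param window_years look-back window length, years
#' @return `grid_layer` of burned fractions on the `target` grid
#' @export
burned_fraction <- function(fires, query_year, radius_m, target, fine = target,
                            window_years = 20) {
  yrs <- vapply(fires, function(f) as.integer(f$year), integer(1))
  sel <- fires[yrs >= query_year - window_years & yrs <= query_year - 1]
  if (length(sel) == 0) {
    return(grid_layer(matrix(0, gl_nrow(target), gl_ncol(target)),
                      target$xmin, target$ymin, target$cellsize, name = "burned"))
  }
  mask <- rasterize_polygons(lapply(sel, `[[`, "xy"), fine)
  k <- disc_kernel(radius_m, fine$cellsize)
  cnt <- focal_counts(list(num = mask, den = matrix(TRUE, nrow(mask), ncol(mask))), k)
  frac <- grid_layer(cnt$num / cnt$den, fine$xmin, fine$ymin, fine$cellsize)
  out <- resample_to_grain(frac, target$cellsize)
  out$name <- "burned"
  out
}

season_months <- function(season) {
  switch(season,
         breeding = c(4L, 5L),
         summer = c(6L, 7L, 8L),
         winter = c(11L, 12L, 1L, 2L, 3L),
         stop2("unknown season '%s'", season))
}

#' Seasonal means of monthly climate normals
#'
#' Cellwise mean of the monthly grids over the season's months: April-May for
#' breeding, June-August for summer, November-March for winter.
#'
#' @param monthly list with components `precip`, `tmin`, `tmax`, each a list of
#'   12 monthly `grid_layer`s (January first)
#' @param season `"breeding"`, `"summer"`, or `"winter"`
#' @return list of three `grid_layer`s: `precip`, `tmin`, `tmax`
#' @export
seasonal_climate <- function(monthly, season) {
  months <- season_months(season)
  out <- lapply(c(precip = "precip", tmin = "tmin", tmax = "tmax"), function(vn) {
    grids <- monthly[[vn]]
    if (is.null(grids)) stop2("seasonal_climate: input error, missing variable '%s'", vn)
    miss <- months[months > length(grids)]
    if (length(miss) > 0 || any(vapply(grids[months], is.null, logical(1)))) {
      bad <- if (length(miss) > 0) miss[1] else months[which(vapply(grids[months], is.null, logical(1)))[1]]
      stop2("seasonal_climate: input error, missing month %d for '%s'", bad, vn)
    }
    tmpl <- grids[[months[1]]]
    acc <- Reduce(`+`, lapply(grids[months], `[[`, "values"))
    grid_layer(acc / length(months), tmpl$xmin, tmpl$ymin, tmpl$cellsize,
               name = paste0(vn, "_", season))
  })
  out
}

#' Epoch lookup for categorical cover
#'
#' A location recorded in year `y` uses the most recent cover epoch `<= y`;
#' years before the first epoch use the first.
#'
#' @param epochs sorted integer vector of epoch years
#' @param year integer vector of location years
#' @return integer vector of epoch years
#' @export
epoch_for_year <- function(epochs, year) {
  epochs <- sort(epochs)
  idx <- findInterval(year, epochs)
  epochs[pmax(idx, 1L)]
}

#' Build the full predictor set from a landscape stack
#'
#' Computes all 24 environmental predictor surfaces at the coarse (model)
#' grain: buffer proportions of the six cover groups per epoch, terrain, soils,
#' seasonal climate, burned fraction per location year, and feature densities.
#'
#' @param stack a `landscape_stack` from [generate_landscape()]
#' @param years integer vector of location years needing burned-fraction layers
#' @param seasons seasons to prepare climate for
#' @param radius_m landscape-context buffer radius, meters (default 5 km)
#' @param vrm_window VRM window size in (fine) cells
#' @return an object of class `predictor_set`
#' @export
build_predictors <- function(stack, years, seasons = c("breeding", "summer", "winter"),
                             radius_m = 5000, vrm_window = 3) {
  coarse_cell <- stack$coarse_cell
  groups <- stack$config$cover_codes$groups
  cover_groups <- c("sagebrush", "agriculture", "conifer", "developed",
                    "grassland", "riparian")

  log_msg("covariates", "cover buffer proportions (%d epochs, %d groups, r = %g m)",
          length(stack$fine$cover), length(cover_groups), radius_m)
  cover <- lapply(stack$fine$cover, function(cg) {
    k <- disc_kernel(radius_m, cg$cellsize)
    valid <- !is.na(cg$values)
    masks <- c(list(.valid = valid),
               lapply(groups[cover_groups], function(codes) {
                 valid & (cg$values %in% codes)
               }))
    cnt <- focal_counts(masks, k)
    out <- lapply(cover_groups, function(gname) {
      p <- cnt[[gname]] / cnt$.valid
      p[cnt$.valid == 0] <- NA_real_
      resample_to_grain(grid_layer(p, cg$xmin, cg$ymin, cg$cellsize, name = gname),
                        coarse_cell)
    })
    stats::setNames(out, cover_groups)
  })

  log_msg("covariates", "terrain (slope, VRM window %d)", vrm_window)
  elev_f <- stack$fine$elevation
  slope_f <- slope_from_elevation(elev_f)
  vrm_f <- vector_ruggedness(elev_f, vrm_window)
  terrain <- list(elevation = resample_to_grain(elev_f, coarse_cell),
                  slope = resample_to_grain(slope_f, coarse_cell),
                  ruggedness = resample_to_grain(vrm_f, coarse_cell))

  soil <- lapply(stack$fine$soil, resample_to_grain, coarse_cell = coarse_cell)

  climate <- lapply(stats::setNames(seasons, seasons), function(s) {
    lapply(seasonal_climate(stack$fine$climate, s), resample_to_grain,
           coarse_cell = coarse_cell)
  })

  template <- terrain$elevation
  years <- sort(unique(as.integer(years)))
  log_msg("covariates", "burned fraction for years %s", paste(years, collapse = ", "))
  burned <- lapply(stats::setNames(years, years), function(y) {
    burned_fraction(stack$vectors$fires, y, radius_m, template,
                    fine = elev_f, window_years = stack$config$fire_window_years)
  })

  log_msg("covariates", "feature densities (r = %g m)", radius_m)
  vec <- stack$vectors
  density <- list(
    road_secondary_density = feature_density(vec$roads_secondary, radius_m, template, "line"),
    highway_density = feature_density(vec$highways, radius_m, template, "line"),
    powerline_density = feature_density(vec$powerlines, radius_m, template, "line"),
    pipeline_density = feature_density(vec$pipelines, radius_m, template, "line"),
    tower_density = feature_density(vec$towers, radius_m, template, "point")
  )

  structure(list(cover = cover, terrain = terrain, soil = soil,
                 climate = climate, burned = burned, density = density,
                 epochs = as.integer(names(stack$fine$cover)),
                 radius_m = radius_m, template = template),
            class = "predictor_set")
}

#' @export
print.predictor_set <- function(x, ...) {
  cat(sprintf("<predictor_set> %d x %d cells of %g m; epochs %s; seasons %s; burn years %s\n",
              gl_nrow(x$template), gl_ncol(x$template), x$template$cellsize,
              paste(x$epochs, collapse = "/"),
              paste(names(x$climate), collapse = "/"),
              paste(names(x$burned), collapse = "/")))
  invisible(x)
}

# Fetch one named predictor layer for a given (year, season) context.
pset_layer <- function(pset, name, year = NULL, season = NULL) {
  cg <- c("sagebrush", "agriculture", "conifer", "developed", "grassland", "riparian")
  if (name %in% cg) {
    ep <- as.character(epoch_for_year(pset$epochs, year))
    return(pset$cover[[ep]][[name]])
  }
  if (name %in% names(pset$terrain)) return(pset$terrain[[name]])
  if (name %in% names(pset$soil)) return(pset$soil[[name]])
  if (name %in% c("precip", "tmin", "tmax")) return(pset$climate[[season]][[name]])
  if (name == "burned") {
    y <- as.character(year)
    if (!y %in% names(pset$burned)) {
      stop2("no burned-fraction layer prepared for year %s", y)
    }
    return(pset$burned[[y]])
  }
  if (name %in% names(pset$density)) return(pset$density[[name]])
  stop2("unknown predictor '%s'", name)
}

# Matrix of the 24 predictors over every coarse cell for one (year, season).
# Rows follow column-major matrix order of the template grid.
cell_predictor_matrix <- function(pset, year, season) {
  nm <- predictor_names()
  cols <- lapply(nm, function(p) as.vector(pset_layer(pset, p, year, season)$values))
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}
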