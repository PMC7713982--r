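test_that("identical config and seed reproduce the landscape exactly", {
  cfg <- landscape_config(extent = c(0, 6000, 0, 6000), fine_cell = 200)
  a <- generate_landscape(cfg, seed = 5)
  b <- generate_landscape(cfg, seed = 5)
  expect_identical(a$fine$elevation$values, b$fine$elevation$values)
  expect_identical(a$fine$cover[[1]]$values, b$fine$cover[[1]]$values)
  expect_identical(a$fine$climate$precip[[6]]$values, b$fine$climate$precip[[6]]$values)
  expect_identical(a$vectors, b$vectors)
  d <- generate_landscape(cfg, seed = 6)
  expect_false(identical(a$fine$elevation$values, d$fine$elevation$values))
})

test_that("zero elevation variance yields a constant elevation surface", {
  cfg <- landscape_config(extent = c(0, 4000, 0, 4000), fine_cell = 200,
                          elev_mean = 1500, elev_sd = 0, elev_smooth = 0)
  stack <- generate_landscape(cfg, seed = 1)
  expect_true(all(stack$fine$elevation$values == 1500))
})

test_that("configuration errors are rejected", {
  expect_error(landscape_config(extent = c(0, -10, 0, 10)), "configuration")
  expect_error(landscape_config(fine_cell = 0), "configuration")
})

test_that("temperature declines with elevation by construction", {
  stack <- fx_stack()
  elev <- as.vector(stack$fine$elevation$values)
  tmax <- as.vector(stack$fine$climate$tmax[[7]]$values)
  expect_gte(length(elev), 10000)
  expect_lt(stats::cor(elev, tmax), 0)
})

test_that("simulation produces the configured record counts", {
  truth <- selection_truth(c(sagebrush = 2),
                           site_centroids = rbind(c(10000, 10000), c(30000, 12000),
                                                  c(20000, 30000), c(28000, 28000)),
                           n_per_site_season_year = 50, years = c(2011L, 2012L),
                           n_lek_per_site_year = 2)
  locs <- suppressMessages(simulate_locations(fx_stack(), truth, seed = 7))
  vhf <- locs[locs$source == "vhf", ]
  lek <- locs[locs$source == "lek", ]
  # 50 x 4 sites x 3 seasons x 2 years
  expect_equal(nrow(vhf), 50 * 4 * 3 * 2)
  expect_equal(nrow(lek), 2 * 4 * 2)
  expect_false(any(duplicated(locs$id)))
  # every point inside the extent and its own site's Voronoi cell
  ext <- fx_stack()$extent
  expect_true(all(locs$x >= ext[1] & locs$x <= ext[2]))
  expect_true(all(locs$y >= ext[3] & locs$y <= ext[4]))
  expect_equal(assign_site(locs, truth$site_centroids), locs$site)
  # lek coordinates repeat at one cell per site and dates are in the window
  expect_lte(length(unique(paste(lek$x, lek$y))), 4)
  md <- as.integer(format(lek$date, "%m%d"))
  expect_true(all(md >= 401 & md <= 531))
})

test_that("zero selection gives spatially uniform use over the territory", {
  truth <- suppressWarnings(selection_truth(
    c(sagebrush = 0), site_centroids = cbind(20000, 20000),
    n_per_site_season_year = 5000, years = 2011L, n_lek_per_site_year = 0))
  locs <- suppressMessages(
    simulate_locations(fx_stack(), truth, seasons = "breeding", seed = 8,
                       predictors = fx_pset()))
  # single site: territory is the whole extent; chi-square over a 4x4 partition
  bx <- cut(locs$x, seq(0, 40000, length.out = 5))
  by <- cut(locs$y, seq(0, 40000, length.out = 5))
  p <- stats::chisq.test(table(bx, by))$p.value
  expect_gt(p, 0.01)
})

test_that("positive selection shifts used points toward the covariate", {
  locs <- fx_locs() # beta_sagebrush = +2, others 0
  pset <- fx_pset()
  sb <- pset$cover[[as.character(epoch_for_year(pset$epochs, 2011L))]]$sagebrush
  used_mean <- mean(gl_extract(sb, locs$x, locs$y), na.rm = TRUE)
  terr_mean <- mean(sb$values, na.rm = TRUE)
  expect_gt(used_mean, terr_mean)
})

test_that("analytic relative selection has its closed forms", {
  # beta = 0 -> surface identically 1
  X <- cbind(sagebrush = runif(100))
  expect_true(all(relative_selection(X, c(sagebrush = 0)) == 1))
  # row at the mean composition -> exactly 1
  X2 <- cbind(sagebrush = c(0.2, 0.4, 0.6), elevation = c(1800, 2000, 2200))
  beta <- c(sagebrush = 1.5, elevation = -0.01)
  rs <- relative_selection(X2, beta)
  expect_equal(rs[2], 1) # middle row is the mean of this symmetric design
  # single beta = ln 2 on a balanced 0/1 covariate -> values 2^(+/-0.5)
  X3 <- cbind(sagebrush = rep(c(0, 1), each = 50))
  rs3 <- relative_selection(X3, c(sagebrush = log(2)))
  expect_equal(sort(unique(rs3)), c(2^-0.5, 2^0.5))
})

test_that("truth surface is 1 everywhere under zero coefficients", {
  truth <- suppressWarnings(selection_truth(
    c(sagebrush = 0), site_centroids = cbind(20000, 20000), years = 2011L))
  tr <- suppressMessages(truth_rss(fx_stack(), truth, "breeding",
                                   predictors = fx_pset()))
  expect_true(all(tr$values[!is.na(tr$values)] == 1))
})

test_that("landscape export writes readable standard formats", {
  cfg <- landscape_config(extent = c(0, 4000, 0, 4000), fine_cell = 400,
                          n_towers = 3, n_fires = 2)
  stack <- generate_landscape(cfg, seed = 9)
  dir <- withr::local_tempdir()
  paths <- write_landscape(stack, dir)
  expect_true(all(file.exists(paths)))
  elev2 <- read_asc(file.path(dir, "elevation.asc"))
  expect_equal(elev2$values, stack$fine$elevation$values, tolerance = 1e-6)
  gj <- jsonlite::read_json(file.path(dir, "fires.geojson"))
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 2)
  expect_true(all(vapply(gj$features, function(f) !is.null(f$properties$year), logical(1))))
  meta <- yaml::read_yaml(file.path(dir, "landscape.yml"))
  expect_equal(meta$seed, 9)
})
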