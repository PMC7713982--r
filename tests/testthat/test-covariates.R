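test_that("focal proportion: uniform grids give 0 or 1 everywhere", {
  g1 <- grid_layer(matrix(1, 15, 15), cellsize = 30)
  expect_true(all(focal_proportion(g1, codes = 1, radius_m = 150)$values == 1))
  expect_true(all(focal_proportion(g1, codes = 2, radius_m = 150)$values == 0))
  expect_error(focal_proportion(g1, 1, radius_m = 10), "radius")
})

test_that("focal proportion matches a brute-force double loop on a 21x21 grid", {
  set.seed(11)
  v <- matrix(sample(1:4, 21 * 21, replace = TRUE), 21, 21)
  v[sample(441, 20)] <- NA # nodata speckle
  cs <- 30
  g <- grid_layer(v, cellsize = cs)
  radius <- 5 * cs
  got <- focal_proportion(g, codes = c(2, 3), radius_m = radius)
  expected <- matrix(NA_real_, 21, 21)
  for (r in 1:21) for (cc in 1:21) {
    num <- 0L; den <- 0L
    for (r2 in 1:21) for (c2 in 1:21) {
      if (((r - r2) * cs)^2 + ((cc - c2) * cs)^2 <= radius^2 && !is.na(v[r2, c2])) {
        den <- den + 1L
        if (v[r2, c2] %in% c(2, 3)) num <- num + 1L
      }
    }
    expected[r, cc] <- num / den
  }
  expect_equal(got$values, expected, tolerance = 1e-12)
})

test_that("focal proportions over a partition of all codes sum to one", {
  ct <- cover_code_table()
  cg <- fx_stack()$fine$cover[[1]]
  sub <- grid_layer(cg$values[1:60, 1:60], cellsize = cg$cellsize)
  total <- Reduce(`+`, lapply(ct$groups, function(codes) {
    focal_proportion(sub, codes, radius_m = 1000)$values
  }))
  expect_true(all(abs(total - 1) < 1e-9))
})

test_that("line density at a cell crossed by one straight line equals 2r / (pi r^2)", {
  g <- grid_layer(matrix(0, 21, 21), cellsize = 500)
  ctr <- c(21 * 500 / 2, 21 * 500 / 2) # center cell center (odd grid)
  r <- 5000
  line <- list(rbind(c(-20000, ctr[2]), c(30000, ctr[2]))) # long horizontal line
  d <- feature_density(line, r, g, type = "line")
  got <- gl_extract(d, ctr[1], ctr[2])
  expect_equal(got, 2 * r / (pi * r^2), tolerance = 1e-9)
  # linear in duplicated features
  d2 <- feature_density(c(line, line), r, g, type = "line")
  expect_equal(d2$values, 2 * d$values, tolerance = 1e-12)
  # no features -> zero
  expect_true(all(feature_density(list(), r, g, type = "line")$values == 0))
  expect_error(feature_density(line, -5, g), "radius")
})

test_that("line density matches a dense point-sampling oracle within 1%", {
  set.seed(12)
  g <- grid_layer(matrix(0, 9, 9), cellsize = 400)
  segs <- lapply(1:6, function(i) {
    p <- runif(2, 0, 3600); q <- p + runif(2, -2500, 2500)
    rbind(p, q)
  })
  r <- 1500
  d <- feature_density(segs, r, g, type = "line")
  centers <- gl_centers(g)
  # oracle: sample each segment every 0.25 m and count sample points in circle
  step <- 0.25
  est <- numeric(nrow(centers))
  for (s in segs) {
    L <- sqrt(sum((s[2, ] - s[1, ])^2))
    tt <- seq(0, 1, by = step / L)
    px <- s[1, 1] + tt * (s[2, 1] - s[1, 1])
    py <- s[1, 2] + tt * (s[2, 2] - s[1, 2])
    for (k in seq_len(nrow(centers))) {
      est[k] <- est[k] + sum((px - centers[k, 1])^2 + (py - centers[k, 2])^2 <= r^2) * step
    }
  }
  est <- est / (pi * r^2)
  nz <- est > 1e-7
  expect_true(any(nz))
  expect_lt(max(abs(d$values[nz] - est[nz]) / est[nz]), 0.01)
})

test_that("point density counts towers within the radius", {
  g <- grid_layer(matrix(0, 5, 5), cellsize = 1000)
  pts <- rbind(c(2500, 2500), c(2600, 2500), c(20000, 20000))
  d <- feature_density(pts, 3000, g, type = "point")
  expect_equal(gl_extract(d, 2500, 2500), 2 / (pi * 3000^2))
})

test_that("vector ruggedness is zero on flat and uniformly inclined planes", {
  flat <- grid_layer(matrix(1500, 9, 9), cellsize = 30)
  v <- vector_ruggedness(flat, 3)$values
  expect_true(all(abs(v[2:8, 2:8]) < 1e-12))
  xy <- outer(1:9, 1:9, function(i, j) 5 * i + 3 * j)
  incl <- grid_layer(xy * 1.0, cellsize = 30)
  v2 <- vector_ruggedness(incl, 3)$values
  expect_true(all(abs(v2[2:8, 2:8]) < 1e-12))
  expect_error(vector_ruggedness(flat, 4), "window")
  expect_error(vector_ruggedness(flat, 1), "window")
})

test_that("vector ruggedness matches an independent vector-sum computation", {
  set.seed(13)
  z <- matrix(rnorm(81, 2000, 15), 9, 9)
  cs <- 30
  g <- grid_layer(z, cellsize = cs)
  got <- vector_ruggedness(g, 3)$values
  # independent oracle: slope/aspect per cell by Horn differences, decompose
  # unit normals via sin/cos, window sums by explicit loops
  xn <- yn <- zn <- matrix(NA_real_, 9, 9)
  for (r in 2:8) for (cc in 2:8) {
    dzdx <- ((z[r - 1, cc + 1] + 2 * z[r, cc + 1] + z[r + 1, cc + 1]) -
               (z[r - 1, cc - 1] + 2 * z[r, cc - 1] + z[r + 1, cc - 1])) / (8 * cs)
    dzdy <- ((z[r - 1, cc - 1] + 2 * z[r - 1, cc] + z[r - 1, cc + 1]) -
               (z[r + 1, cc - 1] + 2 * z[r + 1, cc] + z[r + 1, cc + 1])) / (8 * cs)
    slope <- atan(sqrt(dzdx^2 + dzdy^2))
    aspect <- atan2(-dzdx, dzdy)
    xn[r, cc] <- sin(slope) * sin(aspect)
    yn[r, cc] <- sin(slope) * cos(aspect)
    zn[r, cc] <- cos(slope)
  }
  expected <- matrix(NA_real_, 9, 9)
  for (r in 1:9) for (cc in 1:9) {
    rs <- max(1, r - 1):min(9, r + 1)
    cs2 <- max(1, cc - 1):min(9, cc + 1)
    xs <- xn[rs, cs2]; ok <- !is.na(xs)
    n <- sum(ok)
    if (n == 0 || is.na(zn[r, cc])) next
    expected[r, cc] <- 1 - sqrt(sum(xn[rs, cs2][ok])^2 + sum(yn[rs, cs2][ok])^2 +
                                  sum(zn[rs, cs2][ok])^2) / n
  }
  comparable <- !is.na(expected)
  expect_true(any(comparable))
  expect_equal(got[comparable], expected[comparable], tolerance = 1e-9)
  expect_true(all(got >= 0 & got <= 1, na.rm = TRUE))
})

test_that("ruggedness increases with added surface roughness", {
  set.seed(14)
  base <- matrix(2000 + 5 * sin(outer(1:30, 1:30, `+`)), 30, 30)
  rough <- base + matrix(rnorm(900, 0, 25), 30, 30)
  g1 <- vector_ruggedness(grid_layer(base, cellsize = 30), 3)$values
  g2 <- vector_ruggedness(grid_layer(rough, cellsize = 30), 3)$values
  expect_gt(mean(g2, na.rm = TRUE), mean(g1, na.rm = TRUE))
})

test_that("burned fraction honors the 20-year window and one-year lag", {
  g <- grid_layer(matrix(0, 20, 20), cellsize = 500)
  fire <- list(list(xy = rbind(c(2000, 2000), c(8000, 2000), c(8000, 8000),
                               c(2000, 8000)), year = 2005L))
  r <- 2000
  expect_true(all(burned_fraction(list(), 2010, r, g)$values == 0))
  # query the fire's own year: excluded by the one-year lag
  expect_true(all(burned_fraction(fire, 2005, r, g)$values == 0))
  # one year later: positive where the circle overlaps the perimeter
  b <- burned_fraction(fire, 2006, r, g)
  expect_gt(gl_extract(b, 5000, 5000), 0.9)
  expect_equal(gl_extract(b, 9750, 9750), 0)
  # beyond the 20-year window: gone again
  expect_true(all(burned_fraction(fire, 2026, r, g)$values == 0))
  expect_gt(max(burned_fraction(fire, 2025, r, g)$values), 0)
})

test_that("a half-plane burn gives fraction one half at the boundary", {
  fine <- grid_layer(matrix(0, 200, 200), cellsize = 50)
  fire <- list(list(xy = rbind(c(-1000, -1000), c(5000, -1000), c(5000, 11000),
                               c(-1000, 11000)), year = 2000L))
  b <- burned_fraction(fire, 2001, 2000, fine, fine = fine)
  expect_equal(gl_extract(b, 5025, 5025), 0.5, tolerance = 0.02)
})

test_that("seasonal climate averages exactly the season's months", {
  g <- function(x) grid_layer(matrix(x, 4, 4), cellsize = 1000)
  monthly <- list(precip = lapply(1:12, g), tmin = lapply(1:12, g),
                  tmax = lapply(1:12, g))
  # all months constant at month index: breeding = mean(4, 5)
  br <- seasonal_climate(monthly, "breeding")
  expect_true(all(br$precip$values == mean(c(4, 5))))
  expect_true(all(seasonal_climate(monthly, "summer")$tmax$values == 7))
  expect_true(all(seasonal_climate(monthly, "winter")$tmin$values == mean(c(11, 12, 1, 2, 3))))
  # April = 2, May = 4 -> breeding mean 3
  monthly2 <- monthly
  monthly2$precip[[4]] <- g(2); monthly2$precip[[5]] <- g(4)
  expect_true(all(seasonal_climate(monthly2, "breeding")$precip$values == 3))
  # winter is insensitive to October but sensitive to November
  m_oct <- monthly; m_oct$tmax[[10]] <- g(99)
  m_nov <- monthly; m_nov$tmax[[11]] <- g(99)
  w0 <- seasonal_climate(monthly, "winter")$tmax$values
  expect_equal(seasonal_climate(m_oct, "winter")$tmax$values, w0)
  expect_false(isTRUE(all.equal(seasonal_climate(m_nov, "winter")$tmax$values, w0)))
  # a missing month is reported by name
  m_bad <- monthly; m_bad$tmin[[12]] <- NULL
  expect_error(seasonal_climate(m_bad, "winter"), "12")
})

test_that("epoch lookup takes the most recent epoch at or before the year", {
  epochs <- c(2001L, 2008L, 2010L, 2012L)
  expect_equal(epoch_for_year(epochs, c(1998, 2001, 2007, 2008, 2011, 2030)),
               c(2001L, 2001L, 2001L, 2008L, 2010L, 2012L))
})
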