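# Shared fixtures, memoized so expensive objects are built once per test run.
# The unit-test landscape keeps the default 40 x 40 km extent (so the 5-km
# focal buffer is well interior) but at a 200-m fine grain for speed.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, suppressMessages(build()), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

fx_config <- function() landscape_config(fine_cell = 200)

fx_stack <- function() fx("stack", function() generate_landscape(fx_config(), seed = 101))

fx_truth <- function() {
  selection_truth(
    coefficients = c(sagebrush = 2),
    site_centroids = rbind(c(10000, 10000), c(30000, 12000), c(20000, 30000)),
    n_per_site_season_year = 100, years = 2011L, n_lek_per_site_year = 3
  )
}

fx_pset <- function() {
  fx("pset", function() build_predictors(fx_stack(), years = 2011L, seasons = "breeding"))
}

fx_locs <- function() {
  fx("locs", function() {
    simulate_locations(fx_stack(), fx_truth(), seasons = "breeding", seed = 102,
                       predictors = fx_pset())
  })
}

fx_design <- function() {
  fx("design", function() {
    tbl <- prepare_use_avail(fx_locs(), fx_truth()$site_centroids,
                             fx_stack()$extent, seed = 103)
    build_design_matrix(tbl, fx_pset())
  })
}

fx_cv <- function() {
  fx("cv", function() cross_validate(fx_design(), model_config(seed = 104)))
}

# A small self-contained design table with a known separable rule, for
# classifier-level tests that do not need the landscape machinery.
make_toy_table <- function(n = 400, seed = 1, rule = c("separable", "noise")) {
  rule <- match.arg(rule)
  set.seed(seed)
  nm <- predictor_names()
  X <- matrix(stats::runif(n * length(nm)), n, length(nm), dimnames = list(NULL, nm))
  lab <- if (rule == "separable") X[, "sagebrush"] > 0.5 else stats::runif(n) > 0.5
  # enforce exact class balance by flipping surplus rows farthest from the rule
  surplus <- sum(lab) - n %/% 2
  if (surplus != 0) {
    if (surplus > 0) {
      idx <- order(X[, "sagebrush"], decreasing = FALSE)
      idx <- idx[lab[idx]][seq_len(surplus)]
      lab[idx] <- FALSE
      X[idx, "sagebrush"] <- stats::runif(surplus, 0, 0.5)
    } else {
      idx <- order(X[, "sagebrush"], decreasing = TRUE)
      idx <- idx[!lab[idx]][seq_len(-surplus)]
      lab[idx] <- TRUE
      X[idx, "sagebrush"] <- stats::runif(-surplus, 0.5, 1)
    }
  }
  out <- data.frame(
    label = factor(ifelse(lab, "used", "available"), levels = c("available", "used")),
    year = factor(sample(c(2011, 2012), n, replace = TRUE)),
    site = factor(sample(1:3, n, replace = TRUE)),
    X
  )
  out$x <- stats::runif(n, 0, 1000)
  out$y <- stats::runif(n, 0, 1000)
  out$season <- "breeding"
  out$source <- "vhf"
  out
}

# Sutherland-Hodgman clipping of a convex region by a half-plane a.p <= b,
# used to build explicit Voronoi polygons as an independent geometric oracle.
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    p <- poly[i, ]
    q <- poly[if (i == n) 1 else i + 1, ]
    pin <- sum(a * p) <= b + 1e-9
    qin <- sum(a * q) <= b + 1e-9
    if (pin) out <- rbind(out, p)
    if (pin != qin) {
      t <- (b - sum(a * p)) / (sum(a * (q - p)))
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}

# Explicit Voronoi polygon of centroid i within a bounding rectangle.
voronoi_polygon <- function(centroids, i, extent) {
  poly <- rbind(c(extent[1], extent[3]), c(extent[2], extent[3]),
                c(extent[2], extent[4]), c(extent[1], extent[4]))
  ci <- centroids[i, ]
  for (j in seq_len(nrow(centroids))) {
    if (j == i) next
    cj <- centroids[j, ]
    # half-plane of points at least as close to ci as to cj:
    # 2 (cj - ci) . p <= |cj|^2 - |ci|^2
    a <- 2 * (cj - ci)
    b <- sum(cj^2) - sum(ci^2)
    poly <- clip_halfplane(poly, a, b)
    if (nrow(poly) < 3) break
  }
  poly
}
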