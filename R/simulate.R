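# Location simulator with known log-linear selection, and the analytic
# relative-selection surface it implies (the oracle for parameter recovery).

#' Define the ground-truth selection structure for simulation
#'
#' Used points are drawn within each site's territory (the Voronoi cell of its
#' centroid) with probability proportional to `exp(sum(beta * x))` over the
#' territory's model-grain cells.
#'
#' @param coefficients named numeric vector of log-linear selection weights on
#'   environmental predictors (see [predictor_names()]); either one vector for
#'   all seasons or a named list `season -> vector`. At least one coefficient
#'   must be nonzero.
#' @param site_centroids 2-column matrix of site centroids, meters
#' @param n_per_site_season_year VHF used points per site x season x year
#' @param years integer vector of sampling years
#' @param n_lek_per_site_year lek records per site and year (breeding only)
#' @return list of class `selection_truth`
#' @export
selection_truth <- function(coefficients,
                            site_centroids,
                            n_per_site_season_year = 50,
                            years = c(2011L, 2012L),
                            n_lek_per_site_year = 5) {
  coefs <- if (is.list(coefficients)) coefficients else
    list(breeding = coefficients, summer = coefficients, winter = coefficients)
  for (s in names(coefs)) {
    bad <- setdiff(names(coefs[[s]]), predictor_names())
    if (length(bad) > 0) stop2("selection_truth: unknown predictor(s): %s", paste(bad, collapse = ", "))
  }
  if (all(vapply(coefs, function(b) all(b == 0), logical(1)))) {
    warning("selection_truth: all coefficients are zero (uniform use)")
  }
  structure(list(coefficients = coefs,
                 site_centroids = as.matrix(site_centroids),
                 n_per_site_season_year = n_per_site_season_year,
                 years = as.integer(years),
                 n_lek_per_site_year = n_lek_per_site_year),
            class = "selection_truth")
}

season_window_dates <- function(season, year) {
  switch(season,
         breeding = c(as.Date(sprintf("%d-04-01", year)), as.Date(sprintf("%d-05-31", year))),
         summer = c(as.Date(sprintf("%d-06-01", year)), as.Date(sprintf("%d-08-31", year))),
         winter = c(as.Date(sprintf("%d-11-15", year)), as.Date(sprintf("%d-03-15", year + 1))),
         stop2("unknown season '%s'", season))
}

# linear predictor eta = X beta for the named coefficients (unnamed ones 0)
lin_pred <- function(X, beta) {
  eta <- rep(0, nrow(X))
  for (nm in names(beta)) eta <- eta + beta[[nm]] * X[, nm]
  eta
}

#' Simulate telemetry and lek locations with known selection
#'
#' For every site, year, and season, draws the configured number of VHF used
#' points among the site territory's model-grain cells with probability
#' proportional to `exp(sum(beta * x))`, placing each point uniformly within
#' its cell and dating it uniformly within the season window. One lek per site
#' is placed at the site's highest breeding-selection cell (top 1% by
#' construction) and contributes dated breeding records each year.
#'
#' @param stack a `landscape_stack`
#' @param truth a `selection_truth`
#' @param seasons seasons to simulate
#' @param seed integer seed
#' @param predictors optional pre-built `predictor_set` (rebuilt if NULL)
#' @return data frame of `LocationRecord`s: `id`, `x`, `y`, `date`, `source`
#'   (`"vhf"`/`"lek"`), `site` (true site index)
#' @export
simulate_locations <- function(stack, truth,
                               seasons = c("breeding", "summer", "winter"),
                               seed = 1, predictors = NULL) {
  ext <- stack$extent
  ctr <- truth$site_centroids
  if (any(ctr[, 1] < ext[1] | ctr[, 1] > ext[2] |
          ctr[, 2] < ext[3] | ctr[, 2] > ext[4])) {
    stop2("simulate_locations: site centroid outside the landscape extent")
  }
  if (is.null(predictors)) {
    predictors <- build_predictors(stack, years = truth$years, seasons = seasons)
  }
  tmpl <- predictors$template
  centers <- gl_centers(tmpl)
  cell_site <- assign_site(centers, ctr)
  cs <- tmpl$cellsize

  set.seed(derive_seed(seed, 7))
  rows <- list()
  id <- 0L
  for (season in seasons) {
    for (year in truth$years) {
      X <- cell_predictor_matrix(predictors, year, season)
      eta <- lin_pred(X, truth$coefficients[[season]])
      ok_cell <- stats::complete.cases(X)
      for (s in seq_len(nrow(ctr))) {
        cells <- which(cell_site == s & ok_cell)
        if (length(cells) == 0) {
          stop2("simulate_locations: simulation error, empty territory for site %d", s)
        }
        w <- exp(eta[cells] - max(eta[cells]))
        n <- truth$n_per_site_season_year
        pick <- cells[sample.int(length(cells), n, replace = TRUE, prob = w)]
        px <- centers[pick, 1] + stats::runif(n, -cs / 2, cs / 2)
        py <- centers[pick, 2] + stats::runif(n, -cs / 2, cs / 2)
        # jitter must not carry a point across the Voronoi boundary: site
        # labels are defined by nearest centroid, so redraw strays (cell
        # centers themselves always qualify)
        for (try in 1:20) {
          stray <- assign_site(cbind(px, py), ctr) != s
          if (!any(stray)) break
          px[stray] <- centers[pick[stray], 1] + stats::runif(sum(stray), -cs / 2, cs / 2)
          py[stray] <- centers[pick[stray], 2] + stats::runif(sum(stray), -cs / 2, cs / 2)
        }
        stray <- assign_site(cbind(px, py), ctr) != s
        px[stray] <- centers[pick[stray], 1]
        py[stray] <- centers[pick[stray], 2]
        win <- season_window_dates(season, year)
        dates <- win[1] + sample.int(as.integer(win[2] - win[1]) + 1L, n, replace = TRUE) - 1L
        rows[[length(rows) + 1]] <- data.frame(
          id = id + seq_len(n), x = px, y = py, date = dates,
          source = "vhf", site = s)
        id <- id + n
      }
    }
  }

  # leks: one per site at the top breeding-selection cell, records each year
  if ("breeding" %in% seasons && truth$n_lek_per_site_year > 0) {
    year0 <- max(truth$years)
    X <- cell_predictor_matrix(predictors, year0, "breeding")
    eta <- lin_pred(X, truth$coefficients[["breeding"]])
    ok_cell <- stats::complete.cases(X)
    for (s in seq_len(nrow(ctr))) {
      cells <- which(cell_site == s & ok_cell)
      top <- cells[which.max(eta[cells])]
      for (year in truth$years) {
        n <- truth$n_lek_per_site_year
        win <- season_window_dates("breeding", year)
        dates <- win[1] + sample.int(as.integer(win[2] - win[1]) + 1L, n, replace = TRUE) - 1L
        rows[[length(rows) + 1]] <- data.frame(
          id = id + seq_len(n), x = rep(centers[top, 1], n),
          y = rep(centers[top, 2], n), date = dates,
          source = "lek", site = s)
        id <- id + n
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Centered log-linear relative selection
#'
#' `exp(beta . (x - xbar))`: the analytic relative-selection value of each row
#' of `X` against the mean composition of the valid rows.
#'
#' @param X numeric matrix with named columns covering `names(beta)`
#' @param beta named numeric coefficient vector
#' @return numeric vector, 1 at the mean composition
#' @export
relative_selection <- function(X, beta) {
  eta <- lin_pred(X, beta)
  ok <- stats::complete.cases(X[, names(beta), drop = FALSE])
  exp(eta - mean(eta[ok]))
}

#' Analytic relative-selection surface implied by the simulation truth
#'
#' The oracle surface for parameter recovery: per model-grain cell,
#' `exp(beta . (x - xbar))` with `xbar` the mean over valid cells.
#'
#' @param stack a `landscape_stack`
#' @param truth a `selection_truth`
#' @param season season whose coefficients and climate apply
#' @param predictors optional pre-built `predictor_set`
#' @param year year used for epoch/burn context (default: last truth year)
#' @return `grid_layer` of relative selection (1 at mean conditions)
#' @export
truth_rss <- function(stack, truth, season, predictors = NULL, year = NULL) {
  if (is.null(predictors)) {
    predictors <- build_predictors(stack, years = truth$years, seasons = season)
  }
  year <- year %||% max(truth$years)
  beta <- truth$coefficients[[season]]
  if (is.null(beta)) stop2("truth_rss: no coefficients defined for season '%s'", season)
  X <- cell_predictor_matrix(predictors, year, season)
  rss <- relative_selection(X, beta)
  rss[!stats::complete.cases(X)] <- NA_real_
  tmpl <- predictors$template
  grid_layer(matrix(rss, gl_nrow(tmpl)), tmpl$xmin, tmpl$ymin, tmpl$cellsize,
             name = paste0("truth_rss_", season))
}
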