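# Relative selection strength (RSS): prediction surfaces normalized by the
# probability of use of a hypothetical pixel at mean conditions, fold
# averaging, the year-round habitat rule, and single-predictor response
# curves.

# Mean composition of the 24 predictors over valid cells (seasonal climate for
# the climate variables), as a one-row design table with the categorical
# year/site at the model's modal training category.
reference_row <- function(model, pset, season, year) {
  X <- cell_predictor_matrix(pset, year, season)
  mu <- colMeans(X, na.rm = TRUE)
  out <- data.frame(t(mu))
  out$year <- factor(model$modal_year)
  out$site <- factor(model$modal_site)
  out
}

#' Probability of use at mean conditions
#'
#' The predicted probability of use of a hypothetical pixel whose 24
#' environmental predictors all sit at their mean over the valid cells of the
#' mapped region (seasonal means for climate) and whose categorical year/site
#' are the modal training categories. Deterministic given the model; clamped
#' into (0, 1).
#'
#' @param model an `rsf_forest`
#' @param pset a `predictor_set`
#' @param season season being mapped
#' @param year year context for epoch/burn layers (default: modal training year)
#' @return scalar reference probability in (0, 1)
#' @export
reference_probability <- function(model, pset, season, year = NULL) {
  year <- year %||% as.integer(model$modal_year)
  ref <- reference_row(model, pset, season, year)
  as.numeric(predict_prob(model, ref))
}

#' Relative selection strength surface
#'
#' Per cell: predicted probability of use divided by the reference
#' probability. Values above 1 indicate selection over average conditions,
#' below 1 avoidance.
#'
#' @inheritParams reference_probability
#' @param fold fold identifier stored on the layer
#' @return object of class `rss_layer`: `season`, `rss` (`grid_layer`),
#'   `reference_probability`, `fold`
#' @export
rss_surface <- function(model, pset, season, year = NULL, fold = NA) {
  year <- year %||% as.integer(model$modal_year)
  p_ref <- reference_probability(model, pset, season, year)
  X <- cell_predictor_matrix(pset, year, season)
  ok <- stats::complete.cases(X)
  p <- rep(NA_real_, nrow(X))
  if (any(ok)) {
    enc <- cbind(X[ok, , drop = FALSE],
                 encode_design(data.frame(year = factor(model$modal_year),
                                          site = factor(model$modal_site))[rep(1, sum(ok)), , drop = FALSE],
                               list(numeric = character(0), factors = model$registry$factors)))
    p[ok] <- predict_prob(model, enc)
  }
  tmpl <- pset$template
  structure(list(season = season,
                 rss = grid_layer(matrix(p / p_ref, gl_nrow(tmpl)),
                                  tmpl$xmin, tmpl$ymin, tmpl$cellsize,
                                  name = paste0("rss_", season)),
                 reference_probability = p_ref,
                 fold = fold),
            class = "rss_layer")
}

#' @export
print.rss_layer <- function(x, ...) {
  rng <- range(x$rss$values, na.rm = TRUE)
  cat(sprintf("<rss_layer> season %s, fold %s; p_ref %.4f; RSS in [%.3f, %.3f]\n",
              x$season, as.character(x$fold), x$reference_probability,
              rng[1], rng[2]))
  invisible(x)
}

#' Average RSS surfaces across folds
#'
#' Cellwise arithmetic mean of aligned same-season fold surfaces.
#'
#' @param layers list of `rss_layer`s
#' @return an `rss_layer` with `fold = "mean"`
#' @export
mean_across_folds <- function(layers) {
  if (length(layers) == 0) stop2("mean_across_folds: no layers")
  g1 <- layers[[1]]$rss
  for (l in layers[-1]) {
    if (!gl_same_grid(l$rss, g1)) stop2("mean_across_folds: misaligned grids")
    if (l$season != layers[[1]]$season) stop2("mean_across_folds: mixed seasons")
  }
  vals <- Reduce(`+`, lapply(layers, function(l) l$rss$values)) / length(layers)
  structure(list(season = layers[[1]]$season,
                 rss = grid_layer(vals, g1$xmin, g1$ymin, g1$cellsize, name = g1$name),
                 reference_probability = mean(vapply(layers, `[[`, numeric(1),
                                                     "reference_probability")),
                 fold = "mean"),
            class = "rss_layer")
}

#' Year-round habitat mask
#'
#' A pixel is habitat (1) when its fold-mean RSS exceeds 1 in at least one
#' season, and nonhabitat (0) when all seasons are at or below 1 — i.e. the
#' union of the per-season exceedance masks.
#'
#' @param seasonal named list of fold-mean `rss_layer`s for `breeding`,
#'   `summer`, and `winter`
#' @return binary `grid_layer` (1 habitat, 0 nonhabitat, NA nodata)
#' @export
annual_habitat <- function(seasonal) {
  need <- c("breeding", "summer", "winter")
  miss <- setdiff(need, names(seasonal))
  if (length(miss) > 0) {
    stop2("annual_habitat: missing season(s): %s", paste(miss, collapse = ", "))
  }
  g1 <- seasonal[[need[1]]]$rss
  acc <- matrix(FALSE, nrow(g1$values), ncol(g1$values))
  anyna <- matrix(FALSE, nrow(g1$values), ncol(g1$values))
  for (s in need) {
    v <- seasonal[[s]]$rss$values
    if (!gl_same_grid(seasonal[[s]]$rss, g1)) stop2("annual_habitat: misaligned grids")
    acc <- acc | (!is.na(v) & v > 1)
    anyna <- anyna | is.na(v)
  }
  out <- matrix(as.numeric(acc), nrow(acc))
  out[anyna & !acc] <- NA_real_ # undetermined only if no season exceeds 1
  grid_layer(out, g1$xmin, g1$ymin, g1$cellsize, name = "annual_habitat")
}

#' Single-predictor response curve
#'
#' RSS across the observed range of one continuous predictor, all other
#' predictors held at their mean (seasonal means for climate) and categorical
#' year/site at the modal training category, normalized by the same reference
#' probability — so the curve passes through 1 at the predictor's mean.
#'
#' @param model an `rsf_forest`
#' @param pset a `predictor_set`
#' @param predictor one of [predictor_names()]
#' @param season season context
#' @param n_points evaluation grid size
#' @param year year context (default modal training year)
#' @return `response_curve` data frame: `predictor`, `value`, `rss`, with the
#'   reference value and probability as attributes
#' @export
response_curve <- function(model, pset, predictor, season, n_points = 50,
                           year = NULL) {
  if (!predictor %in% predictor_names()) {
    stop2("response_curve: unknown predictor '%s'", predictor)
  }
  year <- year %||% as.integer(model$modal_year)
  X <- cell_predictor_matrix(pset, year, season)
  mu <- colMeans(X, na.rm = TRUE)
  rng <- range(X[, predictor], na.rm = TRUE)
  if (diff(rng) == 0) {
    stop2("response_curve: predictor '%s' is constant, no range to sweep", predictor)
  }
  vals <- seq(rng[1], rng[2], length.out = n_points)
  sweep_X <- matrix(mu, nrow = n_points, ncol = length(mu), byrow = TRUE,
                    dimnames = list(NULL, names(mu)))
  sweep_X[, predictor] <- vals
  fac <- encode_design(
    data.frame(year = factor(model$modal_year),
               site = factor(model$modal_site))[rep(1, n_points), , drop = FALSE],
    list(numeric = character(0), factors = model$registry$factors))
  p <- predict_prob(model, cbind(sweep_X, fac))
  p_ref <- reference_probability(model, pset, season, year)
  out <- data.frame(predictor = predictor, value = vals, rss = p / p_ref)
  attr(out, "reference_value") <- unname(mu[predictor])
  attr(out, "reference_probability") <- p_ref
  class(out) <- c("response_curve", "data.frame")
  out
}

#' Fold-averaged response curve
#'
#' Evaluates [response_curve()] for every fold model of a cross-validation
#' run on a common value grid and averages the RSS pointwise — the
#' fold-averaged response presentation.
#'
#' @param cv a `cv_result`
#' @param pset a `predictor_set`
#' @param predictor predictor to sweep
#' @param season season context
#' @param n_points evaluation grid size
#' @return `response_curve` data frame of the fold-mean RSS, with per-fold
#'   curves in attribute `"folds"`
#' @export
cv_response_curve <- function(cv, pset, predictor, season, n_points = 50) {
  curves <- lapply(cv$folds, function(f) {
    response_curve(f$model, pset, predictor, season, n_points)
  })
  out <- curves[[1]]
  out$rss <- rowMeans(vapply(curves, `[[`, numeric(n_points), "rss"))
  attr(out, "folds") <- curves
  out
}
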