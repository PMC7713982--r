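# Seeded synthetic experiments used for model checking: single-covariate
# parameter recovery against the analytic truth surface, and calibration of a
# well-specified model at a larger sample size.

#' Single-covariate parameter recovery experiment
#'
#' Simulates one breeding season with selection on sagebrush only
#' (log-linear coefficient +2), runs leave-one-site-out cross-validation, and
#' measures (a) the MDI rank of sagebrush among the 26 predictors and (b) the
#' Spearman concordance of the fold-averaged sagebrush response curve with the
#' analytic relative-selection curve `exp(beta (x - xbar))`.
#'
#' @param seed integer seed (drives landscape, locations, sampling, fitting)
#' @param beta selection coefficient on sagebrush
#' @param landscape a `landscape_config`
#' @return list: `sagebrush_rank`, `response_spearman`, `n_used`,
#'   `importance`, `curve`
#' @export
recovery_experiment <- function(seed, beta = 2, landscape = landscape_config()) {
  stack <- generate_landscape(landscape, seed = derive_seed(seed, 61))
  ext <- landscape$extent
  sx <- ext[1] + (ext[2] - ext[1]) * c(0.25, 0.75, 0.5)
  sy <- ext[3] + (ext[4] - ext[3]) * c(0.25, 0.3, 0.75)
  truth <- selection_truth(c(sagebrush = beta), cbind(sx, sy),
                           n_per_site_season_year = 120, years = 2011L,
                           n_lek_per_site_year = 3)
  pset <- build_predictors(stack, years = 2011L, seasons = "breeding")
  locs <- simulate_locations(stack, truth, "breeding",
                             seed = derive_seed(seed, 62), predictors = pset)
  tbl <- prepare_use_avail(locs, truth$site_centroids, stack$extent,
                           seed = derive_seed(seed, 63))
  design <- build_design_matrix(tbl, pset)
  cv <- cross_validate(design, model_config(seed = derive_seed(seed, 64)))
  imp <- importance_mdi(lapply(cv$folds, `[[`, "model"))
  curve <- cv_response_curve(cv, pset, "sagebrush", "breeding")
  truth_curve <- exp(beta * (curve$value - attr(curve, "reference_value")))
  list(sagebrush_rank = imp$rank[imp$predictor == "sagebrush"],
       response_spearman = stats::cor(curve$rss, truth_curve, method = "spearman"),
       n_used = sum(design$label == "used"),
       importance = imp, curve = curve)
}

#' Calibration of a well-specified model at larger sample size
#'
#' Simulates one breeding season under the default selection truth with about
#' 2,000 used points, runs leave-one-site-out cross-validation, and returns
#' the seasonal calibration statistic (Spearman rho of the fold-mean
#' expected/observed curve) together with the design table, so label
#' permutation nulls can reuse the same data.
#'
#' @param seed integer seed
#' @param n_per_site_season_year used points per site x year (default 250,
#'   giving about 2,000 used points over 4 sites x 2 years)
#' @param landscape a `landscape_config`
#' @return list: `season_rho`, `fold_rho`, `oob_error`, `n_used`, `design`,
#'   `cv`
#' @export
calibration_experiment <- function(seed, n_per_site_season_year = 250,
                                   landscape = landscape_config()) {
  stack <- generate_landscape(landscape, seed = derive_seed(seed, 71))
  truth <- default_truth(n_per_site_season_year = n_per_site_season_year)
  pset <- build_predictors(stack, years = truth$years, seasons = "breeding")
  locs <- simulate_locations(stack, truth, "breeding",
                             seed = derive_seed(seed, 72), predictors = pset)
  tbl <- prepare_use_avail(locs, truth$site_centroids, stack$extent,
                           seed = derive_seed(seed, 73))
  design <- build_design_matrix(tbl, pset)
  cv <- cross_validate(design, model_config(seed = derive_seed(seed, 74)))
  cal <- cv_calibration(cv)
  list(season_rho = cal$season_rho, fold_rho = cal$rho,
       oob_error = used_class_error(pooled_confusion(cv)$oob),
       n_used = sum(design$label == "used"),
       design = design, cv = cv)
}

#' Out-of-bag error under label permutation
#'
#' Shuffles the use/availability labels of a design table (preserving exact
#' class balance) and refits the forest: the used-class out-of-bag error of an
#' uninformative model concentrates at 0.5.
#'
#' Note that out-of-bag error under permutation is unbiased only when
#' predictor rows are distinct. Landscape design tables hold many duplicated
#' rows (locations sharing a model-grain cell), which biases out-of-bag votes
#' away from the held-out row's label and pushes the permuted error a few
#' points above 0.5; use [noise_design()] for a clean classifier-level null.
#'
#' @param design a design table (e.g. from [build_design_matrix()] or
#'   [noise_design()])
#' @param seed integer seed for the permutation and refit
#' @return used-class out-of-bag error of the permuted fit
#' @export
permutation_null <- function(design, seed) {
  set.seed(derive_seed(seed, 81))
  design$label <- sample(design$label)
  fit <- fit_forest(design, model_config(seed = derive_seed(seed, 82)))
  used_class_error(fit$oob_confusion)
}

#' Balanced design table with independent continuous predictors
#'
#' A class-balanced use-availability table whose 24 environmental predictors
#' are independent uniform draws (labels carry no signal beyond what is
#' injected downstream). Used as the clean fixture for classifier-level null
#' checks where duplicated predictor rows would bias out-of-bag estimates.
#'
#' @param n number of rows (must be even)
#' @param seed integer seed
#' @return a design table compatible with [fit_forest()]
#' @export
noise_design <- function(n, seed) {
  if (n %% 2 != 0) stop2("noise_design: n must be even for exact balance")
  set.seed(derive_seed(seed, 83))
  nm <- predictor_names()
  X <- matrix(stats::runif(n * length(nm)), n, length(nm),
              dimnames = list(NULL, nm))
  data.frame(
    label = factor(rep(c("available", "used"), n / 2),
                   levels = c("available", "used")),
    year = factor(sample(c(2011, 2012), n, replace = TRUE)),
    site = factor(sample(1:3, n, replace = TRUE)),
    X, season = "breeding", source = "vhf"
  )
}
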