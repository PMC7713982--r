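# Use-vs-availability random-forest classifier: design matrix construction,
# one-hot encoding of the categorical year/site predictors, fitting with the
# study hyperparameters, mtry tuning, and Gini (MDI) importance.

#' Model configuration
#'
#' Defaults follow the study protocol: 1,000 trees, minimum node size 1, and
#' mtry = 5 (about the square root of the 26 predictors).
#'
#' @param n_trees number of trees
#' @param min_node_size minimum terminal node size
#' @param m_try variables tried at each split
#' @param seed integer seed for fitting
#' @return list of class `model_config`
#' @export
model_config <- function(n_trees = 1000, min_node_size = 1, m_try = 5, seed = 1) {
  if (m_try < 1) stop2("model_config: m_try must be >= 1")
  structure(list(n_trees = n_trees, min_node_size = min_node_size,
                 m_try = m_try, seed = as.integer(seed)),
            class = "model_config")
}

#' Build the use-availability design matrix
#'
#' One row per location carrying the 24 environmental predictors sampled at
#' the model-grain cell containing the point — the cover layers chosen by the
#' location's calendar year via epoch lookup, burned fraction by year, climate
#' by the row's season — plus `year` and `site` as categorical predictors and
#' the use label. Rows falling on nodata are dropped with a logged count.
#'
#' @param locations labeled table from [prepare_use_avail()]
#' @param pset a `predictor_set`
#' @return `UseAvailTable` data frame: `label`, `year`, `site`, the 24
#'   predictors, and bookkeeping columns `x`, `y`, `season`, `source`
#' @export
build_design_matrix <- function(locations, pset) {
  nm <- predictor_names()
  n <- nrow(locations)
  vals <- matrix(NA_real_, n, length(nm), dimnames = list(NULL, nm))
  cal_year <- locations$cal_year %||% locations$year
  key <- interaction(cal_year, locations$year, locations$season, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    r <- locations[idx[1], ]
    for (p in nm) {
      layer <- pset_layer(pset, p, year = if (p == "burned") r$year else cal_year[idx[1]],
                          season = r$season)
      vals[idx, p] <- gl_extract(layer, locations$x[idx], locations$y[idx])
    }
  }
  ok <- stats::complete.cases(vals)
  if (any(!ok)) log_msg("design", "dropped %d row(s) on nodata cells", sum(!ok))
  out <- data.frame(
    label = locations$label[ok],
    year = factor(locations$year[ok]),
    site = factor(locations$site[ok]),
    vals[ok, , drop = FALSE],
    x = locations$x[ok], y = locations$y[ok],
    season = locations$season[ok],
    source = locations$source[ok]
  )
  rownames(out) <- NULL
  out
}

# One-hot encoding registry: numeric predictors pass through; each factor
# level becomes an indicator column "<factor>__<level>". Prediction rows with
# a category absent from the registry get all-zero indicators, which is the
# spatial-transfer semantics for held-out sites.
encoding_registry <- function(tbl) {
  list(numeric = predictor_names(),
       factors = list(year = levels(droplevels(tbl$year)),
                      site = levels(droplevels(tbl$site))))
}

encode_design <- function(tbl, registry) {
  blocks <- list(as.matrix(tbl[, registry$numeric, drop = FALSE]))
  for (f in names(registry$factors)) {
    lv <- registry$factors[[f]]
    m <- matrix(0, nrow(tbl), length(lv),
                dimnames = list(NULL, paste0(f, "__", lv)))
    hit <- match(as.character(tbl[[f]]), lv)
    ok <- !is.na(hit)
    m[cbind(which(ok), hit[ok])] <- 1
    blocks[[length(blocks) + 1]] <- m
  }
  do.call(cbind, blocks)
}

#' Confusion counts for the use-availability classifier
#'
#' @param used_correct,used_wrong,avail_correct,avail_wrong nonnegative counts
#' @return named integer vector of class `confusion_counts`; these add with
#'   `+` when pooling folds
#' @export
confusion_counts <- function(used_correct = 0, used_wrong = 0,
                             avail_correct = 0, avail_wrong = 0) {
  v <- c(used_correct = used_correct, used_wrong = used_wrong,
         avail_correct = avail_correct, avail_wrong = avail_wrong)
  if (any(v < 0)) stop2("confusion_counts: counts must be nonnegative")
  structure(v, class = "confusion_counts")
}

#' @export
`+.confusion_counts` <- function(e1, e2) {
  structure(unclass(e1) + unclass(e2), class = "confusion_counts")
}

confusion_from <- function(label, pred_used) {
  used <- label == "used"
  confusion_counts(used_correct = sum(used & pred_used),
                   used_wrong = sum(used & !pred_used),
                   avail_correct = sum(!used & !pred_used),
                   avail_wrong = sum(!used & pred_used))
}

#' Fit the use-availability random forest
#'
#' Fits a classification forest on the 26 predictors (24 environmental plus
#' one-hot year and site) with the configured hyperparameters. Requires both
#' classes present and exactly balanced (the sampling design guarantees 1:1).
#' Out-of-bag vote fractions and the out-of-bag confusion matrix (0.5 vote
#' threshold) are recorded per training row. Seeded and reproducible.
#'
#' @param tbl design table from [build_design_matrix()]
#' @param config a `model_config`
#' @return object of class `rsf_forest` with components `rf`, `registry`,
#'   `config`, `oob_prob`, `oob_confusion`, `modal_year`, `modal_site`
#' @export
fit_forest <- function(tbl, config = model_config()) {
  if (length(unique(tbl$label)) < 2) {
    stop2("fit_forest: modeling error, both classes must be present")
  }
  n_by <- table(tbl$label)
  if (n_by[["used"]] != n_by[["available"]]) {
    stop2("fit_forest: modeling error, design must be class-balanced (used %d vs available %d)",
          n_by[["used"]], n_by[["available"]])
  }
  registry <- encoding_registry(tbl)
  x <- encode_design(tbl, registry)
  set.seed(config$seed)
  rf <- randomForest::randomForest(
    x = x, y = tbl$label,
    ntree = config$n_trees,
    mtry = min(config$m_try, ncol(x)),
    nodesize = config$min_node_size
  )
  oob_prob <- rf$votes[, "used"]
  pred_used <- oob_prob > 0.5
  structure(list(
    rf = rf, registry = registry, config = config,
    oob_prob = as.numeric(oob_prob),
    oob_confusion = confusion_from(tbl$label, pred_used),
    modal_year = names(which.max(table(tbl$year))),
    modal_site = names(which.max(table(tbl$site))),
    n = nrow(tbl)
  ), class = "rsf_forest")
}

#' @export
print.rsf_forest <- function(x, ...) {
  cat(sprintf("<rsf_forest> %d trees, mtry %d, %d rows; OOB used-class error %.3f\n",
              x$config$n_trees, x$rf$mtry, x$n,
              used_class_error(x$oob_confusion)))
  invisible(x)
}

#' Predict probability of use
#'
#' Fraction of trees voting "used", clamped away from 0/1 for ratio
#' operations. Categories unseen at training time (e.g. a held-out site) enter
#' as all-zero indicator vectors.
#'
#' @param model an `rsf_forest`
#' @param newdata design table rows, or an already-encoded matrix
#' @return numeric vector of clamped probabilities
#' @export
predict_prob <- function(model, newdata) {
  x <- if (is.matrix(newdata)) newdata else encode_design(newdata, model$registry)
  p <- stats::predict(model$rf, x, type = "prob")[, "used"]
  clamp_prob(as.numeric(p), model$config$n_trees)
}

#' Tune mtry by out-of-bag error
#'
#' Fits one forest per candidate (same seed and data) and returns the
#' candidate minimizing the overall out-of-bag error rate; ties go to the
#' smallest candidate. The error vector is attached as attribute `"errors"`
#' for plotting.
#'
#' @param tbl design table
#' @param candidates integer vector of mtry candidates
#' @param config a `model_config` (its `m_try` is ignored)
#' @return chosen mtry with attribute `errors`
#' @export
tune_mtry <- function(tbl, candidates, config = model_config()) {
  if (length(candidates) == 0) stop2("tune_mtry: candidates must be nonempty")
  candidates <- sort(unique(as.integer(candidates)))
  errs <- vapply(candidates, function(m) {
    cfg <- config
    cfg$m_try <- m
    fit <- fit_forest(tbl, cfg)
    cc <- fit$oob_confusion
    (cc[["used_wrong"]] + cc[["avail_wrong"]]) / sum(cc)
  }, numeric(1))
  best <- candidates[which.min(errs)] # first minimum = smallest candidate
  structure(best, errors = stats::setNames(errs, candidates))
}

#' Mean decrease in impurity importance across folds
#'
#' Per-predictor Gini impurity decrease totals from each fold's forest, with
#' one-hot indicator columns summed back to their categorical predictor (year,
#' site), averaged across folds with the standard deviation and descending
#' rank.
#'
#' @param models list of `rsf_forest` fold models (or a single model)
#' @return `ImportanceTable` data frame: `predictor`, `mean_mdi`, `sd_mdi`,
#'   `rank`, ordered by rank
#' @export
importance_mdi <- function(models) {
  if (inherits(models, "rsf_forest")) models <- list(models)
  if (length(models) == 0) stop2("importance_mdi: need at least one fold model")
  preds <- c(predictor_names(), "year", "site")
  per_fold <- vapply(models, function(m) {
    imp <- m$rf$importance[, "MeanDecreaseGini"]
    base <- sub("__.*$", "", names(imp))
    v <- tapply(imp, base, sum)
    as.numeric(v[preds])
  }, numeric(length(preds)))
  per_fold <- matrix(per_fold, nrow = length(preds))
  mean_mdi <- rowMeans(per_fold)
  sd_mdi <- apply(per_fold, 1, function(r) if (length(r) > 1) stats::sd(r) else 0)
  sd_mdi[is.na(sd_mdi)] <- 0
  out <- data.frame(predictor = preds, mean_mdi = mean_mdi, sd_mdi = sd_mdi,
                    rank = rank(-mean_mdi, ties.method = "first"))
  out[order(out$rank), ]
}
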