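# Spatial leave-one-site-out cross-validation: fold construction, pooled
# confusion matrices, used-class error, and use-availability calibration.

#' Build leave-one-site-out folds
#'
#' One fold per site: the fold's test set is that site's rows, its training
#' set all other sites' rows. Fold order follows sorted site labels so the
#' construction is independent of row order.
#'
#' @param tbl design table with a `site` column
#' @return list of folds, each `list(site, train, test)` with row indices
#' @export
make_folds <- function(tbl) {
  sites <- sort(unique(as.character(tbl$site)))
  if (length(sites) < 2) {
    stop2("make_folds: validation error, need at least 2 sites (got %d)", length(sites))
  }
  lapply(sites, function(s) {
    list(site = s,
         train = which(as.character(tbl$site) != s),
         test = which(as.character(tbl$site) == s))
  })
}

#' Run leave-one-site-out cross-validation
#'
#' Fits one forest per fold on the training sites (fold seeds derived from the
#' config seed) and scores the withheld site, whose site indicator is all-zero
#' at prediction (spatial transfer). Records per-fold out-of-bag and held-out
#' confusion counts (0.5 vote threshold), held-out probabilities, and
#' importance.
#'
#' @param tbl design table from [build_design_matrix()]
#' @param config a `model_config`
#' @return object of class `cv_result`: list of `FoldResult`s plus the table
#' @export
cross_validate <- function(tbl, config = model_config()) {
  folds <- make_folds(tbl)
  res <- lapply(seq_along(folds), function(i) {
    f <- folds[[i]]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 100 + i)
    log_msg("cv", "fold %d/%d: withholding site %s (%d test rows)",
            i, length(folds), f$site, length(f$test))
    model <- fit_forest(tbl[f$train, , drop = FALSE], cfg)
    test <- tbl[f$test, , drop = FALSE]
    val_prob <- predict_prob(model, test)
    list(site = f$site, model = model,
         train = f$train, test = f$test,
         oob_confusion = model$oob_confusion,
         val_confusion = confusion_from(test$label, val_prob > 0.5),
         val_prob = val_prob,
         val_label = as.character(test$label))
  })
  structure(list(folds = res, table = tbl, config = config), class = "cv_result")
}

#' Pool confusion matrices across folds
#'
#' Out-of-bag counts are summed over each fold's training predictions (every
#' row appears in K-1 training sets); validation counts are summed over
#' held-out predictions (every row held out exactly once).
#'
#' @param cv a `cv_result`
#' @return list with `oob` and `validation` `confusion_counts`
#' @export
pooled_confusion <- function(cv) {
  list(oob = Reduce(`+`, lapply(cv$folds, `[[`, "oob_confusion")),
       validation = Reduce(`+`, lapply(cv$folds, `[[`, "val_confusion")))
}

#' Used-class classification error
#'
#' Errors are reported for the used class only: available points have unknown
#' true status under a presence-background design, so their error rate is not
#' meaningful.
#'
#' @param cc `confusion_counts` (or anything with `used_correct`/`used_wrong`)
#' @return `used_wrong / (used_correct + used_wrong)`
#' @export
used_class_error <- function(cc) {
  tot <- cc[["used_correct"]] + cc[["used_wrong"]]
  if (tot == 0) stop2("used_class_error: undefined, no used rows")
  unname(cc[["used_wrong"]] / tot)
}

#' Use-availability calibration curve
#'
#' Test rows are binned into `n_bins` quantile bins of predicted probability
#' (by rank, stable order, near-equal bin sizes). Per bin, the expected number
#' of used points is the sum of predicted probabilities and the observed
#' number is the count of used rows; the curve is summarized by Spearman's
#' rank correlation of expected vs observed.
#'
#' @param prob predicted probabilities of use for the test rows
#' @param used logical (or "used"/"available" labels) for the test rows
#' @param n_bins number of quantile bins (default deciles)
#' @return list of class `calibration_curve`: `curve` data frame (`bin`, `n`,
#'   `expected`, `observed`) and `rho`
#' @export
calibration <- function(prob, used, n_bins = 10) {
  if (is.character(used) || is.factor(used)) used <- used == "used"
  n <- length(prob)
  if (n < n_bins) stop2("calibration: fewer test rows (%d) than bins (%d)", n, n_bins)
  if (!any(used) || all(used)) {
    stop2("calibration: test set must contain both used and available rows")
  }
  if (length(unique(prob)) == 1) {
    stop2("calibration: degenerate, all predicted probabilities identical; the model carries no ranking information for these rows")
  }
  ord <- order(prob) # stable; ties keep row order
  bin_of_sorted <- ceiling(seq_len(n) * n_bins / n)
  bin <- integer(n)
  bin[ord] <- bin_of_sorted
  curve <- data.frame(
    bin = seq_len(n_bins),
    n = as.integer(tabulate(bin, n_bins)),
    expected = as.numeric(tapply(prob, factor(bin, levels = seq_len(n_bins)), sum, default = 0)),
    observed = as.integer(tapply(used, factor(bin, levels = seq_len(n_bins)), sum, default = 0))
  )
  rho <- stats::cor(curve$expected, curve$observed, method = "spearman")
  structure(list(curve = curve, rho = rho), class = "calibration_curve")
}

#' Per-fold and season-level calibration of a cross-validation run
#'
#' Computes one calibration curve per fold from its held-out predictions, the
#' fold-mean curve (bin-wise average of expected and observed counts), and
#' Spearman correlations at both levels. The season-level summary
#' `season_rho` is the Spearman correlation of the fold-mean curve, the
#' single per-season calibration statistic; `rho`/`mean_rho` report the
#' fold-level correlations and their average.
#'
#' @param cv a `cv_result`
#' @param n_bins quantile bins per fold
#' @return list with `folds` (per-fold `calibration_curve`s), `rho` (per-fold
#'   vector), `mean_rho`, `mean_curve`, and `season_rho`
#' @export
cv_calibration <- function(cv, n_bins = 10) {
  cal <- lapply(cv$folds, function(f) calibration(f$val_prob, f$val_label, n_bins))
  rho <- vapply(cal, `[[`, numeric(1), "rho")
  names(rho) <- vapply(cv$folds, `[[`, character(1), "site")
  mean_curve <- data.frame(
    bin = seq_len(n_bins),
    expected = rowMeans(vapply(cal, function(cc) cc$curve$expected, numeric(n_bins))),
    observed = rowMeans(vapply(cal, function(cc) cc$curve$observed, numeric(n_bins)))
  )
  list(folds = cal, rho = rho, mean_rho = mean(rho),
       mean_curve = mean_curve,
       season_rho = stats::cor(mean_curve$expected, mean_curve$observed,
                               method = "spearman"))
}
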