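test_that("leave-one-site-out folds partition the rows by site", {
  tbl <- make_toy_table(90, seed = 51)
  folds <- make_folds(tbl)
  expect_length(folds, 3)
  for (f in folds) {
    expect_setequal(c(f$train, f$test), seq_len(nrow(tbl)))
    expect_true(all(tbl$site[f$test] == f$site))
    expect_true(all(tbl$site[f$train] != f$site))
  }
  # each row appears in exactly K - 1 training sets
  train_hits <- tabulate(unlist(lapply(folds, `[[`, "train")), nrow(tbl))
  expect_true(all(train_hits == 2))
  # fold construction is independent of row order
  perm <- sample(nrow(tbl))
  folds2 <- make_folds(tbl[perm, ])
  for (i in seq_along(folds)) {
    expect_setequal(perm[folds2[[i]]$test], folds[[i]]$test)
  }
  one_site <- tbl
  one_site$site <- factor(1)
  expect_error(make_folds(one_site), "at least 2 sites")
})

test_that("pooled confusion totals obey the fold-pooling identities", {
  cv <- fx_cv()
  n <- nrow(cv$table)
  n_used <- sum(cv$table$label == "used")
  K <- length(cv$folds)
  pc <- pooled_confusion(cv)
  expect_equal(sum(pc$oob), (K - 1) * n)
  expect_equal(unname(pc$oob[["used_correct"]] + pc$oob[["used_wrong"]]),
               (K - 1) * n_used)
  expect_equal(sum(pc$validation), n)
  expect_equal(unname(pc$validation[["used_correct"]] + pc$validation[["used_wrong"]]),
               n_used)
  # pooling is order-invariant
  rev_sum <- Reduce(`+`, rev(lapply(cv$folds, `[[`, "oob_confusion")))
  expect_identical(unclass(rev_sum), unclass(pc$oob))
})

test_that("used-class error is the used-row misclassification fraction", {
  expect_equal(used_class_error(confusion_counts(90, 10, 50, 50)), 0.1)
  expect_equal(used_class_error(confusion_counts(123, 0, 1, 1)), 0)
  expect_error(used_class_error(confusion_counts(0, 0, 5, 5)), "no used rows")
  expect_error(confusion_counts(-1, 0, 0, 0), "nonnegative")
})

test_that("calibration is perfect on a well-calibrated toy and inverted on its mirror", {
  probs <- rep(seq(0.05, 0.95, by = 0.1), each = 10)
  # bin b holds b - 1 used rows, so observed counts strictly track expected
  used <- unlist(lapply(1:10, function(b) rep(c(TRUE, FALSE), c(b - 1, 11 - b))))
  cal <- calibration(probs, used, n_bins = 10)
  expect_equal(cal$rho, 1)
  expect_equal(sum(cal$curve$observed), sum(used))
  expect_equal(sum(cal$curve$n), length(probs))
  # anti-ordered observations give rho = -1
  cal2 <- calibration(probs, rev(used), n_bins = 10)
  expect_equal(cal2$rho, -1)
})

test_that("a 20-row worked example matches brute-force quantile binning", {
  set.seed(52)
  prob <- round(runif(20), 3)
  used <- runif(20) < prob
  cal <- calibration(prob, used, n_bins = 10)
  # oracle: sort rows by probability, fill 10 bins of 2 in sorted order
  ord <- order(prob)
  exp_e <- exp_o <- numeric(10)
  for (b in 1:10) {
    rows <- ord[(2 * b - 1):(2 * b)]
    exp_e[b] <- sum(prob[rows])
    exp_o[b] <- sum(used[rows])
  }
  expect_equal(cal$curve$expected, exp_e)
  expect_equal(cal$curve$observed, as.integer(exp_o))
  expect_equal(cal$rho, stats::cor(exp_e, exp_o, method = "spearman"))
})

test_that("calibration rho is invariant to monotone probability transforms", {
  set.seed(53)
  prob <- runif(200)
  used <- runif(200) < prob
  c1 <- calibration(prob, used)
  c2 <- calibration(prob^3, used) # strictly monotone transform
  expect_equal(c2$rho, c1$rho)
  expect_equal(c2$curve$observed, c1$curve$observed)
  expect_true(abs(c1$rho) <= 1)
})

test_that("degenerate calibration inputs raise informative errors", {
  expect_error(calibration(rep(0.5, 50), rep(c(TRUE, FALSE), 25)), "identical")
  expect_error(calibration(runif(50), rep(TRUE, 50)), "both used and available")
  expect_error(calibration(runif(5), c(TRUE, FALSE, TRUE, FALSE, TRUE)), "bins")
})

test_that("season-level calibration summarizes the fold-mean curve", {
  cv <- fx_cv()
  cal <- cv_calibration(cv)
  K <- length(cv$folds)
  expect_length(cal$rho, K)
  expect_true(all(abs(cal$rho) <= 1))
  expect_equal(cal$mean_rho, mean(cal$rho))
  expect_equal(nrow(cal$mean_curve), 10)
  expect_equal(cal$season_rho,
               stats::cor(cal$mean_curve$expected, cal$mean_curve$observed,
                          method = "spearman"))
  # held-out scoring covers every used row exactly once
  expect_equal(sum(vapply(cal$folds, function(f) sum(f$curve$observed), numeric(1))),
               sum(cv$table$label == "used"))
})
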