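test_that("RSS self-normalizes to exactly 1 at the reference composition", {
  cv <- fx_cv()
  pset <- fx_pset()
  model <- cv$folds[[1]]$model
  p_ref <- reference_probability(model, pset, "breeding")
  expect_gt(p_ref, 0)
  expect_lt(p_ref, 1)
  # deterministic: repeated evaluation is identical
  expect_identical(reference_probability(model, pset, "breeding"), p_ref)
  # predicting the reference row itself and dividing gives exactly 1
  ref <- grousehab:::reference_row(model, pset, "breeding",
                                   as.integer(model$modal_year))
  expect_identical(as.numeric(predict_prob(model, ref)) / p_ref, 1)
})

test_that("RSS surfaces preserve prediction ordering and mark selection at 1", {
  cv <- fx_cv()
  pset <- fx_pset()
  surf <- rss_surface(cv$folds[[1]]$model, pset, "breeding", fold = 1)
  v <- surf$rss$values
  expect_true(all(v[!is.na(v)] > 0))
  # rss is p / p_ref: multiplying back recovers clamped probabilities in (0,1)
  p <- v * surf$reference_probability
  expect_true(all(p[!is.na(p)] > 0 & p[!is.na(p)] < 1))
  # division by a positive constant preserves ordering
  expect_equal(order(v[!is.na(v)]), order(p[!is.na(p)]))
})

fake_rss <- function(vals, season = "breeding", fold = 1) {
  structure(list(season = season,
                 rss = grid_layer(vals, cellsize = 1000),
                 reference_probability = 0.5, fold = fold),
            class = "rss_layer")
}

test_that("fold averaging is the cellwise mean and respects alignment", {
  a <- fake_rss(matrix(1, 2, 2))
  b <- fake_rss(matrix(3, 2, 2))
  m <- mean_across_folds(list(a, b))
  expect_true(all(m$rss$values == 2))
  expect_equal(m$fold, "mean")
  # identical folds -> identity
  expect_equal(mean_across_folds(list(a, a))$rss$values, a$rss$values)
  # mean bounded by fold min/max per cell
  set.seed(61)
  layers <- lapply(1:4, function(i) fake_rss(matrix(runif(4, 0.5, 2), 2, 2)))
  mm <- mean_across_folds(layers)$rss$values
  stackv <- sapply(layers, function(l) l$rss$values)
  expect_true(all(mm >= apply(stackv, 1, min) - 1e-12))
  expect_true(all(mm <= apply(stackv, 1, max) + 1e-12))
  # misaligned grids refused
  c2 <- fake_rss(matrix(1, 3, 3))
  expect_error(mean_across_folds(list(a, c2)), "misaligned")
  expect_error(mean_across_folds(list(a, fake_rss(matrix(1, 2, 2), season = "winter"))),
               "seasons")
})

test_that("annual habitat applies the strict any-season exceedance rule", {
  s <- list(breeding = fake_rss(matrix(1.2, 1, 1), "breeding"),
            summer = fake_rss(matrix(0.4, 1, 1), "summer"),
            winter = fake_rss(matrix(0.9, 1, 1), "winter"))
  expect_equal(annual_habitat(s)$values[1, 1], 1)
  s2 <- list(breeding = fake_rss(matrix(0.5, 1, 1), "breeding"),
             summer = fake_rss(matrix(0.7, 1, 1), "summer"),
             winter = fake_rss(matrix(0.99, 1, 1), "winter"))
  expect_equal(annual_habitat(s2)$values[1, 1], 0)
  # the boundary rss = 1 exactly maps to nonhabitat (strict >)
  s3 <- lapply(s2, function(l) { l$rss$values[] <- 1; l })
  expect_equal(annual_habitat(s3)$values[1, 1], 0)
  expect_error(annual_habitat(s[c("breeding", "summer")]), "missing season")
})

test_that("annual habitat equals the union of seasonal exceedance masks", {
  set.seed(62)
  seasons <- c("breeding", "summer", "winter")
  s <- lapply(seasons, function(nm) fake_rss(matrix(runif(100, 0.3, 2), 10, 10), nm))
  names(s) <- seasons
  got <- annual_habitat(s)$values
  union_mask <- Reduce(`|`, lapply(s, function(l) l$rss$values > 1))
  expect_equal(got == 1, union_mask)
})

test_that("response curves pass through 1 at the predictor mean and are reproducible", {
  cv <- fx_cv()
  pset <- fx_pset()
  model <- cv$folds[[1]]$model
  rc <- response_curve(model, pset, "sagebrush", "breeding", n_points = 21)
  expect_equal(nrow(rc), 21)
  # exact self-reference at the mean value
  ref_val <- attr(rc, "reference_value")
  sweep_at_mean <- rc$value[which.min(abs(rc$value - ref_val))]
  expect_lt(abs(sweep_at_mean - ref_val), diff(range(rc$value)) / 20)
  rc2 <- response_curve(model, pset, "sagebrush", "breeding", n_points = 21)
  expect_identical(rc$rss, rc2$rss)
  expect_error(response_curve(model, pset, "nonexistent", "breeding"), "unknown predictor")
  # constant predictor has no range to sweep
  pset2 <- pset
  pset2$terrain$elevation$values[] <- 1500
  expect_error(response_curve(model, pset2, "elevation", "breeding"), "constant")
})

test_that("fitted surfaces recover the direction of single-covariate truth", {
  cv <- fx_cv()
  pset <- fx_pset()
  rssm <- mean_across_folds(lapply(cv$folds, function(f) {
    rss_surface(f$model, pset, "breeding", fold = f$site)
  }))
  tr <- suppressMessages(truth_rss(fx_stack(), fx_truth(), "breeding",
                                   predictors = pset))
  fv <- rssm$rss$values
  tv <- tr$values
  ok <- !is.na(fv) & !is.na(tv)
  # supermajority cellwise sign agreement and positive rank concordance;
  # random-forest surfaces absorb smooth correlated noise fields, which caps
  # cellwise agreement well below 1 at this problem size
  expect_gt(mean(sign(fv[ok] - 1) == sign(tv[ok] - 1)), 2 / 3)
  expect_gt(stats::cor(fv[ok], tv[ok], method = "spearman"), 0.3)
})
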