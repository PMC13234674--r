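# A linear two-target toy on which every base model is exercised cheaply.
linear_toy <- function(n = 250, seed = 8L) {
  set.seed(seed)
  x <- matrix(runif(n * 4, 0, 10), n, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  data.frame(x, upc = 100 + 5 * x[, 1] - 2 * x[, 3],
             mpsp = 250 + 8 * x[, 1] + 3 * x[, 2])
}

test_that("every base model predicts finite values and fits a linear toy", {
  toy <- linear_toy()
  fit <- tea_surrogate(toy, models = c("lm", "knn", "svr", "poly_ridge",
                                       "rf", "xgb"),
                       select = FALSE, seed = 8)
  for (m in fit$model_names) {
    p <- predict(fit, toy, model = m)
    expect_true(all(is.finite(p)), info = m)
  }
  # realizable case: the linear model is essentially exact
  expect_gt(fit$cv$lm["r2", "average"], 0.999)
  expect_lt(fit$cv$lm["mape", "average"], 0.1)
})

test_that("surrogate pipeline on scenario data is seed-deterministic", {
  ds <- small_dataset()
  f1 <- tea_surrogate(ds, models = c("lm", "xgb"), seed = 21)
  f2 <- tea_surrogate(ds, models = c("lm", "xgb"), seed = 21)
  expect_identical(f1$features, f2$features)
  expect_identical(f1$cv, f2$cv)
  expect_identical(predict(f1, ds[1:5, ]), predict(f2, ds[1:5, ]))
  # and the fitted object carries coherent pieces
  expect_s3_class(f1, "tea_surrogate")
  expect_true(f1$best %in% f1$model_names)
  expect_identical(sort(unique(metrics_table(f1, "cv")$target)),
                   sort(c("upc", "mpsp", "average")))
  expect_output(print(f1), "TEA surrogate")
  expect_output(summary(f1), "Hold-out")
  expect_true(is.matrix(coef(f1)))
})

test_that("per-fold refitting shields the pipeline from leakage", {
  # deliberately leaky variant: scale once on all training rows, then CV
  ds <- small_dataset()
  x <- as.matrix(ds[, c("labor_rate", "quinaldine_cost", "irr")])
  y <- as.matrix(ds[, c("upc", "mpsp")])
  folds <- batchtea:::.cv_folds(nrow(x), 5, seed = 31)
  clean <- batchtea:::.cv_model("lm", x, y, folds, seed = 31)
  xs_leaky <- apply_scaler(fit_scaler(x), x)
  leaky <- batchtea:::.cv_model("lm", xs_leaky, y, folds, seed = 31)
  # the linear fit is scale-equivariant, so fold metrics agree here...
  expect_equal(clean["r2", "average"], leaky["r2", "average"],
               tolerance = 1e-6)
  # ...but the fitted scalers themselves must differ fold to fold
  sc_all <- fit_scaler(x)
  sc_fold <- fit_scaler(x[folds != 1, ])
  expect_false(isTRUE(all.equal(sc_all$max, sc_fold$max)))
})

test_that("randomized search stays in the printed space and helps", {
  toy <- linear_toy(300)
  fit <- tea_surrogate(toy, models = "xgb", select = FALSE, seed = 12)
  tn <- tune_surrogate(fit, n_iter = 6, seed = 12)
  tr <- tn$trace
  expect_true(all(tr$nrounds >= 50 & tr$nrounds <= 300))
  expect_true(all(tr$max_depth >= 3 & tr$max_depth <= 30))
  expect_true(all(tr$eta >= 0.001 & tr$eta <= 0.1))
  expect_true(all(tr$subsample >= 0.3 & tr$subsample <= 1))
  expect_true(all(tr$colsample_bytree >= 0.3 & tr$colsample_bytree <= 1))
  expect_true(all(tr$nrounds == as.integer(tr$nrounds)))
  # the reported winner is the argmax of the search trace
  expect_equal(tn$cv_r2, max(tr$cv_r2))
  expect_true(all(is.finite(tn$holdout)))
  # determinism
  tn2 <- tune_surrogate(fit, n_iter = 6, seed = 12)
  expect_identical(tn$best_params, tn2$best_params)
  expect_output(print(tn), "best configuration")
})

test_that("learning curves show the optimism gap and improve with data", {
  ds <- small_dataset()
  fit <- tea_surrogate(ds, models = "xgb", select = FALSE, seed = 13)
  lc <- learning_curve(fit, model = "xgb",
                       sizes = c(24, 48, 72, 96), cv_folds = 4)
  expect_equal(nrow(lc), 4)
  # training score never falls below validation by more than fold noise
  expect_true(all(lc$train_r2 >= lc$val_r2 - lc$val_sd))
  # validation score trends upward with training size
  expect_gt(stats::cor(lc$size, lc$val_r2, method = "spearman"), 0)
  expect_error(learning_curve(fit, sizes = c(30, 60)), "at least 3")
})
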