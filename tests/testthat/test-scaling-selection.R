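test_that("train/test split is disjoint, exhaustive and reproducible", {
  ds <- small_dataset()
  sp <- split_train_test(ds, 0.8, seed = 5)
  expect_length(sp$train, 96)
  expect_length(sp$test, 24)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_len(nrow(ds)))
  expect_identical(sp, split_train_test(ds, 0.8, seed = 5))
  expect_false(identical(sp$train, split_train_test(ds, 0.8, 6)$train))
  expect_error(split_train_test(ds[1:5, ], 0.8), "at least 10")
})

test_that("min-max scaling maps the fit range onto [0, 1] and inverts", {
  set.seed(3)
  x <- matrix(rnorm(200, 50, 20), 50, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  sc <- fit_scaler(x)
  xs <- apply_scaler(sc, x)
  expect_equal(unname(apply(xs, 2, min)), rep(0, 4))
  expect_equal(unname(apply(xs, 2, max)), rep(1, 4))
  expect_equal(invert_scaler(sc, xs), x, tolerance = 1e-12)
  # endpoints
  expect_equal(unname(apply_scaler(sc, rbind(sc$min))[1, ]), rep(0, 4))
  expect_equal(unname(apply_scaler(sc, rbind(sc$max))[1, ]), rep(1, 4))
  # new data outside the fit range are not clipped
  out <- apply_scaler(sc, rbind(sc$max + 10))
  expect_true(all(out > 1))
  # constant features pass through as zero with a warning
  xc <- cbind(x, const = 7)
  expect_warning(scc <- fit_scaler(xc), "constant")
  expect_true(all(apply_scaler(scc, xc)[, "const"] == 0))
})

test_that("fold-wise scaling differs from whole-set scaling (leakage probe)", {
  ds <- small_dataset()
  x <- as.matrix(ds[, 1:35])
  fold_train <- 1:80
  sc_fold <- fit_scaler(x[fold_train, ])
  sc_full <- fit_scaler(x)
  expect_false(isTRUE(all.equal(sc_fold$min, sc_full$min)))
  # validation rows transformed with fold parameters can leave [0, 1]
  xv <- apply_scaler(sc_fold, x[81:120, ])
  expect_true(any(xv < 0 | xv > 1))
})

test_that("regression metrics match hand-computed values", {
  y <- c(100, 200, 300); yhat <- c(110, 190, 310)
  m <- regression_metrics(y, yhat)
  expect_equal(m[["rmse"]], 10)
  expect_equal(m[["mape"]], (10 / 100 + 10 / 200 + 10 / 300) / 3 * 100,
               tolerance = 1e-12)
  expect_equal(m[["mape"]], 6.11, tolerance = 1e-3)
  expect_equal(m[["r2"]], 1 - 300 / 20000)
  # defining identities
  expect_equal(as.numeric(regression_metrics(y, y)), c(1, 0, 0))
  expect_equal(regression_metrics(y, rep(mean(y), 3))[["r2"]], 0)
  # near-zero observations are excluded from the MAPE
  m2 <- regression_metrics(c(0, 1, 2), c(0.1, 1, 2))
  expect_equal(attr(m2, "mape_excluded"), 1L)
  expect_equal(m2[["mape"]], 0)
})

test_that("multitask lasso recovers a planted support exactly", {
  pl <- planted_linear()
  sel <- select_features(pl$x, pl$y, penalty = 0.02)
  expect_setequal(sel$features, pl$support)
  # non-selected coefficients are exactly zero in both target columns
  dropped <- setdiff(rownames(sel$coefficients), sel$features)
  expect_true(all(sel$coefficients[dropped, ] == 0))
  # cross-validated penalty choice recovers the same support here
  sel_cv <- select_features(pl$x, pl$y, penalty = "cv", seed = 2)
  expect_setequal(sel_cv$features, pl$support)
})

test_that("extreme regularization empties the selection", {
  pl <- planted_linear()
  sel <- select_features(pl$x, pl$y, penalty = 1e6)
  expect_length(sel$features, 0)
  expect_error(select_features(pl$x, cbind(a = rep(1, 400),
                                           b = rep(2, 400))),
               "constant")
  expect_error(select_features(pl$x, pl$y, penalty = -1), "positive")
})

test_that("selection on the scenario dataset keeps the key cost drivers", {
  ds <- small_dataset()
  x <- as.matrix(ds[, 1:35]); y <- as.matrix(ds[, c("upc", "mpsp")])
  xs <- apply_scaler(fit_scaler(x), x)
  sel <- select_features(xs, y)
  expect_true(all(c("labor_rate", "quinaldine_cost", "irr") %in%
                    sel$features))
  expect_lt(length(sel$features), 35)
})
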