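#' Split a dataset into training and test parts
#'
#' Seed-reproducible hold-out partition; the two parts are disjoint and
#' exhaustive.
#'
#' @param data A data.frame.
#' @param train_fraction Fraction of rows assigned to training.
#' @param seed Integer seed.
#' @return List with integer row indices `train` and `test`.
#' @export
split_train_test <- function(data, train_fraction = 0.8, seed = 1L) {
  n <- nrow(data)
  if (n < 10) stop("need at least 10 rows to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  set.seed(seed)
  tr <- sort(sample.int(n, round(train_fraction * n)))
  list(train = tr, test = setdiff(seq_len(n), tr))
}

#' Joint sparse feature selection for both targets
#'
#' Multitask LASSO: one group-sparse linear model fitted jointly to the two
#' targets on min-max-scaled features, so a feature is either retained for
#' both targets or dropped for both.  By default the penalty is the fixed
#' library-default strength (`lambda = 1` on the raw targets), matching a
#' default-hyperparameter modelling workflow; `penalty = "cv"` instead
#' chooses it by cross-validation (one-standard-error rule, standardized
#' response).  On a noise-free deterministic dataset the CV choice tends to
#' retain every feature with any real effect, however tiny, so the fixed
#' default is the more parsimonious screen (see the package vignette).
#'
#' @param x Feature matrix (min-max scaled).
#' @param y Two-column target matrix (raw units).
#' @param penalty `"default"` (fixed strength), `"cv"`, or a positive
#'   number used as the penalty directly.
#' @param seed Integer seed for the CV fold assignment.
#' @return An object of class `tea_selection`: `features` (character),
#'   `coefficients` (matrix, per-target; dropped features are exactly
#'   zero), `lambda`.
#' @export
select_features <- function(x, y, penalty = "default", seed = 1L) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(y) == 2)
  if (any(apply(y, 2, stats::sd) == 0))
    stop("degenerate (constant) target; nothing to select on")
  if (is.numeric(penalty)) {
    if (penalty <= 0) stop("penalty must be positive")
    lambda <- penalty
  } else {
    penalty <- match.arg(penalty, c("default", "cv"))
    lambda <- if (penalty == "default") 1 else NULL
  }
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "mgaussian",
                          standardize = FALSE,
                          standardize.response = FALSE, lambda = lambda)
    co <- stats::coef(fit)
  } else {
    set.seed(seed)
    fit <- glmnet::cv.glmnet(x, y, family = "mgaussian",
                             standardize = FALSE,
                             standardize.response = TRUE)
    lambda <- fit$lambda.1se
    co <- stats::coef(fit, s = "lambda.1se")
  }
  cm <- sapply(co, function(m) as.numeric(m)[-1])
  rownames(cm) <- colnames(x)
  keep <- rowSums(abs(cm)) > 0
  structure(list(features = colnames(x)[keep],
                 coefficients = cm,
                 lambda = lambda),
            class = "tea_selection")
}

#' @export
print.tea_selection <- function(x, ...) {
  cat("Multitask-LASSO feature selection\n")
  cat("  lambda:  ", format(x$lambda, digits = 4), "\n")
  cat("  selected ", length(x$features), " of ", nrow(x$coefficients),
      " features:\n", sep = "")
  cat("   ", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

# k-fold assignment, seed-reproducible
.cv_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

# Cross-validate one model: per fold, fit the scaler on the fold-train rows
# only (no leakage), fit one regressor per target, and score the validation
# rows.  Returns mean metrics per target plus the uniform average.
.cv_model <- function(name, x, y, folds, seed, params = NULL) {
  k <- max(folds)
  per_target <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f; va <- folds == f
    sc <- fit_scaler(x[tr, , drop = FALSE])
    xtr <- apply_scaler(sc, x[tr, , drop = FALSE])
    xva <- apply_scaler(sc, x[va, , drop = FALSE])
    m <- sapply(colnames(y), function(tg) {
      fit <- if (name == "xgb" && !is.null(params))
        structure(list(name = "xgb",
                       fit = .xgb_fit(xtr, y[tr, tg], params, seed),
                       features = colnames(xtr)),
                  class = "tea_base_model")
      else .fit_one(name, xtr, y[tr, tg], seed = seed + f)
      regression_metrics(y[va, tg], .predict_one(fit, xva))
    })
    per_target[[f]] <- m
  }
  avg <- Reduce(`+`, per_target) / k
  cbind(avg, average = rowMeans(avg))
}

#' Fit the multi-output TEA surrogate models
#'
#' The central fitting function of the package.  Splits the scenario
#' dataset 80/20, optionally runs joint multitask-LASSO feature selection on
#' the training part, cross-validates the requested regressors (each as an
#' independent-per-target multi-output model on min-max-scaled features,
#' with the scaler refitted inside every fold), refits them on the full
#' training set, and scores the hold-out rows.  The best model by mean
#' cross-validated R-squared is used by `predict()` unless another is
#' requested.
#'
#' @param data A `tea_scenarios` data.frame (or any data.frame holding the
#'   feature columns and the two targets).
#' @param targets Names of the two target columns.
#' @param models Character vector of base regressors among
#'   `"lm", "knn", "svr", "poly_ridge", "rf", "xgb"`.
#' @param select Logical; run multitask-LASSO feature selection and train
#'   on the selected subset.
#' @param penalty Passed to [select_features()].
#' @param cv_folds Number of cross-validation folds.
#' @param train_fraction Hold-out training fraction.
#' @param seed Integer pipeline seed; drives the split, fold assignment,
#'   selection and any stochastic learner.
#' @return An object of class `tea_surrogate` with components `cv`
#'   (per-model, per-target metrics on validation folds), `holdout`
#'   (per-model hold-out metrics), `models` (fitted on the training set),
#'   `selection`, `features`, `scaler`, `split`, `best`.
#' @seealso [predict.tea_surrogate()], [tune_surrogate()],
#'   [learning_curve()]
#' @examples
#' \donttest{
#' ds <- tea_scenarios(300, seed = 3)
#' fit <- tea_surrogate(ds, models = c("lm", "xgb"), seed = 3)
#' fit
#' }
#' @export
tea_surrogate <- function(data, targets = c("upc", "mpsp"),
                          models = .tea_model_names, select = TRUE,
                          penalty = "default", cv_folds = 5,
                          train_fraction = 0.8, seed = 1L) {
  stopifnot(all(targets %in% names(data)), length(targets) == 2)
  models <- match.arg(models, .tea_model_names, several.ok = TRUE)
  feats_all <- setdiff(names(data), targets)
  x <- as.matrix(data[, feats_all, drop = FALSE])
  y <- as.matrix(data[, targets, drop = FALSE])

  sp <- split_train_test(data, train_fraction, seed = seed)
  xtr <- x[sp$train, , drop = FALSE]; ytr <- y[sp$train, , drop = FALSE]

  selection <- NULL
  features <- feats_all
  if (select) {
    sc0 <- fit_scaler(xtr)
    selection <- select_features(apply_scaler(sc0, xtr), ytr,
                                 penalty = penalty, seed = seed + 1L)
    if (length(selection$features) >= 2) features <- selection$features
    else warning("selection kept < 2 features; using all features")
  }
  xtr_f <- xtr[, features, drop = FALSE]

  folds <- .cv_folds(nrow(xtr_f), cv_folds, seed = seed + 2L)
  cv <- lapply(models, function(m)
    .cv_model(m, xtr_f, ytr, folds, seed = seed + 3L))
  names(cv) <- models

  scaler <- fit_scaler(xtr_f)
  xs <- apply_scaler(scaler, xtr_f)
  fitted <- lapply(models, function(m)
    sapply(targets, function(tg)
      .fit_one(m, xs, ytr[, tg], seed = seed + 4L),
      simplify = FALSE))
  names(fitted) <- models

  xte <- apply_scaler(scaler, x[sp$test, features, drop = FALSE])
  yte <- y[sp$test, , drop = FALSE]
  holdout <- lapply(models, function(m) {
    h <- sapply(targets, function(tg)
      regression_metrics(yte[, tg], .predict_one(fitted[[m]][[tg]], xte)))
    cbind(h, average = rowMeans(h))
  })
  names(holdout) <- models

  best <- models[which.max(vapply(cv, function(m) m["r2", "average"],
                                  numeric(1)))]
  structure(list(call = match.call(), targets = targets, models = fitted,
                 model_names = models, cv = cv, holdout = holdout,
                 selection = selection, features = features,
                 scaler = scaler, split = sp, best = best,
                 cv_folds = cv_folds, seed = seed,
                 data = data),
            class = "tea_surrogate")
}

#' Tabulate cross-validation metrics of a surrogate fit
#'
#' @param object A `tea_surrogate`.
#' @param which `"cv"` or `"holdout"`.
#' @return Long-format data.frame: `model`, `target`, `r2`, `rmse`, `mape`.
#' @export
metrics_table <- function(object, which = c("cv", "holdout")) {
  which <- match.arg(which)
  tabs <- object[[which]]
  do.call(rbind, lapply(names(tabs), function(m) {
    t <- tabs[[m]]
    data.frame(model = m, target = colnames(t),
               r2 = t["r2", ], rmse = t["rmse", ], mape = t["mape", ],
               row.names = NULL)
  }))
}

#' @export
print.tea_surrogate <- function(x, ...) {
  cat("TEA surrogate fit (", length(x$model_names), " models, ",
      x$cv_folds, "-fold CV, seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$selection))
    cat("selected features (", length(x$features), "): ",
        paste(x$features, collapse = ", "), "\n", sep = "")
  tab <- metrics_table(x, "cv")
  tab <- tab[tab$target == "average", c("model", "r2", "rmse", "mape")]
  tab[-1] <- lapply(tab[-1], round, 3)
  print(tab[order(-tab$r2), ], row.names = FALSE)
  cat("best model:", x$best, "\n")
  invisible(x)
}

#' @export
summary.tea_surrogate <- function(object, ...) {
  cat("Cross-validated metrics (validation folds):\n")
  tab <- metrics_table(object, "cv")
  tab[3:5] <- lapply(tab[3:5], round, 4)
  print(tab, row.names = FALSE)
  cat("\nHold-out metrics (20% test set):\n")
  tab <- metrics_table(object, "holdout")
  tab[3:5] <- lapply(tab[3:5], round, 4)
  print(tab, row.names = FALSE)
  invisible(object)
}

#' Predict UPC and MPSP with a fitted surrogate
#'
#' @param object A `tea_surrogate`.
#' @param newdata Data.frame or matrix holding the feature columns.
#' @param model Which fitted base model to use (default: best by CV).
#' @param ... Unused.
#' @return Matrix with one column per target.
#' @export
predict.tea_surrogate <- function(object, newdata, model = object$best,
                                  ...) {
  model <- match.arg(model, object$model_names)
  xs <- apply_scaler(object$scaler,
                     as.matrix(as.data.frame(newdata)[, object$features,
                                                      drop = FALSE]))
  sapply(object$targets, function(tg)
    .predict_one(object$models[[model]][[tg]], xs))
}

#' @export
coef.tea_surrogate <- function(object, ...) {
  if (is.null(object$selection))
    stop("no feature selection was run for this fit")
  object$selection$coefficients
}

#' Predicted-versus-actual plot on the hold-out set
#'
#' @param x A `tea_surrogate`.
#' @param model Base model to plot (default: best by CV).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tea_surrogate <- function(x, model = x$best, ...) {
  dat <- x$data
  te <- x$split$test
  obs <- as.matrix(dat[te, x$targets, drop = FALSE])
  pred <- predict(x, dat[te, , drop = FALSE], model = model)
  op <- graphics::par(mfrow = c(1, length(x$targets)))
  on.exit(graphics::par(op))
  for (tg in x$targets) {
    graphics::plot(obs[, tg], pred[, tg],
                   xlab = paste("actual", tg),
                   ylab = paste("predicted", tg),
                   main = paste(.model_labels[model], "-", tg),
                   pch = 16, cex = 0.5,
                   col = grDevices::adjustcolor("steelblue", 0.5), ...)
    graphics::abline(0, 1, col = "red3")
  }
  invisible(x)
}

#' @export
residuals.tea_surrogate <- function(object, model = object$best, ...) {
  te <- object$split$test
  obs <- as.matrix(object$data[te, object$targets, drop = FALSE])
  obs - predict(object, object$data[te, , drop = FALSE], model = model)
}
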