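#' Randomized hyperparameter search for the boosted-tree surrogate
#'
#' Samples hyperparameter configurations uniformly from the search space
#' (integer-uniform for tree counts and depths) and scores each with k-fold
#' cross-validation on the surrogate's training rows, using the same
#' per-fold scaling discipline as the base fit.  The best configuration by
#' mean cross-validated R-squared is refitted on the full training set.
#'
#' @param object A [tea_surrogate()] fit.
#' @param n_iter Number of sampled configurations.
#' @param space Named list of bounds: `nrounds`, `max_depth` (integer
#'   ranges), `eta`, `subsample`, `colsample_bytree` (continuous ranges).
#' @param cv_folds Folds for the search.
#' @param seed Integer seed for sampling and fold assignment.
#' @return An object of class `tea_tuned`: `best_params`, `cv_r2`,
#'   `trace` (one row per configuration), `models` (refitted per-target
#'   boosters), `holdout` metrics.
#' @export
tune_surrogate <- function(object, n_iter = 30,
                           space = list(nrounds = c(50, 300),
                                        max_depth = c(3, 30),
                                        eta = c(0.001, 0.1),
                                        subsample = c(0.3, 1.0),
                                        colsample_bytree = c(0.3, 1.0)),
                           cv_folds = 5, seed = object$seed) {
  stopifnot(inherits(object, "tea_surrogate"))
  dat <- object$data
  x <- as.matrix(dat[object$split$train, object$features, drop = FALSE])
  y <- as.matrix(dat[object$split$train, object$targets, drop = FALSE])

  set.seed(seed + 10L)
  cfg <- data.frame(
    nrounds = sample(space$nrounds[1]:space$nrounds[2], n_iter,
                     replace = TRUE),
    max_depth = sample(space$max_depth[1]:space$max_depth[2], n_iter,
                       replace = TRUE),
    eta = stats::runif(n_iter, space$eta[1], space$eta[2]),
    subsample = stats::runif(n_iter, space$subsample[1],
                             space$subsample[2]),
    colsample_bytree = stats::runif(n_iter, space$colsample_bytree[1],
                                    space$colsample_bytree[2]))

  folds <- .cv_folds(nrow(x), cv_folds, seed = seed + 11L)
  cfg$cv_r2 <- vapply(seq_len(n_iter), function(i) {
    m <- .cv_model("xgb", x, y, folds, seed = seed + 12L,
                   params = as.list(cfg[i, 1:5]))
    m["r2", "average"]
  }, numeric(1))

  best <- which.max(cfg$cv_r2)
  bp <- as.list(cfg[best, 1:5])
  scaler <- object$scaler
  xs <- apply_scaler(scaler, x)
  models <- sapply(object$targets, function(tg)
    structure(list(name = "xgb",
                   fit = .xgb_fit(xs, y[, tg], bp, seed = seed + 13L),
                   features = colnames(xs)),
              class = "tea_base_model"),
    simplify = FALSE)

  te <- object$split$test
  xte <- apply_scaler(scaler, as.matrix(dat[te, object$features,
                                            drop = FALSE]))
  yte <- as.matrix(dat[te, object$targets, drop = FALSE])
  holdout <- sapply(object$targets, function(tg)
    regression_metrics(yte[, tg], .predict_one(models[[tg]], xte)))
  holdout <- cbind(holdout, average = rowMeans(holdout))

  structure(list(best_params = bp, cv_r2 = cfg$cv_r2[best], trace = cfg,
                 models = models, holdout = holdout, scaler = scaler,
                 features = object$features, targets = object$targets,
                 seed = seed),
            class = "tea_tuned")
}

#' @export
print.tea_tuned <- function(x, ...) {
  cat("Tuned gradient-boosting surrogate\n")
  cat("  best configuration:\n")
  for (p in names(x$best_params))
    cat("   ", p, "=", format(x$best_params[[p]], digits = 4), "\n")
  cat("  CV R^2 (uniform average): ", round(x$cv_r2, 4), "\n")
  cat("  hold-out R^2: ", round(x$holdout["r2", "average"], 4), "\n")
  invisible(x)
}

#' Learning curve of a surrogate model
#'
#' For a grid of training-set sizes, fits the model on a subsample of each
#' fold's training rows and records training and validation R-squared,
#' averaged over folds.
#'
#' @param object A [tea_surrogate()] fit.
#' @param model Base model name (default: the fit's best model).
#' @param sizes Vector of training-set sizes (rows); defaults to five
#'   points up to the full fold-training size.
#' @param cv_folds Folds.
#' @param seed Integer seed.
#' @return Data.frame `size`, `train_r2`, `val_r2` (uniform average over
#'   targets and folds) of class `tea_learning_curve`.
#' @export
learning_curve <- function(object, model = object$best, sizes = NULL,
                           cv_folds = 5, seed = object$seed) {
  stopifnot(inherits(object, "tea_surrogate"))
  dat <- object$data
  x <- as.matrix(dat[object$split$train, object$features, drop = FALSE])
  y <- as.matrix(dat[object$split$train, object$targets, drop = FALSE])
  folds <- .cv_folds(nrow(x), cv_folds, seed = seed + 20L)
  full <- min(vapply(seq_len(cv_folds), function(f) sum(folds != f),
                     numeric(1)))
  if (is.null(sizes))
    sizes <- unique(round(seq(max(30, full / 10), full, length.out = 5)))
  if (length(sizes) < 3) stop("need at least 3 size points")
  res <- lapply(sizes, function(s) {
    tr_r2 <- va_r2 <- numeric(cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- which(folds != f); va <- which(folds == f)
      set.seed(seed + 21L + f)
      tr <- sort(sample(tr, min(s, length(tr))))
      sc <- fit_scaler(x[tr, , drop = FALSE])
      xtr <- apply_scaler(sc, x[tr, , drop = FALSE])
      xva <- apply_scaler(sc, x[va, , drop = FALSE])
      r2t <- r2v <- numeric(ncol(y))
      for (j in seq_len(ncol(y))) {
        fit <- .fit_one(model, xtr, y[tr, j], seed = seed + 22L + f)
        r2t[j] <- regression_metrics(y[tr, j],
                                     .predict_one(fit, xtr))["r2"]
        r2v[j] <- regression_metrics(y[va, j],
                                     .predict_one(fit, xva))["r2"]
      }
      tr_r2[f] <- mean(r2t); va_r2[f] <- mean(r2v)
    }
    c(size = s, train_r2 = mean(tr_r2), val_r2 = mean(va_r2),
      train_sd = stats::sd(tr_r2), val_sd = stats::sd(va_r2))
  })
  out <- as.data.frame(do.call(rbind, res))
  class(out) <- c("tea_learning_curve", "data.frame")
  out
}

#' @export
plot.tea_learning_curve <- function(x, ...) {
  graphics::plot(x$size, x$val_r2, type = "b", col = "steelblue",
                 ylim = range(c(x$train_r2, x$val_r2)),
                 xlab = "training size", ylab = expression(R^2), ...)
  graphics::lines(x$size, x$train_r2, type = "b", col = "red3")
  graphics::legend("bottomright", c("training", "validation"),
                   col = c("red3", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}
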