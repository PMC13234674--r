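#' Spearman rank correlations between inputs and targets
#'
#' Rank correlation of every input column against each target, with
#' average-rank tie handling.  Constant columns yield `NA` with a note.
#'
#' @param data A `tea_scenarios` data.frame.
#' @param targets Target column names.
#' @param top Number of top features (by correlation) reported per target
#'   in the `top` attribute.
#' @return Long data.frame `feature`, `target`, `rho` of class
#'   `tea_spearman`; `attr(, "top")` holds the per-target top features.
#' @examples
#' \donttest{
#' st <- spearman_table(tea_scenarios(200, seed = 5))
#' attr(st, "top")$upc
#' }
#' @export
spearman_table <- function(data, targets = c("upc", "mpsp"), top = 5) {
  if (nrow(data) < 3) stop("need at least 3 rows")
  inputs <- setdiff(names(data), targets)
  out <- do.call(rbind, lapply(targets, function(tg) {
    rho <- vapply(inputs, function(f) {
      if (stats::sd(data[[f]]) == 0 || stats::sd(data[[tg]]) == 0)
        return(NA_real_)
      stats::cor(data[[f]], data[[tg]], method = "spearman")
    }, numeric(1))
    data.frame(feature = inputs, target = tg, rho = rho,
               row.names = NULL)
  }))
  topl <- lapply(targets, function(tg) {
    d <- out[out$target == tg & !is.na(out$rho), ]
    utils::head(d[order(-d$rho), c("feature", "rho")], top)
  })
  names(topl) <- targets
  attr(out, "top") <- topl
  class(out) <- c("tea_spearman", "data.frame")
  out
}

#' Kernel density marginals
#'
#' Gaussian-kernel density estimate for each requested feature, Scott's
#' bandwidth rule by default.
#'
#' @param data Data.frame.
#' @param features Columns to estimate; defaults to all numeric columns.
#' @param bw Bandwidth rule passed to [stats::density()].
#' @return Named list of data.frames `x`, `density`, one per feature, of
#'   class `tea_kde`.
#' @export
kde_marginals <- function(data, features = NULL, bw = "nrd") {
  if (nrow(data) < 30) stop("need at least 30 rows for a density estimate")
  if (is.null(features))
    features <- names(data)[vapply(data, is.numeric, logical(1))]
  out <- lapply(features, function(f) {
    v <- data[[f]]
    if (stats::sd(v) == 0) {
      warning("degenerate density for constant feature: ", f)
      return(data.frame(x = v[1], density = Inf))
    }
    d <- stats::density(v, bw = bw)
    data.frame(x = d$x, density = d$y)
  })
  names(out) <- features
  structure(out, class = "tea_kde")
}

#' @export
plot.tea_kde <- function(x, ...) {
  k <- length(x)
  nc <- ceiling(sqrt(k))
  op <- graphics::par(mfrow = c(ceiling(k / nc), nc),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (f in names(x))
    graphics::plot(x[[f]]$x, x[[f]]$density, type = "l", col = "steelblue",
                   xlab = f, ylab = "density", main = f, ...)
  invisible(x)
}

#' SHAP feature attributions for a surrogate model
#'
#' Per-sample additive attributions of one target's predictions to the
#' input features.  For the boosted-tree surrogate the exact tree-path
#' (TreeSHAP) contributions are used; for other base models a Monte Carlo
#' sampling explainer is applied with a warning.  Attributions plus the
#' base value reconstruct each prediction.
#'
#' @param object A [tea_surrogate()] fit (or `tea_tuned`).
#' @param data Rows to explain (feature columns; defaults to the fit's
#'   hold-out rows, capped at `max_rows`).
#' @param target Which target to explain.
#' @param model Base model name (`tea_surrogate` fits only).
#' @param max_rows Cap on explained rows.
#' @param nsim Monte Carlo draws per feature for the sampling explainer.
#' @param seed Seed for the sampling explainer.
#' @return An object of class `tea_shap`: `shap` (n x p matrix),
#'   `base_value`, `prediction`, `ranking` (features by mean |attribution|),
#'   `feature_values`.
#' @export
shap_summary <- function(object, data = NULL, target = "mpsp",
                         model = NULL, max_rows = 1000, nsim = 50,
                         seed = 1L) {
  tuned <- inherits(object, "tea_tuned")
  if (!tuned) stopifnot(inherits(object, "tea_surrogate"))
  if (is.null(model)) model <- if (tuned) "xgb" else object$best
  target <- match.arg(target, object$targets)
  if (is.null(data)) {
    if (tuned) stop("data must be supplied for a tuned fit")
    data <- object$data[object$split$test, , drop = FALSE]
  }
  if (nrow(data) > max_rows) data <- data[seq_len(max_rows), , drop = FALSE]
  xs <- apply_scaler(object$scaler,
                     as.matrix(as.data.frame(data)[, object$features,
                                                   drop = FALSE]))
  bm <- if (tuned) object$models[[target]] else
    object$models[[model]][[target]]
  if (bm$name == "xgb") {
    contrib <- stats::predict(bm$fit, xgboost::xgb.DMatrix(xs),
                              predcontrib = TRUE)
    bias_col <- setdiff(colnames(contrib), colnames(xs))
    base <- contrib[1, bias_col[1]]
    shap <- contrib[, colnames(xs), drop = FALSE]
  } else {
    warning("no exact explainer for model '", bm$name,
            "'; falling back to a sampling-based explainer")
    shap <- .sampling_shap(function(m) .predict_one(bm, m), xs,
                           nsim = nsim, seed = seed)
    base <- mean(.predict_one(bm, xs))
  }
  pred <- .predict_one(bm, xs)
  ranking <- colnames(shap)[order(-colMeans(abs(shap)))]
  structure(list(shap = shap, base_value = base, prediction = pred,
                 ranking = ranking, feature_values = xs,
                 target = target),
            class = "tea_shap")
}

# Monte Carlo permutation Shapley values (Strumbelj-Kononenko sampling):
# marginal contribution of each feature averaged over random orderings,
# with the background taken as rows of x itself.
.sampling_shap <- function(predfun, x, nsim = 50, seed = 1L) {
  set.seed(seed)
  n <- nrow(x); p <- ncol(x)
  shap <- matrix(0, n, p, dimnames = list(NULL, colnames(x)))
  for (s in seq_len(nsim)) {
    ord <- sample.int(p)
    bg <- x[sample.int(n, n, replace = TRUE), , drop = FALSE]
    cur <- bg
    prev <- predfun(cur)
    for (j in ord) {
      cur[, j] <- x[, j]
      now <- predfun(cur)
      shap[, j] <- shap[, j] + (now - prev) / nsim
      prev <- now
    }
  }
  shap
}

#' @export
print.tea_shap <- function(x, ...) {
  cat("SHAP attributions for target '", x$target, "' (",
      nrow(x$shap), " samples)\n", sep = "")
  cat("  base value:", format(x$base_value, digits = 6), "\n")
  imp <- sort(colMeans(abs(x$shap)), decreasing = TRUE)
  cat("  mean |attribution| (top 8):\n")
  print(round(utils::head(imp, 8), 3))
  invisible(x)
}

#' @export
plot.tea_shap <- function(x, top = 9, ...) {
  feats <- utils::head(x$ranking, top)
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = range(x$shap[, feats]),
                 ylim = c(0.5, length(feats) + 0.5), yaxt = "n",
                 xlab = "SHAP value", ylab = "",
                 main = paste("SHAP summary -", x$target))
  graphics::axis(2, at = rev(seq_along(feats)), labels = feats, las = 1)
  for (i in seq_along(feats)) {
    f <- feats[i]
    v <- x$feature_values[, f]
    colv <- grDevices::rgb(grDevices::colorRamp(c("dodgerblue", "red"))(
      (v - min(v)) / max(1e-12, diff(range(v)))) / 255)
    graphics::points(x$shap[, f],
                     rev(seq_along(feats))[i] +
                       stats::runif(nrow(x$shap), -0.25, 0.25),
                     pch = 16, cex = 0.4,
                     col = grDevices::adjustcolor(colv, 0.6))
  }
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
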