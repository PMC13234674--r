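#' Min-max feature scaler
#'
#' Fits per-feature minima and maxima on a training matrix;
#' `apply_scaler()` maps features through
#' `(x - x_min) / (x_max - x_min)`, so training data land in `[0, 1]`
#' while new data may fall outside (no clipping).  Constant features are
#' passed through as 0 with a warning.
#'
#' @param x Numeric matrix or data.frame of training features.
#' @return An object of class `tea_scaler`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  mn <- apply(x, 2, min)
  mx <- apply(x, 2, max)
  const <- mx <= mn
  if (any(const))
    warning("constant feature(s) passed through as 0: ",
            paste(colnames(x)[const], collapse = ", "))
  structure(list(min = mn, max = mx, constant = const),
            class = "tea_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `tea_scaler`.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "tea_scaler"))
  x <- as.matrix(x)
  x <- x[, names(scaler$min), drop = FALSE]
  rng <- ifelse(scaler$constant, 1, scaler$max - scaler$min)
  out <- sweep(sweep(x, 2, scaler$min), 2, rng, "/")
  out[, scaler$constant] <- 0
  out
}

#' @rdname fit_scaler
#' @export
invert_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "tea_scaler"))
  x <- as.matrix(x)
  rng <- ifelse(scaler$constant, 1, scaler$max - scaler$min)
  sweep(sweep(x, 2, rng, "*"), 2, scaler$min, "+")
}

#' Regression evaluation metrics
#'
#' Coefficient of determination, root mean squared error and mean absolute
#' percentage error:
#' \deqn{R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y)^2}
#' \deqn{RMSE = \sqrt{\frac1n \sum(y - \hat y)^2}}
#' \deqn{MAPE = \frac{100}{n} \sum |(y - \hat y) / y|}
#' Rows with `|y| < 1e-9` are excluded from the MAPE (their count is
#' reported in the `mape_excluded` attribute).
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return Named vector `c(r2, rmse, mape)`.
#' @examples
#' regression_metrics(c(100, 200, 300), c(110, 190, 310))
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  rmse <- sqrt(mean((y - yhat)^2))
  ok <- abs(y) >= 1e-9
  mape <- mean(abs((y[ok] - yhat[ok]) / y[ok])) * 100
  out <- c(r2 = r2, rmse = rmse, mape = mape)
  attr(out, "mape_excluded") <- sum(!ok)
  out
}
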