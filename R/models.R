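# Internal wrappers giving the six base regressors one fit/predict surface.
# Each is fitted per target on min-max-scaled features (targets unscaled).
# Default hyperparameters mirror one reference library family throughout:
# k = 5 neighbors; SVR with RBF kernel, C = 1, epsilon = 0.1; ridge penalty
# alpha = 1 on the degree-2 expansion; 100 bagged trees with all features
# tried per split; boosting with 100 rounds, eta 0.3, depth 6.

.tea_model_names <- c("lm", "knn", "svr", "poly_ridge", "rf", "xgb")

.model_labels <- c(lm = "linear regression", knn = "k-nearest neighbors",
                   svr = "support vector regression",
                   poly_ridge = "polynomial ridge", rf = "random forest",
                   xgb = "gradient boosting")

# degree-2 polynomial expansion: x, x^2 and pairwise products
.poly2 <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  sq <- x^2
  colnames(sq) <- paste0(colnames(x), "^2")
  inter <- NULL
  if (p > 1) {
    pairs <- utils::combn(p, 2)
    inter <- x[, pairs[1, ], drop = FALSE] * x[, pairs[2, ], drop = FALSE]
    colnames(inter) <- paste0(colnames(x)[pairs[1, ]], ":",
                              colnames(x)[pairs[2, ]])
  }
  cbind(x, sq, inter)
}

# ridge with unpenalized intercept, penalty alpha on the identity
.ridge_fit <- function(x, y, alpha = 1) {
  X <- cbind(`(Intercept)` = 1, x)
  D <- diag(ncol(X)); D[1, 1] <- 0
  XtX <- crossprod(X) + alpha * D
  if (rcond(XtX) < 1e-14)
    stop("singular polynomial design; reduce the polynomial degree")
  beta <- solve(XtX, crossprod(X, y))
  list(beta = beta)
}

.fit_one <- function(name, x, y, seed = 1L) {
  x <- as.matrix(x)
  fit <- switch(
    name,
    lm = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      stats::lm(.y ~ ., data = df)
    },
    knn = caret::knnreg(x, y),
    svr = e1071::svm(x = x, y = y),
    poly_ridge = .ridge_fit(.poly2(x), y, alpha = 1),
    rf = {
      set.seed(seed)
      randomForest::randomForest(x, y, ntree = 100, mtry = ncol(x))
    },
    xgb = .xgb_fit(x, y, seed = seed),
    stop("unknown model: ", name)
  )
  structure(list(name = name, fit = fit, features = colnames(x)),
            class = "tea_base_model")
}

.xgb_defaults <- list(nrounds = 100, eta = 0.3, max_depth = 6,
                      subsample = 1, colsample_bytree = 1)

.xgb_fit <- function(x, y, params = .xgb_defaults, seed = 1L) {
  dm <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = params$eta,
                  max_depth = params$max_depth,
                  subsample = params$subsample,
                  colsample_bytree = params$colsample_bytree,
                  nthread = 1, seed = seed),
    data = dm, nrounds = params$nrounds, verbose = 0)
}

.predict_one <- function(model, x) {
  x <- as.matrix(x)[, model$features, drop = FALSE]
  switch(
    model$name,
    lm = as.numeric(stats::predict(model$fit,
                                   data.frame(x, check.names = FALSE))),
    knn = as.numeric(stats::predict(model$fit, x)),
    svr = as.numeric(stats::predict(model$fit, x)),
    poly_ridge = as.numeric(cbind(1, .poly2(x)) %*% model$fit$beta),
    rf = as.numeric(stats::predict(model$fit, x)),
    xgb = as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(x)))
  )
}
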