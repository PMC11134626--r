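# Closed-form ridge regression on centered data (features x samples).
ridge_fit <- function(X, y, lambda) {
  xc <- rowMeans(X); yc <- mean(y)
  Xc <- X - xc
  A <- tcrossprod(Xc) + lambda * diag(nrow(X))
  beta <- solve(A, Xc %*% (y - yc))
  list(predict = function(Xnew) drop(crossprod(Xnew - xc, beta)) + yc)
}

# Kernel ridge regression, the package's stand-in for SVR (no SVM solver is
# assumed available); C plays the role of the box constraint: lambda = 1/C.
kernel_gram <- function(X1, X2, kernel, gamma) {
  if (kernel == "rbf") {
    d2 <- outer(colSums(X1^2), colSums(X2^2), `+`) - 2 * crossprod(X1, X2)
    exp(-gamma * pmax(d2, 0))
  } else { # sigmoid
    tanh(gamma * crossprod(X1, X2))
  }
}

krr_fit <- function(X, y, C, kernel, gamma) {
  K <- kernel_gram(X, X, kernel, gamma)
  yc <- mean(y)
  alpha <- solve(K + (1 / C) * diag(ncol(X)), y - yc)
  list(predict = function(Xnew) {
    drop(crossprod(kernel_gram(X, Xnew, kernel, gamma), alpha)) + yc
  })
}

rmse <- function(pred, truth) sqrt(mean((pred - truth)^2))

cv_folds_index <- function(n, k) {
  split(sample.int(n), rep(seq_len(k), length.out = n)[order(seq_len(n))])
}

#' Downstream prediction with cross-validated hyperparameters
#'
#' Predicts each clinical score from a fixed-length representation (enriched
#' or original) with ridge regression or, as the nonlinear comparator, kernel
#' ridge regression with an RBF or sigmoid kernel standing in for SVR.
#' Hyperparameters are selected by k-fold cross-validation on the training
#' samples only — the ridge penalty (and the box constraint `C`) over the
#' grid `10^(3:-3)`, and the kernel family for `"svr"` — then the model is
#' refit on all training samples and scored on the test set.  Test labels
#' are never touched during selection.
#'
#' @param x_train,x_test representation matrices, features by samples.
#' @param y_train,y_test score matrices, scores by samples (a vector is
#'   treated as a single score).
#' @param model `"ridge"` or `"svr"` (kernel ridge stand-in).
#' @param cv_folds folds for hyperparameter selection (>= 2).
#' @param seed seed for the fold assignment.
#' @return list with `rmse` (named per score), `hyperparams` (selected per
#'   score), `predictions` (scores x test samples), `model`.
#' @export
evaluate_downstream <- function(x_train, y_train, x_test, y_test,
                                model = c("ridge", "svr"), cv_folds = 5L,
                                seed = 1L) {
  model <- match.arg(model)
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  if (is.null(dim(y_train))) y_train <- matrix(y_train, nrow = 1)
  if (is.null(dim(y_test))) y_test <- matrix(y_test, nrow = 1)
  y_train <- as.matrix(y_train); y_test <- as.matrix(y_test)
  n_tr <- ncol(x_train)
  stopifnot(ncol(y_train) == n_tr, ncol(y_test) == ncol(x_test),
            nrow(y_train) == nrow(y_test), cv_folds >= 2L)
  if (n_tr < cv_folds) {
    stop(sprintf("fewer training samples (%d) than folds (%d)", n_tr, cv_folds))
  }

  grid_c <- 10^(3:-3)
  gamma_rbf <- 1 / nrow(x_train)
  folds <- with_seed(seed, cv_folds_index(n_tr, cv_folds))

  fit_one <- function(hp_row, X, y) {
    if (model == "ridge") ridge_fit(X, y, hp_row$lambda)
    else krr_fit(X, y, hp_row$C, hp_row$kernel, gamma_rbf)
  }
  grid <- if (model == "ridge") {
    data.frame(lambda = grid_c)
  } else {
    expand.grid(C = grid_c, kernel = c("rbf", "sigmoid"),
                stringsAsFactors = FALSE)
  }

  out_rmse <- numeric(nrow(y_train))
  out_hp <- vector("list", nrow(y_train))
  preds <- matrix(0, nrow(y_test), ncol(x_test))
  for (s in seq_len(nrow(y_train))) {
    y <- y_train[s, ]
    cv_err <- vapply(seq_len(nrow(grid)), function(g) {
      errs <- vapply(folds, function(hold) {
        f <- fit_one(grid[g, , drop = FALSE],
                     x_train[, -hold, drop = FALSE], y[-hold])
        rmse(f$predict(x_train[, hold, drop = FALSE]), y[hold])
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    best <- grid[which.min(cv_err), , drop = FALSE]
    f <- fit_one(best, x_train, y)
    preds[s, ] <- f$predict(x_test)
    out_rmse[s] <- rmse(preds[s, ], y_test[s, ])
    out_hp[[s]] <- as.list(best)
  }
  names(out_rmse) <- rownames(y_train) %||% paste0("score", seq_along(out_rmse))
  list(rmse = out_rmse, hyperparams = out_hp, predictions = preds,
       model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
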