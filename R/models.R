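#' Specify a machine-learning backend
#'
#' Uniform specification for the four supported learners. Unset
#' hyperparameters take backend defaults at fit time:
#' * `svm_rbf`: radial kernel, `cost = 1`, `gamma` by the median heuristic
#'   on the training rows;
#' * `random_forest`: 500 trees (ranger);
#' * `xgboost`: up to 500 rounds, depth 3, learning rate 0.1, early stopping
#'   on a 10% holdout;
#' * `ensemble_dnn`: 10 bagged single-hidden-layer networks (size 6, weight
#'   decay 0.1, 120 iterations); diverged members are dropped and fitting
#'   errors if fewer than half survive.
#'
#' @param name backend name.
#' @param ... named hyperparameter overrides.
#' @param seed seed applied at fit time for reproducible training.
#' @return an object of class `"backend_spec"`.
#' @export
backend_spec <- function(name = c("xgboost", "random_forest", "svm_rbf", "ensemble_dnn"),
                         ..., seed = NULL) {
  name <- match.arg(name)
  structure(list(name = name, params = list(...), seed = seed),
            class = "backend_spec")
}

as_backend_spec <- function(x, seed = NULL) {
  if (inherits(x, "backend_spec")) {
    if (!is.null(seed) && is.null(x$seed)) x$seed <- seed
    return(x)
  }
  backend_spec(x, seed = seed)
}

#' Fit a backend model
#'
#' Trains the specified learner and returns a model with a uniform
#' [predict()][predict.hifit_model] contract: continuous outcomes yield the
#' conditional mean, binary outcomes the class-1 probability. Predictions
#' depend only on the named training feature columns; extra columns in new
#' data are ignored and missing ones raise an error.
#'
#' @param spec a [backend_spec()] or backend name.
#' @param X training feature matrix.
#' @param y outcome vector.
#' @param kind outcome kind, detected when `NULL`.
#' @return an object of class `"hifit_model"`.
#' @export
fit_backend <- function(spec, X, y, kind = NULL) {
  spec <- as_backend_spec(spec)
  X <- validate_features(X, min_n = 5L)
  kind <- validate_outcome(y, nrow(X), kind)
  pr <- spec$params
  fit <- run_seeded(spec$seed, function() {
    switch(spec$name,
      xgboost = fit_xgboost(X, y, kind, pr),
      random_forest = fit_ranger(X, y, kind, pr),
      svm_rbf = fit_svm(X, y, kind, pr),
      ensemble_dnn = fit_ensemble_dnn(X, y, kind, pr))
  })
  structure(list(backend = spec, kind = kind, features = colnames(X), fit = fit),
            class = "hifit_model")
}

fit_xgboost <- function(X, y, kind, pr) {
  nrounds <- pr$nrounds %||% 500L
  early <- pr$early_stopping_rounds %||% 25L
  objective <- if (kind == "binary") "binary:logistic" else "reg:squarederror"
  params <- list(max_depth = pr$max_depth %||% 3L, eta = pr$eta %||% 0.1,
                 nthread = 1L, objective = objective)
  n <- nrow(X)
  if (n >= 50L) {
    hold <- sample.int(n, max(5L, round(0.1 * n)))
    dtr <- xgboost::xgb.DMatrix(X[-hold, , drop = FALSE], label = y[-hold])
    dva <- xgboost::xgb.DMatrix(X[hold, , drop = FALSE], label = y[hold])
    booster <- xgboost::xgb.train(params = params, data = dtr, nrounds = nrounds,
                                  evals = list(val = dva),
                                  early_stopping_rounds = early, verbose = 0)
  } else {
    dtr <- xgboost::xgb.DMatrix(X, label = y)
    booster <- xgboost::xgb.train(params = params, data = dtr,
                                  nrounds = min(nrounds, 200L), verbose = 0)
  }
  booster
}

fit_ranger <- function(X, y, kind, pr) {
  if (kind == "binary") {
    ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                   num.trees = pr$num_trees %||% 500L, probability = TRUE,
                   num.threads = 1L, seed = sample.int(1e6, 1))
  } else {
    ranger::ranger(x = X, y = y, num.trees = pr$num_trees %||% 500L,
                   num.threads = 1L, seed = sample.int(1e6, 1))
  }
}

# median-heuristic gamma for the RBF SVM, estimated on at most 100 rows
svm_gamma <- function(X) {
  n <- nrow(X)
  rows <- if (n > 100L) round(seq(1, n, length.out = 100L)) else seq_len(n)
  D <- as.matrix(stats::dist(X[rows, , drop = FALSE]))
  md <- median(D[upper.tri(D)])
  if (md == 0) return(1 / max(ncol(X), 1L))
  1 / (2 * md^2)
}

fit_svm <- function(X, y, kind, pr) {
  gamma <- pr$gamma %||% svm_gamma(X)
  cost <- pr$cost %||% 1
  if (kind == "binary") {
    e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial", cost = cost,
               gamma = gamma, probability = TRUE)
  } else {
    e1071::svm(X, y, kernel = "radial", cost = cost, gamma = gamma)
  }
}

fit_ensemble_dnn <- function(X, y, kind, pr) {
  n_bags <- pr$n_bags %||% 10L
  size <- pr$size %||% 6L
  decay <- pr$decay %||% 0.1
  maxit <- pr$maxit %||% 120L
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
  n <- nrow(Z)
  yf <- if (kind == "binary") y else zscore(y)
  members <- list()
  for (b in seq_len(n_bags)) {
    rows <- sample.int(n, n, replace = TRUE)
    net <- tryCatch(
      nnet::nnet(Z[rows, , drop = FALSE], yf[rows], size = size, decay = decay,
                 maxit = maxit, linout = (kind == "continuous"),
                 entropy = (kind == "binary"), trace = FALSE,
                 MaxNWts = 100000L),
      error = function(e) NULL)
    if (is.null(net)) next
    pred <- drop(predict(net, Z))
    if (all(is.finite(pred))) members[[length(members) + 1L]] <- net
  }
  if (length(members) < n_bags / 2) {
    stop(sprintf("ensemble_dnn: only %d of %d members converged", length(members), n_bags),
         call. = FALSE)
  }
  list(members = members, mu = mu, sd = sdv,
       y_center = if (kind == "continuous") mean(y) else 0,
       y_scale = if (kind == "continuous") max(sd(y), .Machine$double.eps) else 1)
}

#' Predict from a fitted backend model
#'
#' @param object a model from [fit_backend()].
#' @param newdata feature matrix containing at least the training features;
#'   extra columns are ignored, missing ones raise an error naming them.
#' @param ... unused.
#' @return numeric vector: conditional-mean predictions (continuous) or
#'   class-1 probabilities in `[0, 1]` (binary).
#' @export
predict.hifit_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss)) {
    stop("newdata is missing training features: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- newdata[, object$features, drop = FALSE]
  kind <- object$kind
  out <- switch(object$backend$name,
    xgboost = predict(object$fit, xgboost::xgb.DMatrix(X)),
    random_forest = {
      pr <- predict(object$fit, data = X, num.threads = 1L)$predictions
      if (kind == "binary") pr[, "1"] else pr
    },
    svm_rbf = {
      if (kind == "binary") {
        pr <- predict(object$fit, X, probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      } else {
        unname(predict(object$fit, X))
      }
    },
    ensemble_dnn = {
      mu <- object$fit$mu
      Z <- sweep(sweep(X, 2L, mu, "-"), 2L, object$fit$sd, "/")
      preds <- vapply(object$fit$members, function(m) drop(predict(m, Z)),
                      numeric(nrow(Z)))
      if (nrow(Z) == 1L) preds <- matrix(preds, nrow = 1L)
      avg <- rowMeans(preds)
      if (kind == "continuous") avg * object$fit$y_scale + object$fit$y_center
      else pmin(pmax(avg, 0), 1)
    })
  unname(as.numeric(out))
}

#' @export
print.hifit_model <- function(x, ...) {
  cat(sprintf("<hifit_model> backend=%s kind=%s features=%d\n",
              x$backend$name, x$kind, length(x$features)))
  invisible(x)
}
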