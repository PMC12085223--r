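#' Permute one feature column
#'
#' Replaces column `j` with a uniform random permutation of itself, leaving
#' all other columns untouched. Uses the caller's RNG stream; seed outside
#' for reproducibility.
#'
#' @param X feature matrix.
#' @param j column index or name.
#' @return the matrix with column `j` permuted.
#' @export
permute_feature <- function(X, j) {
  X[, j] <- X[sample.int(nrow(X)), j]
  X
}

# per-sample prediction loss: squared error, or negative Bernoulli
# log-likelihood on clipped probabilities
sample_loss <- function(y, pred, kind) {
  if (kind == "continuous") {
    (y - pred)^2
  } else {
    pr <- pmin(pmax(pred, 1e-6), 1 - 1e-6)
    -(y * log(pr) + (1 - y) * log(1 - pr))
  }
}

# Per-sample permutation contrast for a block of columns permuted jointly
# (each column gets an independent permutation). Returns the length-nV
# vector of loss differences averaged over n_perm permutation passes.
block_contrast <- function(model, X, y, cols, base_loss, n_perm) {
  acc <- numeric(length(y))
  for (r in seq_len(n_perm)) {
    Xp <- X
    for (cc in cols) Xp <- permute_feature(Xp, cc)
    acc <- acc + (sample_loss(y, predict(model, Xp), model$kind) - base_loss)
  }
  acc / n_perm
}

aggregate_contrast <- function(contrib) {
  nv <- length(contrib)
  lambda <- mean(contrib)
  vhat <- mean((contrib - lambda)^2)
  se <- sqrt(vhat / nv)
  if (se > 0) {
    z <- lambda / se
    p <- pnorm(z, lower.tail = FALSE)
  } else {
    z <- 0
    p <- if (lambda > 0) 0 else 1
  }
  list(importance = lambda, se = se, z = z, p_value = p, n_validation = nv)
}

#' Permutation feature importance test on a validation set
#'
#' For each feature, contrasts the per-sample validation loss of the fitted
#' model under a random permutation of that feature's column against the
#' unpermuted loss. The mean contrast is the importance score; its standard
#' error over validation samples yields a one-sided normal z-test of the
#' null "the model's predictions do not depend on this feature". Continuous
#' outcomes use squared error, binary outcomes the negative Bernoulli
#' log-likelihood of the predicted probabilities.
#'
#' Features outside the model's training set are reported with importance 0
#' and p-value 1 by convention.
#'
#' @param model a fitted [fit_backend()] model (trained on samples disjoint
#'   from the validation set).
#' @param X,y validation features and outcome.
#' @param features columns to test (names or indices); defaults to the
#'   model's training features.
#' @param n_perm number of permutation passes averaged per feature.
#' @return a tibble with columns `feature`, `importance`, `se`, `z`,
#'   `p_value`, `n_validation`.
#' @export
permfit_test <- function(model, X, y, features = NULL, n_perm = 1L) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (nrow(X) < 1L) stop("validation set is empty", call. = FALSE)
  if (length(y) != nrow(X)) stop("'y' must match rows of 'X'", call. = FALSE)
  features <- features %||% model$features
  if (is.numeric(features)) features <- colnames(X)[features]
  base_loss <- sample_loss(y, predict(model, X), model$kind)
  rows <- lapply(features, function(f) {
    if (!f %in% model$features) {
      return(list(importance = 0, se = 0, z = 0, p_value = 1,
                  n_validation = length(y)))
    }
    aggregate_contrast(block_contrast(model, X, y, f, base_loss, n_perm))
  })
  tibble::tibble(
    feature = features,
    importance = vapply(rows, `[[`, 0, "importance"),
    se = vapply(rows, `[[`, 0, "se"),
    z = vapply(rows, `[[`, 0, "z"),
    p_value = vapply(rows, `[[`, 0, "p_value"),
    n_validation = vapply(rows, `[[`, 0, "n_validation"))
}

#' Cross-fitted permutation importance
#'
#' Convenience wrapper that handles the data split: either K-fold
#' cross-fitting (fit on K-1 folds, score contrasts on the held-out fold,
#' pool all n contributions; the default) or a single train/validation
#' split.
#'
#' @param X,y full data.
#' @param backend a [backend_spec()] or backend name.
#' @param features columns to test; default all.
#' @param split `"kfold"` or `"single_split"`.
#' @param K number of folds for cross-fitting.
#' @param train_fraction training fraction for the single split.
#' @param n_perm permutation passes per feature.
#' @param seed seed controlling the split, model fits, and permutations.
#' @return a tibble as in [permfit_test()].
#' @export
permfit <- function(X, y, backend = "xgboost", features = NULL,
                    split = c("kfold", "single_split"), K = 5L,
                    train_fraction = 0.8, n_perm = 1L, seed = NULL) {
  split <- match.arg(split)
  X <- validate_features(X)
  kind <- validate_outcome(y, nrow(X))
  features <- features %||% colnames(X)
  if (is.numeric(features)) features <- colnames(X)[features]
  spec <- as_backend_spec(backend)
  run_seeded(seed, function() {
    n <- nrow(X)
    if (split == "single_split") {
      tr <- sample.int(n, round(train_fraction * n))
      folds <- list(setdiff(seq_len(n), tr))
      trains <- list(tr)
    } else {
      fold_id <- sample(rep(seq_len(K), length.out = n))
      folds <- lapply(seq_len(K), function(k) which(fold_id == k))
      trains <- lapply(folds, function(v) setdiff(seq_len(n), v))
    }
    contribs <- matrix(NA_real_, 0L, length(features))
    for (k in seq_along(folds)) {
      model <- fit_backend(spec, X[trains[[k]], , drop = FALSE], y[trains[[k]]], kind)
      Xv <- X[folds[[k]], , drop = FALSE]
      yv <- y[folds[[k]]]
      base_loss <- sample_loss(yv, predict(model, Xv), kind)
      block <- vapply(features, function(f) {
        block_contrast(model, Xv, yv, f, base_loss, n_perm)
      }, numeric(length(yv)))
      if (length(yv) == 1L) block <- matrix(block, nrow = 1L)
      contribs <- rbind(contribs, block)
    }
    rows <- lapply(seq_along(features), function(j) aggregate_contrast(contribs[, j]))
    tibble::tibble(
      feature = features,
      importance = vapply(rows, `[[`, 0, "importance"),
      se = vapply(rows, `[[`, 0, "se"),
      z = vapply(rows, `[[`, 0, "z"),
      p_value = vapply(rows, `[[`, 0, "p_value"),
      n_validation = vapply(rows, `[[`, 0, "n_validation"))
  })
}

#' Refine a screened feature set by importance p-values
#'
#' Keeps the features whose permutation-importance p-value falls below
#' `alpha` (default 0.1). Always-kept covariates are exempt from removal.
#' Benjamini-Hochberg adjustment of the p-values is available as an option.
#'
#' @param importance tibble from [permfit_test()] or [permfit()].
#' @param alpha p-value threshold.
#' @param keep character vector of feature names retained regardless of
#'   p-value.
#' @param adjust apply Benjamini-Hochberg adjustment before thresholding.
#' @return character vector of retained feature names.
#' @export
refine <- function(importance, alpha = 0.1, keep = NULL, adjust = FALSE) {
  p <- importance$p_value
  if (adjust) p <- stats::p.adjust(p, method = "BH")
  union(keep, importance$feature[p < alpha])
}
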