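#' Polynomial marginal utility of a single feature
#'
#' Fits the order-`M` polynomial (generalized) linear model of the outcome on
#' one feature and returns the adjusted R-squared (continuous outcome) or
#' McFadden's pseudo R-squared `1 - LL_M / LL_0` (binary outcome). The
#' monomials are built on the centered/scaled feature, which spans the same
#' polynomial space and conditions the normal equations; R-squared is
#' invariant to this reparameterization.
#'
#' @param x numeric feature vector.
#' @param y outcome vector (continuous, or 0/1 binary).
#' @param M polynomial order (default 2: linear plus quadratic).
#' @param kind outcome kind; detected from `y` when `NULL`.
#' @return scalar utility; adjusted R-squared may be slightly negative for a
#'   null feature. Degenerate inputs (constant feature or constant outcome)
#'   return 0 with a warning.
#' @export
polynomial_utility <- function(x, y, M = 2L, kind = NULL) {
  M <- as.integer(M)
  if (M < 1L) stop("'M' must be a positive integer", call. = FALSE)
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length", call. = FALSE)
  if (n <= M + 1L) stop(sprintf("need n > M + 1 (n = %d, M = %d)", n, M), call. = FALSE)
  kind <- validate_outcome(y, n, kind)
  if (sd(x) == 0) {
    warning("feature has zero variance; utility set to 0", call. = FALSE)
    return(0)
  }
  xs <- zscore(x)
  P <- vapply(seq_len(M), function(m) xs^m, numeric(n))
  if (kind == "continuous") {
    sst <- sum((y - mean(y))^2)
    if (sst == 0) {
      warning("constant outcome; utility set to 0", call. = FALSE)
      return(0)
    }
    fit <- stats::lm.fit(cbind(1, P), y)
    sse <- sum(fit$residuals^2)
    1 - (n - 1) / (n - M - 1) * sse / sst
  } else {
    mcfadden_r2(P, y)
  }
}

# McFadden pseudo R2 with a ridge fallback when the logistic fit separates
mcfadden_r2 <- function(P, y) {
  n <- length(y)
  pbar <- mean(y)
  ll0 <- sum(y * log(pbar) + (1 - y) * log(1 - pbar))
  fit <- suppressWarnings(glm.fit(cbind(1, P), y, family = binomial()))
  mu <- fit$fitted.values
  separated <- !fit$converged || any(mu < 1e-10) || any(mu > 1 - 1e-10)
  if (separated) {
    warning("logistic fit separated; ridge-regularized fit used", call. = FALSE)
    mu <- ridge_logit_fitted(cbind(1, P), y, lambda = 1e-6)
  }
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  llj <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  min(1 - llj / ll0, 1)
}

# small L2-penalized logistic regression via BFGS (intercept unpenalized)
ridge_logit_fitted <- function(Z, y, lambda = 1e-6) {
  pen <- c(0, rep(lambda, ncol(Z) - 1L))
  negll <- function(b) {
    eta <- drop(Z %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + sum(pen * b^2) / 2
  }
  grad <- function(b) {
    mu <- stats::plogis(drop(Z %*% b))
    drop(crossprod(Z, mu - y)) + pen * b
  }
  opt <- stats::optim(rep(0, ncol(Z)), negll, grad, method = "BFGS",
                      control = list(maxit = 200))
  stats::plogis(drop(Z %*% opt$par))
}

#' Per-feature hybrid utility table
#'
#' Computes the polynomial-model utility ([polynomial_utility()]) and the
#' kernel partial correlation ([kpc_coefficient()]) for every column of `X`.
#' The outcome-kernel factor is computed once and shared across features;
#' features are independent, so results do not depend on evaluation order.
#' Degenerate features are flagged rather than aborting the scan.
#'
#' @param X feature matrix (samples x features).
#' @param y outcome vector.
#' @param M polynomial order for the parametric utility.
#' @param delta KPC ridge constant.
#' @param kernel,bandwidth kernel settings for the KPC, see
#'   [kpc_coefficient()].
#' @return a tibble with columns `feature`, `rho1`, `rho2`, `flag`, carrying
#'   the settings as attributes.
#' @export
hfs_utilities <- function(X, y, M = 2L, delta = 1e-3, kernel = "rbf",
                          bandwidth = "median") {
  X <- validate_features(X)
  n <- nrow(X)
  kind <- validate_outcome(y, n)
  ys <- if (kind == "continuous") zscore(y) else y
  if (sd(ys) == 0) stop("outcome has zero kernel variation", call. = FALSE)
  Gy <- kernel_factor(ys, kernel, bandwidth)
  trKy <- sum(Gy^2)
  p <- ncol(X)
  rho1 <- rho2 <- numeric(p)
  flag <- character(p)
  for (j in seq_len(p)) {
    fl <- character(0)
    rho1[j] <- withCallingHandlers(
      polynomial_utility(X[, j], y, M = M, kind = kind),
      warning = function(w) {
        fl <<- c(fl, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    xs <- zscore(X[, j])
    rho2[j] <- if (sd(xs) == 0) 0 else
      kpc_from_factor(xs, Gy, trKy, n, delta, kernel, bandwidth)
    flag[j] <- paste(unique(fl), collapse = "; ")
  }
  out <- tibble::tibble(feature = colnames(X), rho1 = rho1, rho2 = rho2, flag = flag)
  attr(out, "M") <- M
  attr(out, "delta") <- delta
  attr(out, "kernel") <- kernel
  attr(out, "bandwidth") <- bandwidth
  attr(out, "kind") <- kind
  out
}

#' Threshold anomaly scores into a selected feature set
#'
#' @param scores numeric vector of anomaly scores in `[0, 1]`.
#' @param tau cutoff; selection uses `scores >= tau` (inclusive).
#' @return integer indices of the selected features, in input order.
#' @export
select_features <- function(scores, tau) {
  which(scores >= tau)
}

#' Hybrid feature screening
#'
#' Runs the full marginal screen: per-feature utility pair, isolation-forest
#' anomaly scores over the utility pairs, and (when `tau` is supplied) the
#' thresholded feature set. Leave `tau = NULL` to choose the cutoff
#' data-adaptively with [adaptive_cutoff()].
#'
#' @inheritParams hfs_utilities
#' @param n_trees,psi isolation-forest size parameters, see
#'   [anomaly_scores()].
#' @param tau fixed anomaly-score cutoff, or `NULL`.
#' @param seed seed for the isolation forest.
#' @return an object of class `"hfs"`: a list with the screening tibble
#'   (`feature`, `rho1`, `rho2`, `score`, `flag`), `tau`, `selected`
#'   (integer indices or `NULL`), and the parameters used.
#' @export
hfs <- function(X, y, M = 2L, delta = 1e-3, kernel = "rbf", bandwidth = "median",
                n_trees = 100L, psi = NULL, tau = NULL, seed = NULL) {
  util <- hfs_utilities(X, y, M = M, delta = delta, kernel = kernel,
                        bandwidth = bandwidth)
  sc <- anomaly_scores(util, n_trees = n_trees, psi = psi, seed = seed)
  tab <- tibble::tibble(feature = util$feature, rho1 = util$rho1,
                        rho2 = util$rho2, score = sc, flag = util$flag)
  selected <- if (!is.null(tau)) select_features(sc, tau) else NULL
  structure(list(table = tab, tau = tau, selected = selected,
                 params = list(M = M, delta = delta, kernel = kernel,
                               bandwidth = bandwidth, n_trees = n_trees,
                               psi = psi, seed = seed)),
            class = "hfs")
}

#' @export
print.hfs <- function(x, ...) {
  cat(sprintf("Hybrid feature screen: %d features\n", nrow(x$table)))
  if (!is.null(x$tau)) {
    cat(sprintf("  cutoff tau = %.3f, %d selected\n", x$tau, length(x$selected)))
  } else {
    cat("  no cutoff applied (use adaptive_cutoff())\n")
  }
  invisible(x)
}
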