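#' Run the full screen / cutoff / test / refit pipeline
#'
#' Executes, on one dataset: (1) hybrid marginal screening of the
#' non-covariate features; (2) data-driven anomaly-score cutoff via
#' set-level permutation importance; (3) backend fit on the screened
#' features plus covariates; (4) per-feature permutation importance testing
#' and refinement at `alpha`; (5) a final backend fit on the refined set.
#' Always-kept covariates bypass screening and are exempt from refinement.
#' When the refined set is empty the final model falls back to the
#' covariates alone (with a warning), or fails if there are none.
#'
#' @param X feature matrix (samples x features), including any covariate
#'   columns.
#' @param y outcome vector (continuous or 0/1 binary).
#' @param covariates names of always-kept clinical covariate columns.
#' @param backend a [backend_spec()] or backend name used throughout.
#' @param M,delta,kernel,bandwidth screening parameters, see
#'   [hfs_utilities()].
#' @param n_trees,psi isolation-forest parameters.
#' @param candidates cutoff candidate grid.
#' @param split,K,train_fraction importance-test split plan, see
#'   [permfit()].
#' @param alpha refinement p-value threshold (also used for the cutoff
#'   bins).
#' @param n_perm permutation passes in the importance tests.
#' @param seed master seed; the run is reproducible from the arguments plus
#'   this seed.
#' @param newdata,newy optional held-out data scored with the final model.
#' @return an object of class `"hifit"`: screening table (with scores and
#'   selection flags), cutoff diagnostics, importance table, final feature
#'   set, fitted final model, held-out metrics (when given), and a manifest
#'   of the configuration.
#' @export
hifit <- function(X, y, covariates = NULL, backend = "xgboost",
                  M = 2L, delta = 1e-3, kernel = "rbf", bandwidth = "median",
                  n_trees = 100L, psi = NULL, candidates = hfs_cutoff_grid(),
                  split = c("kfold", "single_split"), K = 5L,
                  train_fraction = 0.8, alpha = 0.1, n_perm = 1L, seed = 1L,
                  newdata = NULL, newy = NULL) {
  split <- match.arg(split)
  X <- validate_features(X)
  kind <- validate_outcome(y, nrow(X))
  backend <- as_backend_spec(backend)
  if (!is.null(covariates)) {
    missing_cov <- setdiff(covariates, colnames(X))
    if (length(missing_cov)) {
      stop("covariates not found in X: ", paste(missing_cov, collapse = ", "),
           call. = FALSE)
    }
  }
  omics <- setdiff(colnames(X), covariates)
  if (length(omics) < 2L) stop("need at least 2 features to screen", call. = FALSE)

  screen <- hfs(X[, omics, drop = FALSE], y, M = M, delta = delta,
                kernel = kernel, bandwidth = bandwidth, n_trees = n_trees,
                psi = psi, seed = seed)
  cut <- adaptive_cutoff(X, y,
                         scores = score_for_columns(screen, colnames(X), covariates),
                         backend = backend, candidates = candidates,
                         alpha = alpha, covariates = covariates,
                         train_fraction = train_fraction, n_perm = n_perm,
                         seed = seed + 1L)
  screened <- union(colnames(X)[cut$selected], covariates)
  screen_tab <- screen$table
  screen_tab$selected <- as.integer(screen_tab$feature %in% screened)

  if (length(setdiff(screened, covariates)) == 0L) {
    warning("screening selected no features; refinement skipped", call. = FALSE)
    importance <- NULL
    final <- covariates
  } else {
    importance <- permfit(X[, screened, drop = FALSE], y, backend = backend,
                          split = split, K = K, train_fraction = train_fraction,
                          n_perm = n_perm, seed = seed + 2L)
    final <- refine(importance, alpha = alpha, keep = covariates)
    importance$selected_final <- as.integer(importance$feature %in% final)
  }
  if (length(final) == 0L) {
    stop("no features survive refinement and no covariates are available",
         call. = FALSE)
  }
  if (identical(sort(final), sort(covariates %||% character(0))) &&
      length(setdiff(screened, covariates)) > 0L) {
    warning("no screened feature passed the importance test; ",
            "final model uses covariates only", call. = FALSE)
  }
  model <- fit_backend(backend_spec(backend$name, seed = seed + 3L),
                       X[, final, drop = FALSE], y, kind)
  metrics <- NULL
  if (!is.null(newdata)) {
    pred <- predict(model, newdata)
    metrics <- if (!is.null(newy)) evaluate_prediction(newy, pred, kind) else NULL
    metrics <- c(list(predictions = pred), metrics)
  }
  structure(list(
    screening = screen_tab, tau = cut$tau, bins = cut$bins,
    importance = importance, screened = screened, final_features = final,
    model = model, metrics = metrics,
    manifest = list(backend = backend$name, kind = kind, M = M, delta = delta,
                    kernel = kernel, bandwidth = bandwidth, n_trees = n_trees,
                    psi = psi, candidates = candidates, split = split, K = K,
                    train_fraction = train_fraction, alpha = alpha,
                    n_perm = n_perm, seed = seed, covariates = covariates,
                    package_version = as.character(utils::packageVersion("hifit")))),
    class = "hifit")
}

# scores aligned to all columns of X; covariates get +Inf so they are never
# dropped by the cutoff threshold
score_for_columns <- function(screen, cols, covariates) {
  s <- rep(-Inf, length(cols))
  names(s) <- cols
  s[screen$table$feature] <- screen$table$score
  if (!is.null(covariates)) s[covariates] <- Inf
  unname(s)
}

#' @export
print.hifit <- function(x, ...) {
  cat(sprintf("HiFIT run (%s backend, %s outcome)\n", x$manifest$backend,
              x$manifest$kind))
  cat(sprintf("  screened: %d features at tau = %.2f\n",
              length(x$screened), x$tau))
  cat(sprintf("  refined:  %d features at alpha = %.2g\n",
              length(x$final_features), x$manifest$alpha))
  if (!is.null(x$metrics)) {
    m <- x$metrics[setdiff(names(x$metrics), "predictions")]
    if (length(m)) {
      cat("  held-out: ",
          paste(sprintf("%s = %.3f", names(m),
                        vapply(m, as.numeric, 0)), collapse = ", "), "\n")
    }
  }
  invisible(x)
}
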