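#' Default candidate grid for the anomaly-score cutoff
#'
#' @return the candidate vector `(0.5, 0.55, 0.6, 0.65, 0.7)`.
#' @export
hfs_cutoff_grid <- function() c(0.5, 0.55, 0.6, 0.65, 0.7)

check_candidates <- function(candidates) {
  if (length(candidates) < 2L || any(diff(candidates) <= 0) ||
      any(candidates < 0) || any(candidates > 1)) {
    stop("'candidates' must be a strictly increasing vector in [0, 1]", call. = FALSE)
  }
  candidates
}

#' Bin features by anomaly score over the candidate grid
#'
#' Bin `r` holds the features with scores in the half-open interval
#' `[tau_{r-1}, tau_r)`; features at or above the largest candidate form the
#' top stratum, which is always retained.
#'
#' @param scores anomaly-score vector.
#' @param candidates ordered cutoff candidates `(tau_0, ..., tau_R)`.
#' @return a list with `bins` (list of integer index vectors, one per
#'   interval) and `top` (indices at or above the last candidate).
#' @export
bin_features <- function(scores, candidates = hfs_cutoff_grid()) {
  candidates <- check_candidates(candidates)
  R <- length(candidates) - 1L
  bins <- lapply(seq_len(R), function(r) {
    which(scores >= candidates[r] & scores < candidates[r + 1L])
  })
  list(bins = bins, top = which(scores >= candidates[R + 1L]))
}

#' Set-level permutation importance
#'
#' The permutation-importance contrast applied to a whole block of features
#' permuted jointly (each column receives an independent permutation). Used
#' to test whether an anomaly-score stratum carries predictive signal. An
#' empty set scores 0 with p-value 1.
#'
#' @param model fitted model trained on features including the set.
#' @param X,y validation data.
#' @param set feature names or indices permuted jointly.
#' @param n_perm permutation passes averaged.
#' @return a list with `importance`, `se`, `z`, `p_value`, `n_validation`.
#' @export
set_importance <- function(model, X, y, set, n_perm = 1L) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (length(set) == 0L) {
    return(list(importance = 0, se = 0, z = 0, p_value = 1, n_validation = length(y)))
  }
  if (is.numeric(set)) set <- colnames(X)[set]
  set <- intersect(set, model$features)
  if (length(set) == 0L) {
    return(list(importance = 0, se = 0, z = 0, p_value = 1, n_validation = length(y)))
  }
  base_loss <- sample_loss(y, predict(model, X), model$kind)
  aggregate_contrast(block_contrast(model, X, y, set, base_loss, n_perm))
}

#' Choose the cutoff from bin p-values
#'
#' Scans the score bins from the lowest interval upward and returns the
#' lower edge of the first bin whose set-importance p-value falls below
#' `alpha`, so that the significant stratum and everything above it are
#' retained. When no bin is significant the largest candidate is returned
#' (keep only the top stratum).
#'
#' @param p_values length-R vector of bin p-values (low interval first).
#' @param candidates the cutoff candidates used to form the bins.
#' @param alpha significance threshold (default 0.1).
#' @return the selected cutoff tau.
#' @export
select_tau <- function(p_values, candidates = hfs_cutoff_grid(), alpha = 0.1) {
  candidates <- check_candidates(candidates)
  if (length(p_values) != length(candidates) - 1L) {
    stop("'p_values' must have one entry per bin", call. = FALSE)
  }
  hit <- which(p_values < alpha)
  if (length(hit) == 0L) return(candidates[length(candidates)])
  candidates[hit[1L]]
}

#' Data-driven anomaly-score cutoff
#'
#' Fits the backend once on all features at or above the smallest candidate
#' cutoff (plus any always-kept covariates), estimates the set importance of
#' every candidate-interval bin on a held-out validation split, and picks
#' the cutoff with [select_tau()].
#'
#' @param X,y full data (features as columns).
#' @param scores anomaly scores aligned with `colnames(X)`.
#' @param backend a [backend_spec()] or name.
#' @param candidates cutoff candidate grid.
#' @param alpha bin significance threshold.
#' @param covariates names of always-kept columns included in the model but
#'   never binned or permuted.
#' @param train_fraction fraction of samples used to fit the backend; the
#'   rest evaluate the set contrasts.
#' @param n_perm permutation passes per bin.
#' @param seed seed for split, fit, and permutations.
#' @return list with `tau`, `selected` (integer indices into `colnames(X)`
#'   with `scores >= tau`), and `bins`, a tibble of per-bin diagnostics.
#' @export
adaptive_cutoff <- function(X, y, scores, backend = "xgboost",
                            candidates = hfs_cutoff_grid(), alpha = 0.1,
                            covariates = NULL, train_fraction = 0.8,
                            n_perm = 1L, seed = NULL) {
  candidates <- check_candidates(candidates)
  X <- validate_features(X)
  kind <- validate_outcome(y, nrow(X))
  if (length(scores) != ncol(X)) stop("'scores' must match columns of 'X'", call. = FALSE)
  R <- length(candidates) - 1L
  strata <- bin_features(scores, candidates)
  base_idx <- which(scores >= candidates[1L])
  model_cols <- union(colnames(X)[base_idx], covariates)
  empty_bins <- tibble::tibble(
    bin = seq_len(R), lower = candidates[-length(candidates)],
    upper = candidates[-1L],
    size = vapply(strata$bins, length, 0L),
    importance = 0, se = 0, p_value = 1)
  if (length(model_cols) == 0L) {
    return(list(tau = candidates[length(candidates)], selected = integer(0),
                bins = empty_bins))
  }
  res <- run_seeded(seed, function() {
    n <- nrow(X)
    tr <- sample.int(n, round(train_fraction * n))
    va <- setdiff(seq_len(n), tr)
    model <- fit_backend(backend, X[tr, model_cols, drop = FALSE], y[tr], kind)
    Xv <- X[va, model_cols, drop = FALSE]
    lapply(strata$bins, function(b) {
      set_importance(model, Xv, y[va], setdiff(colnames(X)[b], covariates), n_perm)
    })
  })
  bins <- tibble::tibble(
    bin = seq_len(R), lower = candidates[-length(candidates)],
    upper = candidates[-1L],
    size = vapply(strata$bins, length, 0L),
    importance = vapply(res, `[[`, 0, "importance"),
    se = vapply(res, `[[`, 0, "se"),
    p_value = vapply(res, `[[`, 0, "p_value"))
  tau <- select_tau(bins$p_value, candidates, alpha)
  list(tau = tau, selected = select_features(scores, tau), bins = bins)
}
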