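# Average unsuccessful-search path length in a binary search tree of m
# points; the standard isolation-forest normalizer.
c_factor <- function(m) {
  if (m <= 1) return(0)
  if (m == 2) return(1)
  2 * (log(m - 1) + 0.5772156649015329) - 2 * (m - 1) / m
}

build_itree <- function(pts, depth, hlim) {
  m <- nrow(pts)
  if (m <= 1L || depth >= hlim) return(list(size = m))
  lo <- apply(pts, 2L, min)
  hi <- apply(pts, 2L, max)
  open <- which(hi > lo)
  if (!length(open)) return(list(size = m))  # all points identical
  q <- if (length(open) == 1L) open else sample(open, 1L)
  split <- runif(1L, lo[q], hi[q])
  left <- pts[, q] < split
  list(q = q, split = split,
       left = build_itree(pts[left, , drop = FALSE], depth + 1L, hlim),
       right = build_itree(pts[!left, , drop = FALSE], depth + 1L, hlim))
}

itree_paths <- function(node, pts, idx, depth, out) {
  if (is.null(node$q)) {
    out[idx] <- depth + c_factor(node$size)
    return(out)
  }
  left <- pts[idx, node$q] < node$split
  if (any(left)) out <- itree_paths(node$left, pts, idx[left], depth + 1L, out)
  if (any(!left)) out <- itree_paths(node$right, pts, idx[!left], depth + 1L, out)
  out
}

#' Isolation-forest anomaly scores
#'
#' Fits an ensemble of isolation trees on the rows of `points` (subsample of
#' size `psi` per tree, uniform splits, height limit `ceiling(log2(psi))`)
#' and returns for each row the anomaly score
#' `2^(-mean path length / c(psi))`, where `c(psi)` is the average
#' path-length normalizer. Scores lie in `[0, 1]`; higher means easier to
#' isolate, i.e. more anomalous.
#'
#' @param points numeric matrix, one row per observation.
#' @param n_trees number of isolation trees (default 100).
#' @param psi subsample size per tree (default `min(256, nrow(points))`).
#' @param seed optional seed for the forest's randomness.
#' @return numeric vector of scores, one per row of `points`.
#' @export
isolation_forest <- function(points, n_trees = 100L, psi = NULL, seed = NULL) {
  if (!is.matrix(points)) points <- as.matrix(points)
  m <- nrow(points)
  if (m < 2L) stop("need at least 2 points", call. = FALSE)
  psi <- as.integer(psi %||% min(256L, m))
  if (psi < 2L || psi > m) stop("'psi' must be in [2, nrow(points)]", call. = FALSE)
  hlim <- ceiling(log2(psi))
  run_seeded(seed, function() {
    paths <- matrix(0, m, n_trees)
    for (b in seq_len(n_trees)) {
      rows <- if (psi == m) seq_len(m) else sample.int(m, psi)
      tree <- build_itree(points[rows, , drop = FALSE], 0L, hlim)
      paths[, b] <- itree_paths(tree, points, seq_len(m), 0L, numeric(m))
    }
    2^(-rowMeans(paths) / c_factor(psi))
  })
}

#' Fuse utility pairs into anomaly scores
#'
#' Runs an isolation forest on the p points `(rho1_j, rho2_j)`. Negative
#' adjusted R-squared values are floored at 0 first, so both utility axes
#' point in the direction "stronger association" and anomalous means strong.
#' Points are pre-sorted into a canonical order before the forest is built,
#' making the scores invariant to the input ordering of features under a
#' fixed seed.
#'
#' @param utility a tibble from [hfs_utilities()] (columns `rho1`, `rho2`)
#'   or a two-column numeric matrix.
#' @inheritParams isolation_forest
#' @return numeric vector of anomaly scores in `[0, 1]`, one per feature, in
#'   input order.
#' @export
anomaly_scores <- function(utility, n_trees = 100L, psi = NULL, seed = NULL) {
  pts <- if (is.data.frame(utility)) cbind(utility$rho1, utility$rho2)
         else as.matrix(utility)
  if (ncol(pts) != 2L) stop("'utility' must provide two utility columns", call. = FALSE)
  if (nrow(pts) < 2L) stop("need at least 2 features to score", call. = FALSE)
  pts[, 1L] <- pmax(pts[, 1L], 0)
  ord <- order(pts[, 1L], pts[, 2L])
  sc <- isolation_forest(pts[ord, , drop = FALSE], n_trees = n_trees,
                         psi = psi, seed = seed)
  sc[order(ord)]
}
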