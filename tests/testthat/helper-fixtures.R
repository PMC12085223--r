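# Small in-code fixtures shared across test files.

# independent-normal design with a linear signal in the first `k` features
toy_linear <- function(n, p, k = 3L, beta = NULL, seed = 1L, noise = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("X", seq_len(p))
    beta <- beta %||% rep(1.25, k)
    y <- drop(X[, seq_len(k), drop = FALSE] %*% beta) + noise * rnorm(n)
    list(X = X, y = y, beta = beta)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force AUC: fraction of concordant (positive, negative) pairs,
# ties counted half
auc_bruteforce <- function(y, pred) {
  pos <- pred[y == 1]
  neg <- pred[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
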