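test_that("permute_feature preserves the multiset and other columns", {
  withr::with_seed(1, X <- matrix(rnorm(50 * 4), 50, 4))
  colnames(X) <- paste0("X", 1:4)
  withr::with_seed(2, Xp <- permute_feature(X, 2))
  expect_equal(sort(Xp[, 2]), sort(X[, 2]))
  expect_identical(Xp[, -2], X[, -2])
  withr::with_seed(2, Xp2 <- permute_feature(X, 2))
  expect_identical(Xp, Xp2)
  # single row: a permutation of one element is the identity
  X1 <- X[1, , drop = FALSE]
  expect_identical(permute_feature(X1, 3), X1)
})

test_that("a feature the model cannot see has exactly zero importance", {
  withr::with_seed(5, {
    dat <- toy_linear(200, 4, k = 2)
    X <- cbind(dat$X, const = 1)  # constant column: no tree can split on it
    model <- fit_backend(backend_spec("xgboost", seed = 1), X, dat$y)
    res <- permfit_test(model, X[151:200, ], dat$y[151:200])
    row_const <- res[res$feature == "const", ]
    expect_identical(row_const$importance, 0)
    expect_identical(row_const$p_value, 1)
    # feature absent from the model entirely: 0 / 1 convention
    X2 <- cbind(X[151:200, ], ghost = rnorm(50))
    res2 <- permfit_test(model, X2, dat$y[151:200], features = "ghost")
    expect_identical(res2$importance, 0)
    expect_identical(res2$p_value, 1)
  })
})

test_that("importance results satisfy the z = importance/se identity", {
  withr::with_seed(6, {
    dat <- toy_linear(150, 5, k = 2)
    model <- fit_backend(backend_spec("xgboost", seed = 2), dat$X[1:110, ], dat$y[1:110])
    res <- permfit_test(model, dat$X[111:150, ], dat$y[111:150], n_perm = 2)
    ok <- res$se > 0
    expect_true(any(ok))
    expect_equal(res$z[ok], res$importance[ok] / res$se[ok])
    expect_true(all(res$p_value >= 0 & res$p_value <= 1))
    expect_true(all(res$se >= 0))
  })
})

test_that("signal features reject and cross-fitting pools all samples", {
  withr::with_seed(7, {
    dat <- toy_linear(300, 6, k = 2, beta = c(1.5, 1.2))
    res <- permfit(dat$X, dat$y, backend = "xgboost", split = "kfold", K = 5, seed = 3)
    expect_equal(unique(res$n_validation), 300)
    expect_lt(res$p_value[1], 0.01)
    expect_lt(res$p_value[2], 0.01)
    res_s <- permfit(dat$X, dat$y, backend = "xgboost", split = "single_split",
                     train_fraction = 0.8, seed = 3)
    expect_equal(unique(res_s$n_validation), 60)
  })
})

test_that("a strong linear feature rejects in nearly all replicates", {
  # beta ~ U(1, 1.5) scale signal, model restricted to a screened-size set
  rejections <- 0L
  reps <- 20L
  for (r in seq_len(reps)) {
    dat <- withr::with_seed(100 + r, {
      X <- matrix(rnorm(500 * 15), 500, 15)
      colnames(X) <- paste0("X", 1:15)
      beta <- runif(10, 1, 1.5)
      list(X = X, y = drop(X[, 1:10] %*% beta) + rnorm(500), j = which.max(beta))
    })
    res <- permfit(dat$X, dat$y, backend = "xgboost", split = "single_split",
                   seed = 200 + r)
    if (res$p_value[dat$j] < 0.1) rejections <- rejections + 1L
  }
  expect_gte(rejections, 18L)
})

test_that("more permutation passes do not inflate the variance estimate", {
  withr::with_seed(8, {
    dat <- toy_linear(250, 5, k = 2)
    model <- fit_backend(backend_spec("xgboost", seed = 4), dat$X[1:200, ], dat$y[1:200])
    se1 <- se4 <- numeric(10)
    for (r in 1:10) {
      a <- permfit_test(model, dat$X[201:250, ], dat$y[201:250], n_perm = 1)
      b <- permfit_test(model, dat$X[201:250, ], dat$y[201:250], n_perm = 4)
      se1[r] <- mean(a$se)
      se4[r] <- mean(b$se)
    }
    expect_lte(mean(se4), mean(se1) * 1.05)
  })
})

test_that("binary outcomes use the log-likelihood contrast", {
  withr::with_seed(9, {
    n <- 300
    X <- matrix(rnorm(n * 5), n, 5)
    colnames(X) <- paste0("X", 1:5)
    y <- rbinom(n, 1, plogis(2.5 * X[, 1]))
    res <- permfit(X, y, backend = "xgboost", split = "single_split", seed = 10)
    expect_lt(res$p_value[1], 0.05)
    expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  })
})

test_that("refine keeps sub-alpha features plus exempt covariates", {
  imp <- tibble::tibble(feature = c("a", "b", "c"),
                        p_value = c(0.05, 0.5, 0.09))
  expect_equal(refine(imp, alpha = 0.1), c("a", "c"))
  expect_equal(refine(imp, alpha = 1), c("a", "b", "c"))
  imp$p_value <- rep(1, 3)
  expect_equal(refine(imp, alpha = 0.1, keep = "age"), "age")
  # BH adjustment can only shrink the list
  imp$p_value <- c(0.01, 0.09, 0.5)
  expect_true(all(refine(imp, adjust = TRUE) %in% refine(imp)))
})
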