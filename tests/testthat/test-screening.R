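test_that("polynomial utility matches hand-solved least squares", {
  # exact first-order fit
  expect_equal(polynomial_utility(1:5, 2 * (1:5), M = 1), 1)

  # normal-equations oracle: x = 1..5, y as below, M = 1
  # slope = Sxy/Sxx = 10/10 = 1, intercept = 0.04, SSE = 0.072, SST = 10.072,
  # adjusted R2 = 1 - (4/3) * SSE/SST = 0.99046863...
  y <- c(1.1, 1.9, 3.2, 3.9, 5.1)
  expect_equal(polynomial_utility(1:5, y, M = 1),
               1 - (4 / 3) * 0.072 / 10.072, tolerance = 1e-10)

  withr::with_seed(2, {
    x <- rnorm(30)
    expect_warning(r <- polynomial_utility(x, rep(1.5, 30), M = 2), "constant outcome")
    expect_equal(r, 0)
    expect_warning(r2 <- polynomial_utility(rep(2, 30), rnorm(30)), "zero variance")
    expect_equal(r2, 0)
  })
  expect_error(polynomial_utility(1:3, 1:3, M = 2), "n > M")
})

test_that("binary utility is McFadden pseudo R-squared with separation fallback", {
  withr::with_seed(3, {
    x <- rnorm(200)
    y <- rbinom(200, 1, plogis(2 * x))
    r_strong <- polynomial_utility(x, y, M = 2)
    r_null <- polynomial_utility(rnorm(200), y, M = 2)
    expect_gt(r_strong, r_null)
    expect_gte(r_null, 0)
    expect_lte(r_strong, 1)
    # quasi-complete separation triggers the ridge fallback, still finite
    xs <- c(rnorm(20, -3), rnorm(20, 3))
    ys <- rep(c(0, 1), each = 20)
    expect_warning(rs <- polynomial_utility(xs, ys, M = 1), "separated")
    expect_true(is.finite(rs) && rs > 0.5)
  })
})

test_that("utility table matches the scalar operations and flags degeneracy", {
  withr::with_seed(13, {
    n <- 120
    X <- cbind(s = rnorm(n), dup = 0, noise = rnorm(n), flat = 1)
    X[, "dup"] <- X[, "s"]
    y <- 1.5 * X[, "s"] + rnorm(n)
    ut <- hfs_utilities(X, y)
    expect_equal(ut$rho1[1], polynomial_utility(X[, 1], y, M = 2))
    expect_equal(ut$rho2[1], kpc_coefficient(X[, 1], y))
    # duplicated columns get identical utilities
    expect_equal(ut$rho1[1], ut$rho1[2])
    expect_equal(ut$rho2[1], ut$rho2[2])
    # degenerate feature flagged, not fatal
    expect_match(ut$flag[4], "zero variance")
    expect_equal(ut$rho1[4], 0)
    expect_equal(ut$rho2[4], 0)
    expect_true(all(ut$rho2 >= 0 & ut$rho2 <= 1))
  })
})

test_that("strongest feature attains both maximal utilities", {
  withr::with_seed(17, {
    n <- 500
    X <- matrix(rnorm(n * 3), n, 3)
    y <- 2 * X[, 1] + rnorm(n)
    ut <- hfs_utilities(X, y)
    expect_equal(which.max(ut$rho1), 1L)
    expect_equal(which.max(ut$rho2), 1L)
  })
  # single-feature table is consistent with the scalar ops
  withr::with_seed(18, {
    x <- matrix(rnorm(60), ncol = 1)
    y <- drop(x) + rnorm(60)
    ut1 <- hfs_utilities(x, y)
    expect_equal(nrow(ut1), 1L)
    expect_equal(ut1$rho1, polynomial_utility(drop(x), y, M = 2))
  })
})

test_that("select_features applies an inclusive threshold", {
  expect_equal(select_features(c(0.4, 0.55, 0.7), 0.55), c(2L, 3L))
  expect_equal(select_features(c(0.4, 0.55, 0.7), 0), 1:3)
  expect_length(select_features(c(0.4, 0.55, 0.7), 1.01), 0)
})

test_that("fused anomaly score ranks planted features at least as well as either utility", {
  # linear scenario; fused ranking should not be worse than the better of
  # the two marginal utilities for the 10 planted features
  scn <- sim_scenario("linear", n = 500, p = 500, seed = 3)
  wins <- 0L
  reps <- 20L
  for (r in seq_len(reps)) {
    dat <- hifit:::sim_replicate(scn, seed = 5000 + r)
    sc <- hfs(dat$X, dat$y, seed = r)
    mean_rank <- function(s) mean(rank(-s, ties.method = "average")[1:10])
    fused <- mean_rank(sc$table$score)
    single <- min(mean_rank(pmax(sc$table$rho1, 0)), mean_rank(sc$table$rho2))
    if (fused <= single + 1e-9) wins <- wins + 1L
  }
  expect_gte(wins, 0.8 * reps)
})
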