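test_that("block-correlated Gaussian design has the configured moments", {
  X <- gen_design(5000, 20, "mvn_block", block_size = 10, rho = 0.3, seed = 1)
  se_mean <- 1 / sqrt(5000)
  expect_true(all(abs(colMeans(X)) < 3 * se_mean))
  expect_true(all(abs(apply(X, 2, var) - 1) < 0.1))
  C <- cor(X)
  within <- C[1:10, 1:10][upper.tri(diag(10))]
  across <- C[1:10, 11:20]
  expect_lt(abs(mean(within) - 0.3), 0.03)
  expect_lt(abs(mean(across)), 0.03)
  # reproducibility
  expect_identical(X, gen_design(5000, 20, "mvn_block", seed = 1))
})

test_that("non-Gaussian designs emit the stated families", {
  Xm <- gen_design(200, 15, "multinomial", seed = 2)
  expect_true(all(Xm %in% 0:2))
  Xp <- gen_design(200, 15, "poisson_lognormal", seed = 3)
  expect_true(all(Xp >= 0 & Xp == round(Xp)))
  expect_error(gen_design(100, 10, rho = 1.2), "rho")
})

test_that("outcome generators follow the printed closed forms", {
  # all-zero design and known noise: the nonlinear signal vanishes
  X0 <- matrix(0, 20, 10)
  noise <- withr::with_seed(5, rnorm(20))
  expect_equal(gen_outcome(X0, "nonlinear", seed = 5), noise)
  # one-hot row picks out a single coefficient in the linear model
  beta <- seq(1, 1.45, by = 0.05)
  Xe <- diag(10)
  y <- gen_outcome(Xe, "linear", beta = beta, seed = 6)
  expect_equal(y - withr::with_seed(6, rnorm(10)), beta)
  # a nonlinear spot value: 2sin(2) for x1 = 1, everything else 0
  X1 <- matrix(0, 5, 10)
  X1[, 1] <- 1
  y1 <- gen_outcome(X1, "nonlinear", seed = 7)
  expect_equal(y1 - withr::with_seed(7, rnorm(5)), rep(2 * sin(2), 5))
  expect_error(gen_outcome(X0, "linear", beta = 1:3), "length-10")
})

test_that("linear outcome variance matches the block-covariance closed form", {
  scn <- sim_scenario("linear", n = 1e5, p = 10, seed = 4)
  dat <- hifit:::sim_replicate(scn, seed = 8)
  beta <- scn$beta
  analytic <- 0.7 * sum(beta^2) + 0.3 * sum(beta)^2 + 1
  expect_lt(abs(var(dat$y) / analytic - 1), 0.03)
})

test_that("coefficients are drawn once per scenario and reused across replicates", {
  s1 <- sim_scenario("linear", p = 50, seed = 9)
  s2 <- sim_scenario("linear", p = 50, seed = 9)
  expect_identical(s1$beta, s2$beta)
  expect_true(all(s1$beta >= 1 & s1$beta <= 1.5))
  d1 <- hifit:::sim_replicate(s1, seed = 1)
  d2 <- hifit:::sim_replicate(s1, seed = 2)
  expect_false(identical(d1$X, d2$X))
})

test_that("selection metrics match their definitions", {
  expect_equal(evaluate_selection(1:10)[c("recall", "precision")],
               list(recall = 1, precision = 1))
  expect_equal(evaluate_selection(1:20)[c("recall", "precision")],
               list(recall = 1, precision = 0.5))
  expect_equal(evaluate_selection(integer(0))[c("recall", "precision")],
               list(recall = 0, precision = 0))
  # names are translated and ranks summarized
  ev <- evaluate_selection(c("X1", "X2"), important = 1:2,
                           scores = c(0.9, 0.8, 0.1, 0.2))
  expect_equal(ev$recall, 1)
  expect_equal(ev$mean_rank, 1.5)
})

test_that("prediction metrics agree with brute-force oracles", {
  y <- c(1.2, -0.5, 3, 0.1)
  expect_equal(evaluate_prediction(y, y), list(mse = 0, pcc = 1, pcc_degenerate = FALSE))
  yc <- y - mean(y)
  expect_equal(evaluate_prediction(yc, -yc)$pcc, -1)
  expect_equal(evaluate_prediction(y, rep(1, 4))$pcc, 0)  # degenerate flagged
  expect_true(evaluate_prediction(y, rep(1, 4))$pcc_degenerate)

  # AUC against the concordant-pair count, including a tie
  yb <- c(0, 0, 1, 1)
  pr <- c(0.1, 0.4, 0.4, 0.8)
  expect_equal(evaluate_prediction(yb, pr, "binary")$auc, auc_bruteforce(yb, pr))
  withr::with_seed(12, {
    for (i in 1:5) {
      yb <- rbinom(30, 1, 0.5)
      if (length(unique(yb)) < 2) next
      pr <- runif(30)
      expect_equal(evaluate_prediction(yb, pr, "binary")$auc, auc_bruteforce(yb, pr))
    }
  })
  expect_equal(evaluate_prediction(c(0, 1, 1, 0), c(0.2, 0.8, 0.6, 0.4), "binary")$accuracy, 1)
})

test_that("benchmark harness emits one row per scenario/backend/variant and is reproducible", {
  scn <- sim_scenario("linear", n = 60, p = 50, seed = 13)
  res <- run_benchmark(scn, backends = "xgboost", replicates = 2, seed = 99,
                       variants = c("screened", "full"))
  expect_equal(nrow(res), 4L)
  expect_setequal(unique(res$variant), c("screened", "full"))
  expect_true(all(res$recall >= 0 & res$recall <= 1, na.rm = TRUE))
  res2 <- run_benchmark(scn, backends = "xgboost", replicates = 2, seed = 99,
                        variants = c("screened", "full"))
  expect_identical(res, res2)
})
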