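#' Define a simulation scenario
#'
#' Captures the parameters of one synthetic study: outcome model, sample
#' size, dimension, predictor design, and the coefficient vector of the ten
#' important features. For the linear scenario the coefficients are drawn
#' once from U(1, 1.5) under `seed` and held fixed across all replicates of
#' the scenario.
#'
#' @param scenario `"linear"` (additive effects) or `"nonlinear"`
#'   (sin/log-quadratic/interaction effects).
#' @param n samples per replicate (default 500).
#' @param p number of features (10 important + p-10 noise).
#' @param design predictor family, see [gen_design()].
#' @param block_size,rho block-correlation parameters.
#' @param split_ratio train fraction for benchmark splits (default 0.9).
#' @param seed seed fixing the coefficient draw.
#' @return an object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(scenario = c("linear", "nonlinear"), n = 500L, p = 500L,
                         design = "mvn_block", block_size = 10L, rho = 0.3,
                         split_ratio = 0.9, seed = 1L) {
  scenario <- match.arg(scenario)
  if (p < 10L) stop("'p' must be at least 10", call. = FALSE)
  beta <- if (scenario == "linear") {
    run_seeded(seed, function() runif(10L, 1, 1.5))
  } else NULL
  structure(list(scenario = scenario, n = n, p = p, design = design,
                 block_size = block_size, rho = rho,
                 split_ratio = split_ratio, beta = beta, seed = seed),
            class = "sim_scenario")
}

#' Generate a block-correlated predictor matrix
#'
#' `mvn_block` draws standard-normal marginals with exchangeable correlation
#' `rho` inside consecutive blocks of `block_size` features and independence
#' across blocks. `multinomial` cuts the same latent Gaussian field at its
#' terciles into categories \{0, 1, 2\}; `poisson_lognormal` draws
#' `Poisson(exp(Z))` counts from the latent field.
#'
#' @param n,p dimensions.
#' @param design predictor family.
#' @param block_size features per correlated block.
#' @param rho within-block correlation, in `[0, 1)`.
#' @param seed optional seed.
#' @return an `n x p` matrix with columns `X1..Xp`.
#' @export
gen_design <- function(n, p, design = c("mvn_block", "multinomial", "poisson_lognormal"),
                       block_size = 10L, rho = 0.3, seed = NULL) {
  design <- match.arg(design)
  if (rho < 0 || rho >= 1) stop("'rho' must be in [0, 1)", call. = FALSE)
  run_seeded(seed, function() {
    Z <- matrix(rnorm(n * p), n, p)
    if (rho > 0) {
      n_blocks <- ceiling(p / block_size)
      shared <- matrix(rnorm(n * n_blocks), n, n_blocks)
      block_of <- rep(seq_len(n_blocks), each = block_size)[seq_len(p)]
      Z <- sqrt(rho) * shared[, block_of, drop = FALSE] + sqrt(1 - rho) * Z
    }
    X <- switch(design,
      mvn_block = Z,
      multinomial = {
        cuts <- qnorm(c(1 / 3, 2 / 3))
        matrix(findInterval(Z, cuts), n, p)
      },
      poisson_lognormal = matrix(rpois(n * p, exp(Z)), n, p))
    colnames(X) <- paste0("X", seq_len(p))
    X
  })
}

#' Generate the outcome from a design matrix
#'
#' Linear: `y = sum_{j=1..10} beta_j x_j + e`. Nonlinear:
#' `y = sum_{j=1..4} 2 sin(2 x_j) - sum_{j=5..8} 2 log(2 x_j^2 + 1)
#'  + x_9 exp(x_10) + e`, with `e ~ N(0, 1)` i.i.d. In both cases exactly
#' the first ten columns are important.
#'
#' @param X design matrix with at least 10 columns.
#' @param scenario `"linear"` or `"nonlinear"`.
#' @param beta length-10 coefficient vector (linear scenario).
#' @param seed optional seed for the noise draw.
#' @return numeric outcome vector.
#' @export
gen_outcome <- function(X, scenario = c("linear", "nonlinear"), beta = NULL,
                        seed = NULL) {
  scenario <- match.arg(scenario)
  if (ncol(X) < 10L) stop("'X' must have at least 10 columns", call. = FALSE)
  signal <- if (scenario == "linear") {
    if (is.null(beta) || length(beta) != 10L) {
      stop("linear scenario needs a length-10 'beta'", call. = FALSE)
    }
    drop(X[, 1:10, drop = FALSE] %*% beta)
  } else {
    rowSums(2 * sin(2 * X[, 1:4, drop = FALSE])) -
      rowSums(2 * log(2 * X[, 5:8, drop = FALSE]^2 + 1)) +
      X[, 9] * exp(X[, 10])
  }
  run_seeded(seed, function() signal + rnorm(nrow(X)))
}

# generate one replicate (X, y) for a scenario
sim_replicate <- function(scn, seed = NULL) {
  X <- gen_design(scn$n, scn$p, scn$design, scn$block_size, scn$rho, seed = seed)
  y <- gen_outcome(X, scn$scenario, scn$beta,
                   seed = if (is.null(seed)) NULL else seed + 1L)
  list(X = X, y = y)
}

#' Selection quality of a feature set
#'
#' Recall is the fraction of important features selected; precision the
#' fraction of selected features that are important (0 when nothing is
#' selected). Optionally reports the mean rank of the important features
#' under a score vector (rank 1 = highest score).
#'
#' @param selected selected features (integer indices or names `X<j>`).
#' @param important the important features (default the first ten).
#' @param scores optional score vector for the rank summary.
#' @return list with `recall`, `precision`, `n_selected`, and `mean_rank`
#'   when scores are given.
#' @export
evaluate_selection <- function(selected, important = 1:10, scores = NULL) {
  if (is.character(selected)) selected <- as.integer(sub("^X", "", selected))
  hits <- length(intersect(selected, important))
  out <- list(recall = hits / length(important),
              precision = if (length(selected)) hits / length(selected) else 0,
              n_selected = length(selected))
  if (!is.null(scores)) {
    rk <- rank(-scores, ties.method = "average")
    out$mean_rank <- mean(rk[important])
  }
  out
}

#' Prediction quality metrics
#'
#' Continuous outcomes: mean squared error and Pearson correlation (reported
#' as 0 with `pcc_degenerate = TRUE` when either vector is constant). Binary
#' outcomes: accuracy at the 0.5 probability threshold and AUC.
#'
#' @param y_true observed outcome.
#' @param y_pred predictions (probabilities for binary).
#' @param kind outcome kind, detected from `y_true` when `NULL`.
#' @return named list of metrics.
#' @export
evaluate_prediction <- function(y_true, y_pred, kind = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  kind <- kind %||% outcome_kind(y_true)
  if (kind == "continuous") {
    degen <- sd(y_pred) == 0 || sd(y_true) == 0
    list(mse = mean((y_true - y_pred)^2),
         pcc = if (degen) 0 else cor(y_true, y_pred),
         pcc_degenerate = degen)
  } else {
    auc <- as.numeric(pROC::auc(pROC::roc(response = y_true, predictor = y_pred,
                                          levels = c(0, 1), direction = "<",
                                          quiet = TRUE)))
    list(accuracy = mean((y_pred >= 0.5) == y_true), auc = auc)
  }
}

#' Benchmark screening and refinement across model variants
#'
#' For each replicate of each scenario: simulate, split train/test, run the
#' hybrid screen with the adaptive cutoff per backend, and evaluate up to
#' three variants per backend on the held-out split: `full` (all p
#' features), `screened` (features above the chosen cutoff), and `refined`
#' (screened features passing the permutation importance test at
#' `alpha`). Selection metrics are reported against the ten planted
#' features. Failed replicates are dropped with a count in the
#' `"failures"` attribute.
#'
#' @param scenarios a `sim_scenario` or list of them.
#' @param backends backend names for the screened variant.
#' @param replicates Monte Carlo replicates per scenario.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param variants subset of `c("full", "screened", "refined")`.
#' @param full_backends,refined_backends backends used for the `full` and
#'   `refined` variants (default: same as `backends`).
#' @param alpha refinement p-value threshold.
#' @param n_perm permutation passes in the importance tests.
#' @return tibble with one row per (scenario, replicate, backend, variant):
#'   selection and prediction metrics.
#' @export
run_benchmark <- function(scenarios, backends = c("xgboost", "svm_rbf"),
                          replicates = 20L, seed = 1L,
                          variants = c("screened", "full", "refined"),
                          full_backends = NULL, refined_backends = NULL,
                          alpha = 0.1, n_perm = 1L) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  variants <- match.arg(variants, several.ok = TRUE)
  full_backends <- full_backends %||% backends
  refined_backends <- refined_backends %||% backends
  rows <- list()
  failures <- 0L
  for (scn in scenarios) {
    seeds <- child_seeds(seed + scn$p + (scn$scenario == "nonlinear") * 7L,
                         replicates)
    for (r in seq_len(replicates)) {
      res <- tryCatch(
        benchmark_replicate(scn, seeds[r], backends, variants, full_backends,
                            refined_backends, alpha, n_perm),
        error = function(e) {
          warning(sprintf("replicate %d (%s, p=%d) failed: %s", r, scn$scenario,
                          scn$p, conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (is.null(res)) {
        failures <- failures + 1L
        next
      }
      res$replicate <- r
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  out
}

benchmark_replicate <- function(scn, rep_seed, backends, variants,
                                full_backends, refined_backends, alpha, n_perm) {
  dat <- sim_replicate(scn, seed = rep_seed)
  n <- scn$n
  tr <- run_seeded(rep_seed + 2L, function() sample.int(n, round(scn$split_ratio * n)))
  te <- setdiff(seq_len(n), tr)
  Xtr <- dat$X[tr, , drop = FALSE]
  ytr <- dat$y[tr]
  Xte <- dat$X[te, , drop = FALSE]
  yte <- dat$y[te]
  screen <- NULL
  if (any(c("screened", "refined") %in% variants)) {
    screen <- hfs(Xtr, ytr, seed = rep_seed + 3L)
  }
  out <- list()
  add_row <- function(backend, variant, sel, pred_metrics, sel_metrics) {
    tibble::tibble(scenario = scn$scenario, p = scn$p, backend = backend,
                   variant = variant, n_selected = sel_metrics$n_selected,
                   recall = sel_metrics$recall, precision = sel_metrics$precision,
                   mse = pred_metrics$mse, pcc = pred_metrics$pcc)
  }
  all_sel <- list(recall = NA_real_, precision = NA_real_, n_selected = ncol(Xtr))
  for (bk in unique(c(backends, full_backends, refined_backends))) tryCatch({
    bseed <- rep_seed + 10L + match(bk, c("xgboost", "random_forest", "svm_rbf", "ensemble_dnn"))
    sel_idx <- NULL
    if ((bk %in% backends && "screened" %in% variants) ||
        (bk %in% refined_backends && "refined" %in% variants)) {
      cut <- adaptive_cutoff(Xtr, ytr, screen$table$score, backend = backend_spec(bk),
                             alpha = alpha, n_perm = n_perm, seed = bseed)
      sel_idx <- cut$selected
    }
    if (bk %in% backends && "screened" %in% variants) {
      sm <- evaluate_selection(sel_idx, scores = screen$table$score)
      if (length(sel_idx)) {
        model <- fit_backend(backend_spec(bk, seed = bseed + 1L),
                             Xtr[, sel_idx, drop = FALSE], ytr)
        pm <- evaluate_prediction(yte, predict(model, Xte), "continuous")
      } else {
        pm <- list(mse = NA_real_, pcc = NA_real_)
      }
      out[[length(out) + 1L]] <- add_row(bk, "screened", sel_idx, pm, sm)
    }
    if (bk %in% refined_backends && "refined" %in% variants) {
      if (length(sel_idx)) {
        imp <- permfit(Xtr[, sel_idx, drop = FALSE], ytr, backend = backend_spec(bk),
                       split = "single_split", n_perm = n_perm, seed = bseed + 2L)
        final <- refine(imp, alpha = alpha)
      } else {
        final <- character(0)
      }
      sm <- evaluate_selection(final)
      if (length(final)) {
        model <- fit_backend(backend_spec(bk, seed = bseed + 3L),
                             Xtr[, final, drop = FALSE], ytr)
        pm <- evaluate_prediction(yte, predict(model, Xte), "continuous")
      } else {
        pm <- list(mse = NA_real_, pcc = NA_real_)
      }
      out[[length(out) + 1L]] <- add_row(bk, "refined", final, pm, sm)
    }
    if (bk %in% full_backends && "full" %in% variants) {
      model <- fit_backend(backend_spec(bk, seed = bseed + 4L), Xtr, ytr)
      pm <- evaluate_prediction(yte, predict(model, Xte), "continuous")
      out[[length(out) + 1L]] <- add_row(bk, "full", NULL, pm, all_sel)
    }
  }, error = function(e) {
    warning(sprintf("backend %s failed on one replicate: %s", bk,
                    conditionMessage(e)), call. = FALSE)
  })
  do.call(rbind, out)
}
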