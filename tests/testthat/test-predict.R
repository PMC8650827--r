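test_that("feature matrices have the representation-specific widths", {
  ex <- get_default_experiment(11)
  f <- ex$features
  expect_equal(ncol(f$baseline$values), 2)
  expect_equal(ncol(f$`2d`$values), 4)
  expect_equal(ncol(f$categorial$values), 2 + ex$rep$cluster_model$n_final)
  expect_equal(ncol(f$`50d`$values), 50)
  ## 50d is the NMF scores alone
  expect_equal(unname(f$`50d`$values), unname(ex$rep$nmf$scores))
  expect_error(build_features(ex$cohort, "categorial"), "cluster_model")
})

test_that("balanced draws equalise the classes without replacement", {
  y <- c(rep(TRUE, 40), rep(FALSE, 160))
  idx <- balanced_indices(y, seed = 3)
  expect_length(idx, 80)
  expect_equal(sum(y[idx]), 40)
  expect_equal(anyDuplicated(idx), 0)
  ## already balanced: everyone drawn once
  y2 <- rep(c(TRUE, FALSE), 25)
  expect_setequal(balanced_indices(y2, 1), seq_along(y2))
  expect_identical(balanced_indices(y, 9), balanced_indices(y, 9))
  expect_error(balanced_indices(rep(TRUE, 10), 1), "degenerate")
})

test_that("the inner grid enumerates 18 points and breaks ties lexically", {
  withr::with_seed(1, {
    X <- matrix(rnorm(80 * 3), 80, 3)
    y <- rep(c(0, 1), 40)
  })
  fit <- fit_gbm_nested(X, y, seed = 2)
  expect_equal(nrow(fit$grid_accuracy), 18)
  expect_setequal(unique(fit$grid_accuracy$loss), c("deviance", "exponential"))
  ## constant features make every grid point identical: the tie goes to
  ## (deviance, 100, depth 1)
  Xc <- matrix(1, 60, 2)
  yc <- rep(c(0, 1), 30)
  fitc <- fit_gbm_nested(Xc, yc, seed = 1)
  expect_equal(fitc$chosen$loss, "deviance")
  expect_equal(fitc$chosen$n_estimators, 100L)
  expect_equal(fitc$chosen$max_depth, 1L)
})

test_that("separable data is fit perfectly and scored correctly", {
  X <- matrix(c(1:40), 40, 1)
  y <- as.numeric(X[, 1] > 20)
  m <- gbm_fit(X, y, "deviance", n_estimators = 50, max_depth = 1)
  expect_equal(mean(predict(m, X, type = "class") == y), 1)
  sc <- score_model(m, X, y)
  expect_equal(sc$accuracy, 1)
  expect_equal(sc$auroc, 1)
  ## constant scores: accuracy by sign, AUROC 0.5 by tie correction
  expect_equal(lesionlatent:::rank_auroc(rep(0.3, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  ## single-class test set: AUROC undefined, accuracy still returned
  sc2 <- score_model(m, X[30:40, , drop = FALSE], y[30:40])
  expect_true(is.na(sc2$auroc))
  expect_equal(sc2$accuracy, 1)
})

test_that("the deviance arm agrees with an independent boosting implementation", {
  skip_if_not_installed("xgboost")
  withr::with_seed(12, {
    X <- matrix(rnorm(200 * 10), 200, 10)
    y <- as.numeric(X[, 1] + 0.8 * X[, 2] + rnorm(200, sd = 0.6) > 0)
    Xt <- matrix(rnorm(300 * 10), 300, 10)
    yt <- as.numeric(Xt[, 1] + 0.8 * Xt[, 2] + rnorm(300, sd = 0.6) > 0)
  })
  ours <- gbm_fit(X, y, "deviance", n_estimators = 300, max_depth = 3)
  acc_ours <- mean(predict(ours, Xt, type = "class") == yt)
  ref <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                  nthread = 1),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = 300, verbose = 0)
  pref <- as.integer(predict(ref, xgboost::xgb.DMatrix(Xt, nthread = 1)) > 0.5)
  expect_lt(abs(acc_ours - mean(pref == yt)), 0.05)
  expect_gt(mean(predict(ours, Xt, type = "class") == pref), 0.85)
})

test_that("the experiment produces a complete factorial of records", {
  withr::with_seed(30, {
    n <- 80
    feats <- list(
      baseline = structure(list(values = matrix(rnorm(n * 2), n, 2),
                                kind = "baseline"), class = "feature_matrix"),
      `2d` = structure(list(values = matrix(rnorm(n * 4), n, 4),
                            kind = "2d"), class = "feature_matrix"))
    labs <- cbind(a = rep(c(TRUE, FALSE), n / 2),
                  b = sample(c(TRUE, FALSE), n, replace = TRUE))
  })
  res <- run_experiment(feats, labs, n_outer = 3, seed = 5)
  expect_equal(nrow(res), 2 * 2 * 3)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  expect_true(all(is.na(res$auroc) | (res$auroc >= 0 & res$auroc <= 1)))
  expect_equal(nrow(unique(res[, c("representation", "network", "repeat_index")])),
               nrow(res))
  ## bit-identical reproduction under the same master seed
  res2 <- run_experiment(feats, labs, n_outer = 3, seed = 5)
  expect_identical(res, res2)
})
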