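## R interface to the compiled boosting machine, plus the balanced
## resampling and nested cross-validation scaffolding used to benchmark
## lesion representations.

#' Hyperparameter grid for the boosting machine
#'
#' The factorial grid searched by the inner cross-validation: loss
#' (binomial deviance vs exponential), number of boosting stages, and
#' maximal tree depth.
#'
#' @param losses character subset of `c("deviance", "exponential")`.
#' @param n_estimators integer stage counts.
#' @param max_depths integer tree depths.
#' @param inner_folds stratified inner CV folds.
#' @return an object of class `gbm_grid`.
#' @export
gbm_grid <- function(losses = c("deviance", "exponential"),
                     n_estimators = c(100, 300, 500),
                     max_depths = c(1, 2, 3),
                     inner_folds = 5) {
  stopifnot(length(losses) >= 1, length(n_estimators) >= 1,
            length(max_depths) >= 1, inner_folds >= 2)
  structure(list(losses = losses,
                 n_estimators = sort(as.integer(n_estimators)),
                 max_depths = sort(as.integer(max_depths)),
                 inner_folds = as.integer(inner_folds)),
            class = "gbm_grid")
}

#' Fit a gradient boosting machine
#'
#' @param X numeric feature matrix (n x p).
#' @param y 0/1 (or logical) outcome vector.
#' @param loss `"deviance"` or `"exponential"`.
#' @param n_estimators boosting stages.
#' @param max_depth maximal tree depth.
#' @param learning_rate shrinkage (default 0.1).
#' @return an object of class `gbm_model`.
#' @export
gbm_fit <- function(X, y, loss = "deviance", n_estimators = 100,
                    max_depth = 3, learning_rate = 0.1) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("y must contain both classes")
  fit <- cpp_gbm_train(X, y, loss, as.integer(n_estimators),
                       as.integer(max_depth), learning_rate,
                       matrix(0, 0, ncol(X)), integer(0), TRUE)
  structure(list(trees = fit$trees, f0 = fit$f0, loss = loss,
                 n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, p = ncol(X)),
            class = "gbm_model")
}

#' Predict from a gbm_model
#' @param object a `gbm_model`.
#' @param newdata numeric matrix with the training columns.
#' @param type `"margin"` (additive score), `"prob"` (deviance only:
#'   sigmoid of the margin), or `"class"` (margin > 0).
#' @param ... unused.
#' @return numeric (or integer for `"class"`) vector.
#' @export
predict.gbm_model <- function(object, newdata, type = c("margin", "prob", "class"),
                              ...) {
  type <- match.arg(type)
  m <- cpp_gbm_predict(object$trees, object$f0, as.matrix(newdata),
                       object$n_estimators)
  switch(type,
         margin = m,
         prob = 1 / (1 + exp(-m)),
         class = as.integer(m > 0))
}

#' Balanced class-equalising draw
#'
#' Draws `min(#affected, #unaffected)` subjects from each class without
#' replacement and returns the shuffled indices, so chance accuracy on the
#' draw is exactly 50%.
#'
#' @param y logical/0-1 labels.
#' @param seed integer RNG seed.
#' @return integer indices into `y`.
#' @export
balanced_indices <- function(y, seed) {
  y <- as.logical(y)
  pos <- which(y); neg <- which(!y)
  if (length(pos) == 0 || length(neg) == 0) stop("degenerate network label")
  m <- min(length(pos), length(neg))
  with_seed(seed, {
    idx <- c(sample_vec(pos, m), sample_vec(neg, m))
    sample_vec(idx, length(idx))
  })
}

## Stratified k-fold assignment: within each class, shuffle then deal
## round-robin. Returns integer fold per observation.
stratified_folds <- function(y, k, seed) {
  y <- as.logical(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      ids <- which(y == cls)
      ids <- sample_vec(ids, length(ids))
      folds[ids] <- rep_len(seq_len(k), length(ids))
    }
  })
  folds
}

#' Nested-CV hyperparameter selection and refit
#'
#' Evaluates every point of the factorial grid by stratified inner
#' cross-validated mean accuracy and refits the best configuration on all
#' of `(X, y)`. The three stage counts are harvested from a single fit per
#' (loss, depth, fold) via intermediate-stage predictions, so the full
#' grid costs `losses x depths x folds` fits. Ties go to the first point
#' in (loss, n_estimators, depth) order.
#'
#' @param X numeric feature matrix.
#' @param y 0/1 or logical labels, both classes present.
#' @param grid a `gbm_grid`.
#' @param seed RNG seed for the inner fold assignment.
#' @param learning_rate shrinkage (default 0.1).
#' @return list with `model` (refit `gbm_model`), `chosen` (data.frame
#'   row: loss, n_estimators, max_depth, inner_accuracy), and
#'   `grid_accuracy` (full grid with inner CV accuracies).
#' @export
fit_gbm_nested <- function(X, y, grid = gbm_grid(), seed = 1,
                           learning_rate = 0.1) {
  X <- as.matrix(X); y <- as.numeric(as.logical(y))
  if (length(unique(y)) < 2) stop("y must contain both classes")
  k <- grid$inner_folds
  if (length(y) < 2 * k) stop("too few observations for inner CV")
  folds <- stratified_folds(y, k, seed)
  n_est <- grid$n_estimators
  max_rounds <- max(n_est)
  ## accuracy accumulator: loss x depth x n_est
  acc <- array(0, c(length(grid$losses), length(grid$max_depths), length(n_est)))
  cnt <- array(0, dim(acc))
  for (fold in seq_len(k)) {
    tr <- folds != fold; te <- !tr
    if (!any(te) || length(unique(y[tr])) < 2) next
    for (li in seq_along(grid$losses)) {
      for (di in seq_along(grid$max_depths)) {
        fit <- cpp_gbm_train(X[tr, , drop = FALSE], y[tr], grid$losses[li],
                             max_rounds, grid$max_depths[di], learning_rate,
                             X[te, , drop = FALSE], as.integer(n_est), FALSE)
        for (ei in seq_along(n_est)) {
          pred <- fit$val_margins[, ei] > 0
          acc[li, di, ei] <- acc[li, di, ei] + mean(pred == (y[te] == 1))
          cnt[li, di, ei] <- cnt[li, di, ei] + 1
        }
      }
    }
  }
  acc <- acc / pmax(cnt, 1)
  ## enumerate in (loss, n_estimators, depth) order; first max wins
  rows <- expand.grid(max_depth = grid$max_depths, n_estimators = n_est,
                      loss = grid$losses, stringsAsFactors = FALSE)
  rows <- rows[, c("loss", "n_estimators", "depth" = "max_depth")]
  names(rows) <- c("loss", "n_estimators", "max_depth")
  rows$inner_accuracy <- mapply(function(l, e, d) {
    acc[match(l, grid$losses), match(d, grid$max_depths), match(e, n_est)]
  }, rows$loss, rows$n_estimators, rows$max_depth)
  best <- which.max(rows$inner_accuracy)
  chosen <- rows[best, ]
  model <- gbm_fit(X, y, loss = chosen$loss,
                   n_estimators = chosen$n_estimators,
                   max_depth = chosen$max_depth,
                   learning_rate = learning_rate)
  list(model = model, chosen = chosen, grid_accuracy = rows)
}

#' Accuracy and AUROC of a fitted model on a test set
#'
#' Accuracy is the fraction of correct sign predictions (equal to balanced
#' accuracy under balanced sampling); AUROC is the rank statistic with tie
#' correction (0.5 for constant scores). With a single-class test set the
#' AUROC is undefined and returned as `NA`.
#'
#' @param model a `gbm_model`.
#' @param X_test,y_test nonempty test set.
#' @return list with `accuracy` and `auroc`.
#' @export
score_model <- function(model, X_test, y_test) {
  y <- as.logical(y_test)
  stopifnot(length(y) > 0)
  m <- predict(model, X_test, type = "margin")
  accuracy <- mean((m > 0) == y)
  auroc <- if (length(unique(y)) < 2) NA_real_ else rank_auroc(m, y)
  list(accuracy = accuracy, auroc = auroc)
}

## Mann-Whitney AUROC with midrank tie correction.
rank_auroc <- function(scores, y) {
  r <- rank(scores)           # midranks
  n1 <- sum(y); n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
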