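## The representation benchmark: for every sub-network deficit and every
## lesion representation, repeated balanced resampling with a stratified
## 80/20 train/test split, nested-CV boosting on the train side, accuracy
## and AUROC on the held-out side. One record per (representation, network,
## repeat) gives the complete factorial design the ANOVA needs.

#' Run the representation-benchmark experiment
#'
#' Per sub-network and repeat: one balanced draw (shared across
#' representations, so kinds are compared on identical subjects), a
#' stratified 80/20 split, [fit_gbm_nested()] on the train side per
#' representation, [score_model()] on the test side.
#'
#' @param features named list of `feature_matrix` objects (names are the
#'   representation kinds), e.g. from [build_features()].
#' @param deficits a `deficit_table` (or logical n x networks matrix).
#' @param n_outer number of balanced resampling repeats (default 10).
#' @param seed master seed; every draw, split and inner fold assignment is
#'   derived from it.
#' @param grid a `gbm_grid`.
#' @param train_frac train share of each balanced draw (default 0.8).
#' @param permute_labels if TRUE, deficit labels are permuted (seeded)
#'   before each repeat's draw: the no-signal null used for chance
#'   calibration.
#' @return an object of class `experiment_result`: data.frame with columns
#'   representation, network, repeat_index, accuracy, auroc, loss,
#'   n_estimators, max_depth, n_train, n_test, seed.
#' @export
run_experiment <- function(features, deficits, n_outer = 10, seed = 1,
                           grid = gbm_grid(), train_frac = 0.8,
                           permute_labels = FALSE) {
  vals <- if (inherits(deficits, "deficit_table")) deficits$values else deficits
  stopifnot(is.matrix(vals))
  kinds <- names(features)
  stopifnot(!is.null(kinds), all(nzchar(kinds)))
  n <- nrow(vals)
  for (f in features) stopifnot(nrow(f$values) == n)
  nets <- colnames(vals)
  if (is.null(nets)) nets <- as.character(seq_len(ncol(vals)))
  out <- list()
  for (j in seq_len(ncol(vals))) {
    y_full <- vals[, j]
    if (length(unique(y_full)) < 2) stop("degenerate network label: ", nets[j])
    for (rep_i in seq_len(n_outer)) {
      rep_seed <- derive_seed(seed, j * 1000 + rep_i)
      y_use <- y_full
      if (permute_labels) {
        y_use <- with_seed(derive_seed(rep_seed, 7), sample_vec(y_full, n))
      }
      idx <- balanced_indices(y_use, rep_seed)
      y_bal <- y_use[idx]
      split <- with_seed(derive_seed(rep_seed, 8), {
        tr <- logical(length(idx))
        for (cls in c(TRUE, FALSE)) {
          ids <- which(y_bal == cls)
          ntr <- round(train_frac * length(ids))
          tr[sample_vec(ids, ntr)] <- TRUE
        }
        tr
      })
      for (kind in kinds) {
        Xk <- features[[kind]]$values[idx, , drop = FALSE]
        fit <- fit_gbm_nested(Xk[split, , drop = FALSE], y_bal[split],
                              grid = grid, seed = derive_seed(rep_seed, 9))
        sc <- score_model(fit$model, Xk[!split, , drop = FALSE], y_bal[!split])
        out[[length(out) + 1]] <- data.frame(
          representation = kind, network = nets[j], repeat_index = rep_i,
          accuracy = sc$accuracy, auroc = sc$auroc,
          loss = fit$chosen$loss, n_estimators = fit$chosen$n_estimators,
          max_depth = fit$chosen$max_depth,
          n_train = sum(split), n_test = sum(!split),
          seed = rep_seed, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("experiment_result", "data.frame")
  res
}

#' Assemble the four default representations' features
#'
#' Convenience wrapper building the named feature list
#' [run_experiment()] expects.
#'
#' @param cohort a `lesion_cohort`.
#' @param cluster_model a `cluster_model`.
#' @param embedding an `embedding_2d` (filtered coordinates).
#' @param nmf_model an `nmf_model`.
#' @param kinds representation kinds to include.
#' @return named list of `feature_matrix`.
#' @export
representation_features <- function(cohort, cluster_model, embedding, nmf_model,
                                    kinds = c("baseline", "categorial", "2d", "50d")) {
  stats::setNames(lapply(kinds, function(k) {
    build_features(cohort, k, cluster_model = cluster_model,
                   embedding = embedding, nmf_model = nmf_model)
  }), kinds)
}
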