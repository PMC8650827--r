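## The four lesion representations benchmarked as predictors:
##   baseline    age + lesion volume                        (p = 2)
##   categorial  age + volume + one-hot final cluster       (p = 2 + n_final)
##   2d          age + volume + embedding coordinates       (p = 4)
##   50d         the NMF scores alone                       (p = k)

#' Build a feature matrix for one representation
#'
#' @param cohort a `lesion_cohort`.
#' @param kind one of `"baseline"`, `"categorial"`, `"2d"`, `"50d"`.
#' @param cluster_model `cluster_model` (required for `"categorial"`).
#' @param embedding `embedding_2d` or n x 2 coords (required for `"2d"`).
#' @param nmf_model `nmf_model` (required for `"50d"`).
#' @return an object of class `feature_matrix`: list with `values`,
#'   `kind`, `column_names`.
#' @export
build_features <- function(cohort, kind = c("baseline", "categorial", "2d", "50d"),
                           cluster_model = NULL, embedding = NULL,
                           nmf_model = NULL) {
  kind <- match.arg(kind)
  masks <- if (inherits(cohort, "lesion_cohort")) cohort$masks else cohort
  age <- vapply(masks, `[[`, numeric(1), "age")
  vol <- vapply(masks, lesion_volume, numeric(1))
  values <- switch(kind,
    baseline = {
      cbind(age = age, volume_mm3 = vol)
    },
    categorial = {
      if (is.null(cluster_model)) stop("categorial features need a cluster_model")
      lab <- cluster_model$labels
      stopifnot(length(lab) == length(masks))
      onehot <- vapply(seq_len(cluster_model$n_final),
                       function(cl) as.numeric(lab == cl),
                       numeric(length(lab)))
      colnames(onehot) <- paste0("cluster_", seq_len(cluster_model$n_final))
      cbind(age = age, volume_mm3 = vol, onehot)
    },
    "2d" = {
      if (is.null(embedding)) stop("2d features need an embedding")
      co <- if (inherits(embedding, "embedding_2d")) embedding$coords else embedding
      stopifnot(nrow(co) == length(masks))
      cbind(age = age, volume_mm3 = vol, x = co[, 1], y = co[, 2])
    },
    "50d" = {
      if (is.null(nmf_model)) stop("50d features need an nmf_model")
      sc <- nmf_model$scores
      stopifnot(nrow(sc) == length(masks))
      colnames(sc) <- paste0("nmf_", seq_len(ncol(sc)))
      sc
    })
  structure(list(values = values, kind = kind,
                 column_names = colnames(values)),
            class = "feature_matrix")
}
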