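## Categorial representation: Ward clustering of the 2-D embedding,
## archetype centroid images, amalgamation of redundant clusters, and
## assignment of new lesions to their closest archetype.

#' Ward clustering of embedding coordinates
#'
#' Agglomerative clustering with Ward's minimum-variance linkage on
#' Euclidean distances (`stats::hclust(method = "ward.D2")`), cut at
#' `n_clusters`.
#'
#' @param coords n x 2 matrix or `embedding_2d`.
#' @param n_clusters number of clusters in `[1, n]`.
#' @return integer cluster labels (1..n_clusters).
#' @export
ward_cluster <- function(coords, n_clusters) {
  if (inherits(coords, "embedding_2d")) coords <- coords$coords
  n <- nrow(coords)
  if (n_clusters < 1 || n_clusters > n) stop("n_clusters out of range [1, n]")
  if (n_clusters == n) return(seq_len(n))
  hc <- hclust(dist(coords), method = "ward.D2")
  as.integer(cutree(hc, k = n_clusters))
}

#' Archetype centroid images of lesion clusters
#'
#' Per cluster, the voxel-wise mean of the members' collapsed, unsmoothed
#' binary masks: an occupancy-fraction image in \[0, 1\].
#'
#' @param cohort a `lesion_cohort` (or list of `lesion_mask`).
#' @param labels integer cluster label per subject.
#' @return list of `archetype_image` objects (fields `grid`, `cluster_id`,
#'   `member_count`), ordered by cluster id.
#' @export
compute_centroids <- function(cohort, labels) {
  masks <- if (inherits(cohort, "lesion_cohort")) cohort$masks else cohort
  stopifnot(length(masks) == length(labels))
  ids <- sort(unique(labels))
  gs <- masks[[1]]$grid_shape
  lapply(ids, function(cl) {
    members <- which(labels == cl)
    if (length(members) == 0) stop("empty cluster ", cl)
    acc <- array(0, gs)
    for (s in members) {
      m <- collapse_hemisphere(masks[[s]])
      acc[m$voxels] <- acc[m$voxels] + 1
    }
    structure(list(grid = acc / length(members), cluster_id = cl,
                   member_count = length(members)),
              class = "archetype_image")
  })
}

## Dice between two centroids binarised at 0.5.
centroid_dice <- function(a, b) {
  dice_similarity(a$grid >= 0.5, b$grid >= 0.5)
}

#' Amalgamate clusters into the final categorial model
#'
#' Replaces the original expert pruning step with either (a) an explicit
#' `merge_map` from initial to final cluster ids (faithful mode), or (b)
#' automated greedy merging of the pair of clusters with highest centroid
#' Dice overlap (centroids binarised at 0.5), until the overlap falls below
#' `dice_threshold` and/or the cluster count reaches `target_n`.
#'
#' @param labels integer initial cluster labels per subject.
#' @param centroids list of `archetype_image` from [compute_centroids()].
#' @param merge_map optional integer vector (or named vector) mapping each
#'   initial cluster id to a final group; must cover every initial id.
#' @param dice_threshold optional Dice floor in (0, 1\] for greedy merging.
#' @param target_n optional final cluster count for greedy merging.
#' @return an object of class `cluster_model`: list with `labels` (final,
#'   renumbered 1..n_final), `n_initial`, `n_final`, `merge_map`,
#'   `centroids` (member-count weighted means of merged centroids),
#'   `linkage_record` (merge history).
#' @export
amalgamate <- function(labels, centroids, merge_map = NULL,
                       dice_threshold = NULL, target_n = NULL) {
  init_ids <- vapply(centroids, `[[`, numeric(1), "cluster_id")
  stopifnot(all(labels %in% init_ids))
  n_initial <- length(init_ids)
  record <- list()
  if (!is.null(merge_map)) {
    if (is.null(names(merge_map))) {
      if (length(merge_map) != n_initial) {
        stop("merge_map must give a final group for every initial cluster")
      }
      names(merge_map) <- init_ids
    }
    if (!all(as.character(init_ids) %in% names(merge_map))) {
      stop("merge_map must cover every initial cluster id")
    }
    group <- merge_map[as.character(init_ids)]
  } else {
    if (is.null(dice_threshold) && is.null(target_n)) {
      stop("supply merge_map, dice_threshold, or target_n")
    }
    if (!is.null(dice_threshold) &&
        (dice_threshold <= 0 || dice_threshold > 1)) {
      stop("dice_threshold must be in (0, 1]")
    }
    group <- stats::setNames(init_ids, init_ids)
    cents <- centroids
    alive <- rep(TRUE, n_initial)
    repeat {
      n_cur <- sum(alive)
      if (!is.null(target_n) && n_cur <= target_n) break
      if (n_cur <= 1) break
      ia <- which(alive)
      best <- c(NA, NA); best_d <- -1
      for (a in seq_along(ia)) {
        for (b in seq_len(a - 1)) {
          d <- centroid_dice(cents[[ia[a]]], cents[[ia[b]]])
          if (d > best_d) { best_d <- d; best <- c(ia[b], ia[a]) }
        }
      }
      if (is.null(target_n) && best_d < dice_threshold) break
      keep <- best[1]; drop <- best[2]
      wk <- cents[[keep]]$member_count; wd <- cents[[drop]]$member_count
      cents[[keep]]$grid <- (wk * cents[[keep]]$grid + wd * cents[[drop]]$grid) / (wk + wd)
      cents[[keep]]$member_count <- wk + wd
      alive[drop] <- FALSE
      group[group == init_ids[drop]] <- init_ids[keep]
      record[[length(record) + 1]] <- list(kept = init_ids[keep],
                                           merged = init_ids[drop],
                                           dice = best_d)
    }
  }
  ## renumber final groups 1..n_final in ascending order of group id
  finals <- sort(unique(as.integer(group)))
  remap <- stats::setNames(seq_along(finals), finals)
  final_map <- stats::setNames(as.integer(remap[as.character(group)]),
                               init_ids)
  new_labels <- final_map[as.character(labels)]
  ## recompute final centroids as weighted means of initial ones
  out_cents <- lapply(seq_along(finals), function(g) {
    members <- which(final_map == g)
    w <- vapply(centroids[members], `[[`, numeric(1), "member_count")
    acc <- Reduce(`+`, lapply(seq_along(members), function(m) {
      w[m] * centroids[[members[m]]]$grid
    }))
    structure(list(grid = acc / sum(w), cluster_id = g,
                   member_count = as.integer(sum(w))),
              class = "archetype_image")
  })
  structure(list(labels = as.integer(unname(new_labels)),
                 n_initial = as.integer(n_initial),
                 n_final = length(finals),
                 merge_map = final_map,
                 centroids = out_cents,
                 linkage_record = record),
            class = "cluster_model")
}

#' Assign a lesion to its closest archetype
#'
#' The lesion is collapsed onto the canonical hemisphere and compared with
#' every archetype centroid binarised at 0.5 by the Dice coefficient
#' `2|A∩B| / (|A|+|B|)`; the highest-similarity archetype wins, ties going
#' to the lowest cluster id. A centroid that binarises to the empty set
#' scores 0.
#'
#' @param mask a nonempty `lesion_mask` on the model's grid.
#' @param cluster_model a `cluster_model`.
#' @return list with `cluster_id` and `similarity` (named numeric vector
#'   over clusters).
#' @export
assign_lesion <- function(mask, cluster_model) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(cluster_model, "cluster_model"))
  if (length(mask$voxels) == 0) stop("empty lesion")
  m <- collapse_hemisphere(mask)
  sims <- vapply(cluster_model$centroids, function(ct) {
    bin <- which(ct$grid >= 0.5)
    if (length(bin) == 0) return(0)
    dice_similarity(m$voxels, bin)
  }, numeric(1))
  ids <- vapply(cluster_model$centroids, `[[`, numeric(1), "cluster_id")
  names(sims) <- ids
  list(cluster_id = as.integer(ids[which.max(sims)]), similarity = sims)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: %d initial -> %d final clusters, %d subjects\n",
              x$n_initial, x$n_final, length(x$labels)))
  invisible(x)
}
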