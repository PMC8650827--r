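## Synthetic stroke cohort generator. Each subject's lesion is a jittered,
## noised copy of one vascular territory, optionally mirrored to the right
## hemisphere, with an age drawn from a truncated normal matched to a
## typical acute ischaemic stroke admission cohort.

#' Specification of a synthetic lesion cohort
#'
#' Bundles every knob of the simulator. Defaults describe the study
#' conditions used throughout: a desk-scale 48x56x48 grid at 4 mm spacing,
#' a depth-3 territory tree sampled at the leaves, mild boundary noise and
#' volume jitter (well inside the regime where territories remain
#' identifiable), symmetric lateralisation, and ages ~ Normal(63.89, 15.91)
#' truncated to \[18, 97\] years.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param grid_shape integer length-3 voxel dimensions.
#' @param voxel_size_mm isotropic spacing in mm.
#' @param tree_depth levels of the vascular tree.
#' @param node_weights probability over tree depths `0:tree_depth` from
#'   which the occluded node's depth is drawn; default puts all mass on the
#'   leaves (purely distal occlusions), giving `2^tree_depth` recoverable
#'   archetypes.
#' @param noise_rate fraction of lesion voxels toggled within a 1-voxel rim
#'   of the lesion boundary.
#' @param volume_jitter relative half-width of the uniform lesion-volume
#'   multiplier (lesion grown/shrunk morphologically to the target volume).
#' @param age_mean,age_sd,age_bounds truncated-normal age model (years).
#' @param right_hemisphere_prob probability a lesion is mirrored to the
#'   right hemisphere.
#' @param seed master RNG seed for the cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 400, grid_shape = c(48, 56, 48),
                        voxel_size_mm = 4, tree_depth = 3,
                        node_weights = NULL, noise_rate = 0.03,
                        volume_jitter = 0.15, age_mean = 63.89,
                        age_sd = 15.91, age_bounds = c(18, 97),
                        right_hemisphere_prob = 0.5, seed = 1) {
  if (is.null(node_weights)) node_weights <- c(rep(0, tree_depth), 1)
  stopifnot(n_subjects >= 1, length(node_weights) == tree_depth + 1,
            all(node_weights >= 0), sum(node_weights) > 0,
            noise_rate >= 0, noise_rate <= 1,
            volume_jitter >= 0, volume_jitter < 1,
            right_hemisphere_prob >= 0, right_hemisphere_prob <= 1,
            length(age_bounds) == 2, age_bounds[1] <= age_bounds[2])
  structure(list(n_subjects = as.integer(n_subjects),
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, tree_depth = as.integer(tree_depth),
                 node_weights = node_weights / sum(node_weights),
                 noise_rate = noise_rate, volume_jitter = volume_jitter,
                 age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
                 right_hemisphere_prob = right_hemisphere_prob,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Construct a lesion mask object
#'
#' @param voxels sorted linear voxel indices of the lesion.
#' @param grid_shape integer length-3 voxel dimensions.
#' @param voxel_size_mm isotropic spacing in mm.
#' @param subject_id identifier.
#' @param age years.
#' @param planted_node simulator ground-truth node id (NA for real data).
#' @return an object of class `lesion_mask`.
#' @export
lesion_mask <- function(voxels, grid_shape, voxel_size_mm,
                        subject_id = NA_character_, age = NA_real_,
                        planted_node = NA_integer_) {
  structure(list(voxels = as.integer(sort(voxels)),
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 subject_id = subject_id, age = age,
                 planted_node = planted_node),
            class = "lesion_mask")
}

#' Dense binary volume of a lesion mask
#' @param mask a `lesion_mask`.
#' @return logical 3-D array.
#' @export
as_volume <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  indices_to_volume(mask$voxels, mask$grid_shape)
}

## Grow or shrink a voxel set morphologically (6-neighbourhood layers) to a
## target voxel count, completing the last partial layer at random.
resize_to_volume <- function(vox, target, grid_shape, within) {
  target <- max(1L, as.integer(target))
  if (length(vox) == target) return(vox)
  if (length(vox) > target) {
    while (length(vox) > target) {
      inner <- erode_indices(vox, grid_shape)
      layer <- setdiff(vox, inner)
      drop_n <- length(vox) - target
      if (length(layer) == 0 || length(layer) <= drop_n && length(inner) == 0) {
        ## cannot erode further; drop random voxels
        return(sort(sample_vec(vox, target)))
      }
      if (length(layer) <= drop_n) {
        vox <- inner
      } else {
        vox <- sort(c(inner, sample_vec(layer, length(layer) - drop_n)))
      }
    }
  } else {
    while (length(vox) < target) {
      grown <- dilate_indices(vox, grid_shape, within = within)
      layer <- setdiff(grown, vox)
      add_n <- target - length(vox)
      if (length(layer) == 0) break   # mask saturated
      if (length(layer) <= add_n) {
        vox <- grown
      } else {
        vox <- sort(c(vox, sample_vec(layer, add_n)))
      }
    }
  }
  vox
}

#' Sample one synthetic lesion from a vascular tree
#'
#' Draws an occluded node (depth from `spec$node_weights`, node uniform at
#' that depth), perturbs its territory's volume by the jitter multiplier,
#' toggles `noise_rate` of its voxels within a 1-voxel rim of the boundary,
#' and mirrors the result to the right hemisphere with probability
#' `right_hemisphere_prob`. Consumes the current RNG state; seed outside
#' (e.g. via [generate_cohort()]) for reproducibility.
#'
#' @param tree a `vascular_tree`.
#' @param spec a `cohort_spec` with matching `grid_shape`.
#' @param subject_id identifier stored in the mask.
#' @param max_retry resample attempts should a perturbation empty the lesion.
#' @return a `lesion_mask` with `planted_node` set to the chosen node id.
#' @export
sample_lesion <- function(tree, spec, subject_id = NA_character_, max_retry = 5) {
  stopifnot(inherits(tree, "vascular_tree"), inherits(spec, "cohort_spec"),
            identical(tree$grid_shape, spec$grid_shape))
  brain <- make_brain_mask(spec$grid_shape)
  for (attempt in seq_len(max_retry)) {
    d <- sample.int(spec$tree_depth + 1, 1, prob = spec$node_weights) - 1L
    ids <- tree_nodes_at_depth(tree, d)
    node <- ids[sample.int(length(ids), 1)]
    terr <- tree$nodes[[node]]$voxels
    vox <- terr
    if (spec$volume_jitter > 0) {
      f <- runif(1, 1 - spec$volume_jitter, 1 + spec$volume_jitter)
      vox <- resize_to_volume(vox, round(f * length(terr)), spec$grid_shape, brain)
    }
    if (spec$noise_rate > 0 && length(vox) > 0) {
      rim <- setdiff(dilate_indices(vox, spec$grid_shape, within = brain),
                     erode_indices(vox, spec$grid_shape))
      n_tog <- min(length(rim), round(spec$noise_rate * length(vox)))
      if (n_tog > 0) {
        tog <- sample_vec(rim, n_tog)
        vox <- sort(c(setdiff(vox, tog), setdiff(tog, vox)))
      }
    }
    if (length(vox) == 0) next
    if (runif(1) < spec$right_hemisphere_prob) {
      vox <- sort(mirror_indices(vox, spec$grid_shape))
    }
    ## sample age here so the per-subject RNG stream is self-contained
    age <- repeat_age(spec)
    return(lesion_mask(vox, spec$grid_shape, spec$voxel_size_mm,
                       subject_id = subject_id, age = age,
                       planted_node = node))
  }
  stop("sample_lesion: lesion empty after ", max_retry, " perturbation attempts")
}

## Rejection-sampled truncated normal age (exact truncation).
repeat_age <- function(spec) {
  repeat {
    a <- rnorm(1, spec$age_mean, spec$age_sd)
    if (a >= spec$age_bounds[1] && a <= spec$age_bounds[2]) return(a)
  }
}

#' Generate a full synthetic cohort
#'
#' Builds the vascular tree (seeded from `spec$seed`) and draws
#' `spec$n_subjects` lesions with ages. Purely deterministic in `spec`.
#'
#' @param spec a `cohort_spec`.
#' @param tree optional pre-built `vascular_tree`; by default one is built
#'   from the spec (seed `derive_seed(spec$seed, 1)`).
#' @return an object of class `lesion_cohort`: list with `masks` (list of
#'   `lesion_mask`), `manifest` (data.frame subject_id, age, planted_node),
#'   `grid_shape`, `voxel_size_mm`, `tree`, `spec`.
#' @export
generate_cohort <- function(spec, tree = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(tree)) {
    tree <- build_vascular_tree(spec$grid_shape, spec$voxel_size_mm,
                                spec$tree_depth, seed = derive_seed(spec$seed, 1))
  }
  masks <- with_seed(derive_seed(spec$seed, 2), {
    lapply(seq_len(spec$n_subjects), function(i) {
      sample_lesion(tree, spec, subject_id = sprintf("sub-%04d", i))
    })
  })
  manifest <- data.frame(
    subject_id = vapply(masks, `[[`, character(1), "subject_id"),
    age = vapply(masks, `[[`, numeric(1), "age"),
    planted_node = vapply(masks, `[[`, integer(1), "planted_node"),
    stringsAsFactors = FALSE)
  structure(list(masks = masks, manifest = manifest,
                 grid_shape = spec$grid_shape,
                 voxel_size_mm = spec$voxel_size_mm,
                 tree = tree, spec = spec),
            class = "lesion_cohort")
}

#' Planted ground-truth labels of a synthetic cohort
#' @param cohort a `lesion_cohort`.
#' @return integer vector of planted node ids, one per subject.
#' @export
planted_labels <- function(cohort) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  cohort$manifest$planted_node
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat(sprintf("lesion_cohort: %d subjects, grid %s @ %g mm, ages %.1f-%.1f (mean %.1f)\n",
              nrow(x$manifest), paste(x$grid_shape, collapse = "x"),
              x$voxel_size_mm, min(x$manifest$age), max(x$manifest$age),
              mean(x$manifest$age)))
  invisible(x)
}
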