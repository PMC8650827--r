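## Hierarchical vascular-territory model used by the lesion simulator.
##
## Real ischaemic lesions are shaped by the branching topology of the
## arterial tree: a proximal occlusion devastates a whole territory, a
## distal one a nested sub-territory. The simulator encodes that structure
## as a binary tree of territories obtained by recursive bisection of one
## hemisphere, so that territories at each level exactly partition the
## hemisphere and nest across levels.

#' Build a synthetic vascular territory tree
#'
#' Recursively bisects the left-hemisphere brain mask along alternating
#' axes, with seeded jitter of the cut plane, into `2^depth` leaf
#' territories. Node `i`'s children are nodes `2i` and `2i+1` (heap
#' indexing, root = 1); a node's territory is the exact union of its
#' children's, and territories at any depth partition the hemisphere.
#'
#' @param grid_shape integer length-3 voxel dimensions.
#' @param voxel_size_mm isotropic voxel spacing in mm.
#' @param depth number of bisection levels (>= 1); leaves sit at this depth.
#' @param seed integer RNG seed; the tree is a pure function of
#'   `(grid_shape, depth, seed)`.
#' @param jitter half-width of the uniform jitter on the cut fraction
#'   (default 0.15, i.e. cuts between the 35% and 65% quantiles).
#' @return an object of class `vascular_tree`: list with `nodes` (list of
#'   `node_id`, `parent_id`, `depth`, `voxels` linear indices), `depth`,
#'   `grid_shape`, `voxel_size_mm`, `seed`.
#' @export
build_vascular_tree <- function(grid_shape, voxel_size_mm = 4, depth = 3,
                                seed = 1, jitter = 0.15) {
  stopifnot(depth >= 1, length(grid_shape) == 3)
  grid_shape <- as.integer(grid_shape)
  hemi <- make_hemisphere_mask(grid_shape)
  root <- which(hemi)
  min_leaf <- 8L
  nodes <- vector("list", 2^(depth + 1) - 1)
  nodes[[1]] <- list(node_id = 1L, parent_id = NA_integer_, depth = 0L,
                     voxels = root)
  with_seed(seed, {
    for (node in seq_len(2^depth - 1)) {
      d <- floor(log2(node))
      vox <- nodes[[node]]$voxels
      need <- min_leaf * 2^(depth - d - 1)   # each child must feed its leaves
      if (length(vox) < 2 * need) {
        stop(sprintf("grid too small to split node %d at depth %d (%d voxels, need %d)",
                     node, d, length(vox), 2 * need))
      }
      axis <- d %% 3 + 1
      coord <- index_to_ijk(vox, grid_shape)[, axis]
      frac <- runif(1, 0.5 - jitter, 0.5 + jitter)
      cut <- as.numeric(quantile(coord, frac, type = 1))
      left <- coord <= cut
      ## keep both children large enough for their subtrees
      ord <- order(coord)
      nl <- sum(left)
      if (nl < need || length(vox) - nl < need) {
        nl <- max(need, min(length(vox) - need, nl))
        left <- seq_along(vox) %in% ord[seq_len(nl)]
      }
      nodes[[2 * node]] <- list(node_id = 2L * node, parent_id = as.integer(node),
                                depth = d + 1L, voxels = sort(vox[left]))
      nodes[[2 * node + 1]] <- list(node_id = 2L * node + 1L, parent_id = as.integer(node),
                                    depth = d + 1L, voxels = sort(vox[!left]))
    }
  })
  structure(list(nodes = nodes, depth = as.integer(depth),
                 grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 seed = as.integer(seed)),
            class = "vascular_tree")
}

#' Node ids at a given depth of a vascular tree
#' @param tree a `vascular_tree`.
#' @param depth tree level (0 = root, `tree$depth` = leaves).
#' @return integer node ids.
#' @export
tree_nodes_at_depth <- function(tree, depth) {
  stopifnot(depth >= 0, depth <= tree$depth)
  as.integer(seq(2^depth, 2^(depth + 1) - 1))
}

#' Leaf territory voxel sets of a vascular tree
#' @param tree a `vascular_tree`.
#' @return named list of linear-index vectors, one per leaf node.
#' @export
tree_leaves <- function(tree) {
  ids <- tree_nodes_at_depth(tree, tree$depth)
  stats::setNames(lapply(ids, function(i) tree$nodes[[i]]$voxels), ids)
}

#' @export
print.vascular_tree <- function(x, ...) {
  cat(sprintf("vascular_tree: depth %d (%d leaves), grid %s, %d hemisphere voxels\n",
              x$depth, 2^x$depth, paste(x$grid_shape, collapse = "x"),
              length(x$nodes[[1]]$voxels)))
  invisible(x)
}
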