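test_that("vascular tree partitions the hemisphere at every level", {
  tree <- build_vascular_tree(small_grid, depth = 3, seed = 7)
  expect_length(tree_leaves(tree), 8)
  root <- tree$nodes[[1]]$voxels
  hemi <- which(make_hemisphere_mask(small_grid))
  expect_identical(root, hemi)
  for (d in 1:3) {
    terr <- lapply(tree_nodes_at_depth(tree, d),
                   function(i) tree$nodes[[i]]$voxels)
    expect_identical(sort(unname(unlist(terr))), root)
    for (a in seq_along(terr)) {
      for (b in seq_len(a - 1)) {
        expect_length(intersect(terr[[a]], terr[[b]]), 0)
      }
    }
  }
  ## every territory nonempty, leaves comfortably above the size floor
  sizes <- vapply(tree_leaves(tree), length, integer(1))
  expect_true(all(sizes >= 8))
})

test_that("tree construction is deterministic and fails on tiny grids", {
  t1 <- build_vascular_tree(small_grid, depth = 3, seed = 42)
  t2 <- build_vascular_tree(small_grid, depth = 3, seed = 42)
  expect_identical(t1$nodes, t2$nodes)
  t3 <- build_vascular_tree(small_grid, depth = 3, seed = 43)
  expect_false(identical(t1$nodes, t3$nodes))
  expect_error(build_vascular_tree(c(6, 6, 6), depth = 5, seed = 1),
               "too small to split node")
})

test_that("degenerate sampling parameters reproduce the chosen territory", {
  tree <- build_vascular_tree(small_grid, depth = 2, seed = 3)
  spec <- small_spec(tree_depth = 2, noise_rate = 0, volume_jitter = 0,
                     right_hemisphere_prob = 0)
  withr::with_seed(1, {
    m <- sample_lesion(tree, spec)
    expect_identical(m$voxels, tree$nodes[[m$planted_node]]$voxels)
  })
  ## forced mirroring preserves voxel count and mirrors the territory
  spec_r <- small_spec(tree_depth = 2, noise_rate = 0, volume_jitter = 0,
                       right_hemisphere_prob = 1)
  withr::with_seed(1, {
    m <- sample_lesion(tree, spec_r)
    terr <- tree$nodes[[m$planted_node]]$voxels
    expect_identical(m$voxels,
                     sort(lesionlatent:::mirror_indices(terr, small_grid)))
    expect_length(m$voxels, length(terr))
  })
})

test_that("proximal occlusions produce strictly larger lesions than distal", {
  tree <- build_vascular_tree(small_grid, depth = 3, seed = 5)
  base <- list(noise_rate = 0, volume_jitter = 0, right_hemisphere_prob = 0,
               tree_depth = 3)
  spec1 <- do.call(small_spec, c(base, list(node_weights = c(0, 1, 0, 0))))
  spec3 <- do.call(small_spec, c(base, list(node_weights = c(0, 0, 0, 1))))
  withr::with_seed(2, {
    v1 <- lesion_volume(sample_lesion(tree, spec1))
    v3 <- lesion_volume(sample_lesion(tree, spec3))
  })
  expect_gt(v1, v3)
})

test_that("noisy jittered lesions remain nearest (max Dice) to their territory", {
  spec <- small_spec(n = 200, seed = 9, noise_rate = 0.05, volume_jitter = 0.2)
  co <- generate_cohort(spec)
  leaves <- tree_leaves(co$tree)
  hit <- vapply(seq_along(co$masks), function(s) {
    m <- collapse_hemisphere(co$masks[[s]])
    d <- vapply(leaves, function(t) dice_similarity(m$voxels, t), numeric(1))
    as.integer(names(leaves))[which.max(d)] == co$manifest$planted_node[s]
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("cohort ages follow the truncated normal and runs are reproducible", {
  spec <- cohort_spec(n_subjects = 1000, grid_shape = small_grid,
                      tree_depth = 1, seed = 31)
  co <- generate_cohort(spec)
  ages <- co$manifest$age
  expect_true(all(ages >= 18 & ages <= 97))
  expect_lt(abs(mean(ages) - 63.89), 2.0)
  co_small1 <- generate_cohort(small_spec(n = 15, seed = 4))
  co_small2 <- generate_cohort(small_spec(n = 15, seed = 4))
  expect_identical(co_small1$manifest, co_small2$manifest)
  expect_identical(lapply(co_small1$masks, `[[`, "voxels"),
                   lapply(co_small2$masks, `[[`, "voxels"))
})

test_that("synthetic parcellations tile the mask and map onto networks", {
  parc <- generate_parcellation(small_grid, n_regions = 100, n_networks = 17,
                                seed = 2)
  mask <- make_hemisphere_mask(small_grid)
  labs <- parc$label_grid[mask]
  expect_setequal(unique(labs), 1:100)
  expect_true(all(parc$label_grid[!mask] == 0))
  expect_setequal(unique(parc$region_to_network), 1:17)
  ## degenerate single region
  p1 <- generate_parcellation(small_grid, n_regions = 1, n_networks = 1,
                              seed = 1)
  expect_true(all(p1$label_grid[mask] == 1))
  expect_error(generate_parcellation(c(4, 4, 4), n_regions = 1e5,
                                     n_networks = 2, seed = 1),
               "exceeds available mask voxels")
  ## determinism
  parc2 <- generate_parcellation(small_grid, n_regions = 100, n_networks = 17,
                                 seed = 2)
  expect_identical(parc$label_grid, parc2$label_grid)
})
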