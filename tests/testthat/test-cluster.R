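test_that("structure-aware filtering respects its contract", {
  withr::with_seed(2, Y <- matrix(rnorm(40), 20, 2))
  expect_identical(saf_filter(Y, mu = 0), Y)
  expect_identical(saf_filter(Y[1, , drop = FALSE], mu = 0.5), Y[1, , drop = FALSE])
  ## two clusters further apart than the neighbourhood radius are filtered
  ## independently: their centroid separation is untouched
  withr::with_seed(3, {
    a <- matrix(rnorm(20, sd = 0.03), 10, 2)
    b <- matrix(rnorm(20, sd = 0.03), 10, 2) + 100
  })
  Yf <- saf_filter(rbind(a, b), mu = 0.2, r = 0.1)
  d0 <- sqrt(sum((colMeans(a) - colMeans(b))^2))
  d1 <- sqrt(sum((colMeans(Yf[1:10, ]) - colMeans(Yf[11:20, ]))^2))
  expect_equal(d1, d0, tolerance = 1e-9)
  ## and the filtering contracts each cluster around its centre
  expect_lt(mean(sqrt(rowSums(sweep(Yf[1:10, ], 2, colMeans(Yf[1:10, ]))^2))),
            mean(sqrt(rowSums(sweep(a, 2, colMeans(a))^2))))
})

test_that("Ward clustering matches the hand-worked four-point example", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  lab <- ward_cluster(pts, 2)
  expect_equal(lab[1], lab[2])
  expect_equal(lab[3], lab[4])
  expect_false(lab[1] == lab[3])
  expect_identical(ward_cluster(pts, 4), 1:4)
  expect_identical(ward_cluster(pts, 1), rep(1L, 4))
  expect_error(ward_cluster(pts, 0), "out of range")
  expect_error(ward_cluster(pts, 5), "out of range")
})

test_that("centroids are occupancy fractions of member masks", {
  m1 <- mask_from_ijk(c(2, 2, 2, 3, 2, 2))          # voxels A, B
  m2 <- mask_from_ijk(c(2, 2, 2, 4, 2, 2))          # voxels A, C
  cents <- compute_centroids(list(m1, m1), c(1, 1))
  expect_equal(cents[[1]]$grid[m1$voxels], c(1, 1))
  expect_equal(sum(cents[[1]]$grid), 2)
  cents2 <- compute_centroids(list(m1, m2), c(1, 1))
  vals <- cents2[[1]]$grid[cents2[[1]]$grid > 0]
  expect_setequal(unique(vals), c(1, 0.5))
  expect_equal(cents2[[1]]$member_count, 2)
})

test_that("amalgamation merges by map or by centroid Dice", {
  co <- small_cohort(n = 24, seed = 8)
  labels <- rep(1:6, length.out = 24)
  cents <- compute_centroids(co, labels)
  ## explicit map: 6 -> 3 groups
  cm <- amalgamate(labels, cents, merge_map = c(1, 1, 2, 2, 3, 3))
  expect_equal(cm$n_initial, 6L)
  expect_equal(cm$n_final, 3L)
  expect_true(all(cm$labels %in% 1:3))
  expect_length(cm$centroids, 3)
  ## merged centroid is the member-count weighted mean
  w <- vapply(cents[1:2], `[[`, numeric(1), "member_count")
  expected <- (w[1] * cents[[1]]$grid + w[2] * cents[[2]]$grid) / sum(w)
  expect_equal(cm$centroids[[1]]$grid, expected)
  ## greedy mode with an unreachable Dice floor merges nothing
  cm2 <- amalgamate(labels, cents, dice_threshold = 1)
  expect_equal(cm2$n_final, 6L)
  ## target count reached regardless of threshold
  cm3 <- amalgamate(labels, cents, target_n = 4)
  expect_equal(cm3$n_final, 4L)
  expect_error(amalgamate(labels, cents, merge_map = c(1, 2)), "every initial cluster")
})

test_that("lesions are assigned to the closest archetype with a stable tie-break", {
  A <- mask_from_ijk(rbind(c(2, 2, 2), c(3, 2, 2)))
  B <- mask_from_ijk(rbind(c(8, 8, 8), c(9, 8, 8)))
  cm <- amalgamate(c(1, 2), compute_centroids(list(A, B), c(1, 2)),
                   merge_map = c(1, 2))
  hit <- assign_lesion(A, cm)
  expect_equal(hit$cluster_id, 1L)
  expect_equal(unname(hit$similarity["1"]), 1)
  expect_equal(unname(hit$similarity["2"]), 0)
  ## equidistant lesion: lowest cluster id wins
  mid <- mask_from_ijk(rbind(c(2, 2, 2), c(8, 8, 8)))
  tie <- assign_lesion(mid, cm)
  expect_equal(unname(tie$similarity["1"]), unname(tie$similarity["2"]))
  expect_equal(tie$cluster_id, 1L)
  ## disjoint from everything: all-zero similarities, lowest id
  far <- mask_from_ijk(c(5, 20, 20))
  miss <- assign_lesion(far, cm)
  expect_true(all(miss$similarity == 0))
  expect_equal(miss$cluster_id, 1L)
  expect_error(assign_lesion(lesion_mask(integer(0), small_grid, 4), cm),
               "empty lesion")
})

test_that("archetype assignment agrees with cluster labels on the training set", {
  ex <- get_default_experiment(11)
  cm <- ex$rep$cluster_model
  agree <- vapply(seq_along(ex$cohort$masks), function(s) {
    assign_lesion(ex$cohort$masks[[s]], cm)$cluster_id == cm$labels[s]
  }, logical(1))
  expect_gte(mean(agree), 0.8)
})
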