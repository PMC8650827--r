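## A 20x8x8-voxel bar grid with two networks:
##   network 1: region 1 (100 voxels), region 2 (100 voxels)
##   network 2: region 3 (200 voxels)
## Each region is a union of full left-right voxel rows, so it is
## mirror-symmetric and hemisphere collapse cannot change any overlap.
bar_grid <- c(20L, 8L, 8L)
bar_parc <- function() {
  parcellation_from_regions(
    list(`1` = list(1:100, 101:200), `2` = list(201:400)),
    bar_grid)
}

test_that("damage fractions are exact region overlaps", {
  parc <- bar_parc()
  m <- lesion_mask(1:15, bar_grid, 4)       # 15 of region 1's 100 voxels
  expect_equal(damage_fraction(m, parc, 1), 0.15)
  expect_equal(damage_fraction(m, parc, 2), 0)
  full <- lesion_mask(1:100, bar_grid, 4)
  expect_equal(damage_fraction(full, parc, 1), 1)
  expect_error(damage_fraction(m, parc, 99), "unknown region_id")
})

test_that("a network is affected iff one region crosses the threshold", {
  parc <- bar_parc()
  ## region 1 at 20%, region 2 untouched -> network 1 affected (OR rule)
  d <- label_deficits(list(lesion_mask(1:20, bar_grid, 4)), parc)
  expect_true(d$values[1, "1"])
  expect_false(d$values[1, "2"])
  ## 10% + 10% across two regions never aggregates
  d2 <- label_deficits(list(lesion_mask(c(1:10, 101:110), bar_grid, 4)), parc)
  expect_false(d2$values[1, "1"])
  ## the boundary is inclusive: exactly 15% affects, just below does not
  d3 <- label_deficits(list(lesion_mask(1:15, bar_grid, 4)), parc)
  expect_true(d3$values[1, "1"])
  d4 <- label_deficits(list(lesion_mask(1:14, bar_grid, 4)), parc)
  expect_false(d4$values[1, "1"])
  expect_error(label_deficits(list(lesion_mask(1:5, bar_grid, 4)), parc,
                              threshold = 1.5), "threshold")
})

test_that("threshold extremes behave as full-coverage and any-overlap rules", {
  parc <- bar_parc()
  m <- lesion_mask(1:99, bar_grid, 4)
  expect_false(label_deficits(list(m), parc, threshold = 1)$values[1, "1"])
  full <- lesion_mask(1:100, bar_grid, 4)
  expect_true(label_deficits(list(full), parc, threshold = 1)$values[1, "1"])
  tiny <- lesion_mask(1L, bar_grid, 4)
  expect_true(label_deficits(list(tiny), parc, threshold = 1e-9)$values[1, "1"])
})

test_that("empty lesions leave every network unaffected", {
  parc <- bar_parc()
  d <- label_deficits(list(lesion_mask(integer(0), bar_grid, 4)), parc)
  expect_false(any(d$values))
})

test_that("adding lesion voxels never switches a network off", {
  parc <- bar_parc()
  withr::with_seed(17, {
    for (i in 1:50) {
      base <- sort(sample(1:400, 30))
      extra <- sort(union(base, sample(1:400, 20)))
      d_base <- label_deficits(list(lesion_mask(base, bar_grid, 4)), parc)
      d_ext <- label_deficits(list(lesion_mask(extra, bar_grid, 4)), parc)
      expect_true(all(d_ext$values >= d_base$values))
    }
  })
})
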