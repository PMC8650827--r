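test_that("hemisphere collapse mirrors right-dominant lesions only", {
  left <- mask_from_ijk(c(3, 5, 5, 4, 5, 5))
  expect_identical(collapse_hemisphere(left)$voxels, left$voxels)
  right <- mask_from_ijk(c(20, 5, 5, 21, 5, 5))
  cr <- collapse_hemisphere(right)
  expect_false(identical(cr$voxels, right$voxels))
  expect_length(cr$voxels, length(right$voxels))
  expect_identical(cr$voxels,
                   sort(lesionlatent:::mirror_indices(right$voxels, small_grid)))
  ## exactly balanced bilateral lesion: tie keeps the original orientation
  bal <- mask_from_ijk(c(3, 5, 5, 22, 5, 5))
  expect_identical(collapse_hemisphere(bal)$voxels, bal$voxels)
  expect_error(collapse_hemisphere(lesion_mask(integer(0), small_grid, 4)),
               "empty lesion")
})

test_that("collapse is idempotent on random lesions", {
  withr::with_seed(11, {
    for (i in 1:20) {
      m <- lesion_mask(sample(prod(small_grid), 40), small_grid, 4)
      c1 <- collapse_hemisphere(m)
      expect_identical(collapse_hemisphere(c1)$voxels, c1$voxels)
    }
  })
})

test_that("Gaussian smoothing conserves mass and handles edge cases", {
  vol <- array(0, c(11, 11, 11))
  vol[6, 6, 6] <- 1
  sm <- smooth_volume(vol, fwhm_mm = 2, voxel_size_mm = 1)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_gt(sm[6, 6, 6], sm[5, 6, 6])      # peaked at the source
  expect_identical(smooth_volume(vol, 0, 1), vol)
  expect_equal(smooth_volume(array(0, c(5, 5, 5)), 2, 1),
               array(0, c(5, 5, 5)))
  expect_error(smooth_volume(vol, -1, 1), ">= 0")
})

test_that("smoothing commutes with mirroring about the midline", {
  withr::with_seed(3, {
    vol <- array(0, c(12, 10, 10))
    vol[sample(length(vol), 30)] <- 1
  })
  mir <- vol[12:1, , ]
  a <- smooth_volume(mir, 3, 2)
  b <- smooth_volume(vol, 3, 2)[12:1, , ]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the data matrix stacks collapsed smoothed lesions row-wise", {
  co <- small_cohort(n = 6, seed = 21)
  dm <- build_data_matrix(co, fwhm_mm = 2)
  expect_equal(nrow(dm$values), 6)
  expect_equal(ncol(dm$values), sum(make_hemisphere_mask(small_grid)))
  expect_true(all(dm$values >= 0))
  ## fwhm = 0 keeps binary entries
  dm0 <- build_data_matrix(co, fwhm_mm = 0)
  expect_true(all(dm0$values %in% c(0, 1)))
  ## identical lesions give identical rows
  m <- co$masks[[1]]
  dm2 <- build_data_matrix(list(m, m), fwhm_mm = 2)
  expect_identical(dm2$values[1, ], dm2$values[2, ])
  ## permutation equivariance in subject order
  perm <- c(4, 1, 6, 2, 5, 3)
  dmp <- build_data_matrix(co$masks[perm], fwhm_mm = 2)
  expect_equal(dmp$values, dm$values[perm, ])
  ## shape mismatch names the offender
  odd <- lesion_mask(1:3, c(10L, 10L, 10L), 4, subject_id = "sub-odd")
  expect_error(build_data_matrix(c(co$masks[1:2], list(odd))), "sub-odd")
})

test_that("lesion volume is voxel count times voxel volume", {
  m <- lesion_mask(1:10, small_grid, 2)
  expect_equal(lesion_volume(m), 80)
  expect_equal(lesion_volume(lesion_mask(integer(0), small_grid, 2)), 0)
  mm <- lesion_mask(lesionlatent:::mirror_indices(m$voxels, small_grid),
                    small_grid, 2)
  expect_equal(lesion_volume(mm), lesion_volume(m))
})
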