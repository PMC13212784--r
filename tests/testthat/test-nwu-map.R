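test_that("nwu_scalar follows the defining formula and guards the denominator", {
  expect_equal(nwu_scalar(33, 33), 0)
  for (b in c(0.5, 1, 27, 33, 41.7, 1000))
    expect_equal(nwu_scalar(0.9 * b, b), 10, tolerance = 1e-12)
  expect_equal(nwu_scalar(30, 40), 25)
  expect_error(nwu_scalar(10, 0), "denominator")
  expect_error(nwu_scalar(10, -5), "denominator")
})

test_that("parenchyma mask applies positivity, HU band and edge rules", {
  v <- array(35, c(24, 24, 24))
  v[2, 2, 2] <- 1200      # skull-range voxel
  v[3, 3, 3] <- -5        # negative voxel
  v[4, 4, 4] <- 8         # CSF-range voxel
  hemi <- ct_volume(v)
  pm <- parenchyma_mask(hemi, list(csf_hu = 10, bone_hu = 60,
                                   edge_threshold = 120))
  expect_identical(pm$mask$values[2, 2, 2], 0L)
  expect_identical(pm$mask$values[3, 3, 3], 0L)
  expect_identical(pm$mask$values[4, 4, 4], 0L)
  expect_gt(pm$exclusions[["edge"]], 0)

  # uniform block: interior voxels survive; boundary removed by the edge
  # rule exactly where the brute-force Sobel magnitude crosses threshold
  u <- ct_volume(array(35, c(16, 16, 16)))
  pmu <- parenchyma_mask(u, list(csf_hu = 10, bone_hu = 60,
                                 edge_threshold = 120))
  expect_true(all(pmu$mask$values[3:14, 3:14, 3:14] == 1L))
  for (pt in list(c(1, 8, 8), c(8, 1, 8), c(16, 8, 8), c(5, 5, 5))) {
    sob <- oracle_sobel_at(u$values, pt[1], pt[2], pt[3])
    expect_identical(pmu$mask$values[pt[1], pt[2], pt[3]],
                     as.integer(sob < 120))
  }
  expect_error(parenchyma_mask(ct_volume(array(-10, c(12, 12, 12)))),
               "no parenchyma")
})

test_that("masked pooling matches the brute-force sliding-window oracle", {
  set.seed(42)
  for (i in 1:6) {
    d <- c(14, 12, 10)
    vol <- ct_volume(array(rnorm(prod(d), 30, 10), d))
    mask <- binary_mask(array(runif(prod(d)) > 0.3, d))
    pf <- masked_average_pool(vol, mask, kernel_mm = c(5, 5, 3), min_count = 10)
    or <- oracle_masked_pool(vol$values, mask$values, c(2, 2, 1))
    expect_true(all(pf$count == or$count))
    both <- !is.na(or$mean)
    expect_lt(max(abs(pf$mean[both] - or$mean[both])), 1e-6)
    expect_true(all(pf$valid == (or$count >= 10)))
  }
})

test_that("pooling respects constants, bounds and the coverage rule", {
  d <- c(20, 20, 20)
  vol <- ct_volume(array(35, d))
  full <- binary_mask(array(TRUE, d))
  pf <- masked_average_pool(vol, full, kernel_mm = c(5, 5, 5), min_count = 1)
  expect_lt(max(abs(pf$mean - 35)), 1e-9)

  set.seed(9)
  rv <- ct_volume(array(runif(prod(d), 10, 60), d))
  msk <- binary_mask(array(runif(prod(d)) > 0.4, d))
  pp <- masked_average_pool(rv, msk, kernel_mm = c(7, 7, 7), min_count = 5)
  inmask <- rv$values[msk$values == 1]
  ok <- !is.na(pp$mean)
  expect_gte(min(pp$mean[ok]), min(inmask) - 1e-9)
  expect_lte(max(pp$mean[ok]), max(inmask) + 1e-9)

  # validity count is non-increasing in min_count
  counts <- vapply(c(1, 50, 150, 250, 343),
                   function(mc) sum(masked_average_pool(rv, msk,
                     kernel_mm = c(7, 7, 7), min_count = mc)$valid),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))

  expect_error(masked_average_pool(rv, msk, kernel_mm = c(6, 6, 6)), "odd")
  expect_error(masked_average_pool(rv, msk, kernel_mm = c(31, 31, 31)),
               "larger")
})

test_that("the 10% coverage rule at 1 mm gives 133 voxels and gates validity", {
  d <- c(24, 24, 24)
  vol <- ct_volume(array(35, d))
  mask <- binary_mask(array(TRUE, d))
  pf <- masked_average_pool(vol, mask)   # defaults: 11 mm kernel, 10%
  expect_identical(pf$min_count, 133)
  expect_identical(prod(pf$kernel_voxels), 1331)

  # a window holding only 100 in-mask voxels is invalid at min_count 133
  sparse <- array(FALSE, d)
  sparse[12 + (-4:4), 12 + (-3:3), 12:13] <- TRUE   # 9*7*2 = 126 voxels
  spm <- binary_mask(sparse)
  pf2 <- masked_average_pool(vol, spm)
  expect_identical(sum(spm$values), 126L)
  expect_false(pf2$valid[12, 12, 12])
})

test_that("the NWU map is zero for identical fields and exact for scaled ones", {
  d <- c(20, 20, 20)
  vol <- ct_volume(array(rnorm(prod(d), 35, 3), d))
  mask <- binary_mask(array(TRUE, d))
  pl <- masked_average_pool(vol, mask, kernel_mm = c(5, 5, 5), min_count = 5)
  nm <- compute_nwu_map(pl, pl)
  expect_lt(max(abs(nm$nwu_left[nm$valid])), 1e-9)

  vol9 <- ct_volume(0.9 * vol$values, vol$spacing, vol$origin)
  pl9 <- masked_average_pool(vol9, mask, kernel_mm = c(5, 5, 5), min_count = 5)
  nm2 <- compute_nwu_map(pl9, pl)   # left = 0.9 * right
  expect_lt(max(abs(nm2$nwu_left[nm2$valid_left] - 10)), 1e-9)
  expect_lt(max(abs(nm2$nwu_right[nm2$valid_right] - (-100 / 9))), 1e-9)
})

test_that("NWU values are clipped to the configured range", {
  d <- c(16, 16, 16)
  lo <- ct_volume(array(10, d))
  hi <- ct_volume(array(40, d))
  mask <- binary_mask(array(TRUE, d))
  pl <- masked_average_pool(lo, mask, kernel_mm = c(3, 3, 3), min_count = 1)
  ph <- masked_average_pool(hi, mask, kernel_mm = c(3, 3, 3), min_count = 1)
  nm <- compute_nwu_map(pl, ph, clip = c(-30, 30))   # raw value would be 75
  expect_equal(max(nm$nwu_left[nm$valid_left]), 30)
  expect_equal(min(nm$nwu_right[nm$valid_right]), -30)
})

test_that("lesion-centre NWU approaches the implanted uptake for a large lesion", {
  # lesion much wider than the kernel: windows at its centre lie fully
  # inside, so the pooled ratio reproduces the implanted uptake
  sp <- small_spec(lesion_center_mm = c(-16, 0, 0),
                   lesion_radii_mm = c(12, 16, 14),
                   uptake_percent = 15, seed = 33)
  ph <- generate_phantom(sp)
  pair <- split_and_mirror(ph$ct)
  pml <- parenchyma_mask(pair$left)
  pmr <- parenchyma_mask(pair$right_mirrored)
  pl <- masked_average_pool(pair$left, pml$mask)
  pr <- masked_average_pool(pair$right_mirrored, pmr$mask)
  nm <- compute_nwu_map(pl, pr)
  # lesion centre x = -16 mm -> voxel index 36 - 16 = 20 on the left grid
  ctr <- c(20, 44, 32)
  expect_true(nm$valid[ctr[1], ctr[2], ctr[3]])
  expect_lt(abs(nm$nwu_left[ctr[1], ctr[2], ctr[3]] - 15), 0.5)
})

test_that("deepening the lesion never lowers its centre NWU", {
  prev <- -Inf
  for (w in c(5, 10, 15, 20)) {
    sp <- small_spec(lesion_center_mm = c(-16, 0, 0),
                     lesion_radii_mm = c(12, 16, 14),
                     uptake_percent = w, seed = 33)
    ph <- generate_phantom(sp)
    pair <- split_and_mirror(ph$ct)
    pl <- masked_average_pool(pair$left, parenchyma_mask(pair$left)$mask)
    pr <- masked_average_pool(pair$right_mirrored,
                              parenchyma_mask(pair$right_mirrored)$mask)
    nm <- compute_nwu_map(pl, pr)
    val <- nm$nwu_left[20, 44, 32]
    expect_gt(val, prev)
    prev <- val
  }
})
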