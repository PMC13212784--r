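test_that("Otsu matches the exhaustive between-class-variance oracle", {
  set.seed(5)
  for (i in 1:20) {
    v <- c(rnorm(150, 2, 0.3), rnorm(80, 18, 1.2))
    expect_equal(otsu_threshold(v), oracle_otsu(v), tolerance = 1e-10)
  }
  # a clearly bimodal sample thresholds between the modes
  v <- c(rnorm(100, 2, 0.1), rnorm(100, 20, 0.1))
  t <- otsu_threshold(v)
  expect_gt(t, 3)
  expect_lt(t, 19)
  # invariant to duplicating the data
  expect_equal(otsu_threshold(c(v, v)), t)
  expect_error(otsu_threshold(rep(7, 50)), "degenerate")
})

test_that("largest connected component agrees with the union-find oracle", {
  set.seed(11)
  for (i in 1:20) {
    m <- array(runif(12^3) < 0.25, c(12, 12, 12))
    for (conn in c(6, 26)) {
      mine <- largest_connected_component(binary_mask(m), conn)
      orc <- oracle_largest_cc(m * 1L, conn)
      expect_identical(mine$values, orc)
      # component counts agree too
      labs <- nwuct:::cpp_label_components(as.integer(m), dim(m), conn)
      expect_identical(max(labs, 0L), max(oracle_label_cc(m * 1L, conn)))
    }
  }
})

test_that("largest-CC picks the bigger cuboid and breaks ties deterministically", {
  m <- array(FALSE, c(16, 16, 16))
  m[2:4, 2:4, 2:4] <- TRUE      # 27 voxels
  m[10:11, 10:11, 10:11] <- TRUE  # 8 voxels
  out <- largest_connected_component(binary_mask(m), 26)
  expect_identical(sum(out$values), 27L)
  expect_true(all(out$values[2:4, 2:4, 2:4] == 1L))

  # equal-size components: the one containing the smaller linear index wins
  m2 <- array(FALSE, c(16, 16, 16))
  m2[2:4, 2:4, 2:4] <- TRUE
  m2[10:12, 10:12, 10:12] <- TRUE
  out2 <- largest_connected_component(binary_mask(m2), 26)
  expect_true(all(out2$values[2:4, 2:4, 2:4] == 1L))
  expect_identical(sum(out2$values), 27L)

  # diagonal-touching voxels: connected at 26, split at 6
  m3 <- array(FALSE, c(8, 8, 8))
  m3[2, 2, 2] <- TRUE
  m3[3, 3, 3] <- TRUE
  expect_identical(max(nwuct:::cpp_label_components(as.integer(m3), dim(m3), 26L)), 1L)
  expect_identical(max(nwuct:::cpp_label_components(as.integer(m3), dim(m3), 6L)), 2L)

  # empty input passes through
  e <- binary_mask(array(FALSE, c(8, 8, 8)))
  expect_identical(sum(largest_connected_component(e)$values), 0L)
})

test_that("ball morphology and hole filling behave geometrically", {
  m <- array(FALSE, c(20, 20, 20))
  m[5:15, 5:15, 5:15] <- TRUE
  bm <- binary_mask(m)
  er <- morph_ball(bm, 1, "erode")
  expect_identical(sum(er$values), as.integer(9^3))
  di <- morph_ball(er, 1, "dilate")
  # opening is anti-extensive and volume-preserving up to edges/corners
  expect_true(all(di$values <= m))
  expect_true(all(di$values >= er$values))
  expect_gte(sum(di$values), 11^3 - 12 * 11 - 8)

  holey <- m
  holey[9:11, 9:11, 9:11] <- FALSE
  filled <- fill_holes(binary_mask(holey))
  expect_identical(filled$values, binary_mask(m)$values)
})

test_that("two supra-threshold blobs reduce to the larger one", {
  d <- c(40, 40, 40)
  nl <- array(0, d)
  nl[5:16, 5:16, 5:16] <- 12    # 1728-voxel blob
  nl[25:30, 25:30, 25:30] <- 12 # 216-voxel blob
  nl[20:29, 5:14, 5:14] <- 3    # low-NWU skirt giving Otsu two classes
  nm <- structure(list(nwu_left = nl, nwu_right = array(-10, d),
                       valid_left = array(TRUE, d),
                       valid_right = array(TRUE, d),
                       valid = array(TRUE, d), clip = c(-30, 30),
                       spacing = c(1, 1, 1), origin = c(0, 0, 0)),
                  class = "nwu_map")
  lc <- extract_lesion_mask(nm)
  expect_identical(lc$side, "left")
  expect_identical(lc$component_count, 2L)
  w <- which(lc$mask$values == 1, arr.ind = TRUE)
  expect_true(all(w[, 1] <= 16))   # only the large blob survives
  # single connected component after post-processing
  labs <- nwuct:::cpp_label_components(as.integer(lc$mask$values),
                                       dim(lc$mask$values), 26L)
  expect_identical(max(labs), 1L)
})

test_that("raising the lower cutoff never grows the lesion mask", {
  ph <- generate_phantom(small_lesion_spec(uptake = 12, noise_sd = 2))
  pair <- split_and_mirror(ph$ct)
  pl <- masked_average_pool(pair$left, parenchyma_mask(pair$left)$mask)
  pr <- masked_average_pool(pair$right_mirrored,
                            parenchyma_mask(pair$right_mirrored)$mask)
  nm <- compute_nwu_map(pl, pr)
  vols <- vapply(c(1, 2.5, 5, 8, 11),
                 function(lc) sum(extract_lesion_mask(nm,
                   list(lower_cutoff = lc))$mask$values),
                 numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("lesion report: volume conversion, side, and exact phantom NWU", {
  ph <- generate_phantom(small_lesion_spec(uptake = 10, noise_sd = 0))
  pair <- split_and_mirror(ph$ct)
  gt_h <- nwuct:::full_mask_to_hemisphere(ph$gt_mask$values, pair, "left")
  cand <- as_lesion_candidate(binary_mask(gt_h != 0, pair$spacing, pair$origin),
                              "left")
  rep <- lesion_report(pair, pair$right_mirrored, cand)
  expect_identical(rep$side, "left")
  expect_equal(rep$volume_ml, sum(gt_h) / 1000)
  expect_lt(abs(rep$nwu_total - 10), 0.1)

  # 20000 voxels at 1 mm3 are 20 mL
  big <- array(FALSE, c(40, 40, 40))
  big[1:20, 1:40, 1:25] <- TRUE   # 20000 voxels
  expect_equal(mask_volume_ml(binary_mask(big)), 20)

  # empty lesion: side none, volume 0, NWU undefined
  emp <- as_lesion_candidate(binary_mask(array(FALSE, dim(gt_h)),
                                         pair$spacing, pair$origin), "none")
  rep0 <- lesion_report(pair, pair$right_mirrored, emp)
  expect_identical(rep0$side, "none")
  expect_identical(rep0$volume_ml, 0)
  expect_true(is.na(rep0$nwu_total))
})

test_that("noise shifts the ground-truth NWU estimate only slightly", {
  base <- phantom_measured_nwu(generate_phantom(
    small_spec(lesion_center_mm = c(-14, -6, 0), lesion_radii_mm = c(11, 12, 10),
               uptake_percent = 12, noise_sd = 0, seed = 55)))
  noisy <- phantom_measured_nwu(generate_phantom(
    small_spec(lesion_center_mm = c(-14, -6, 0), lesion_radii_mm = c(11, 12, 10),
               uptake_percent = 12, noise_sd = 6, seed = 55)))
  expect_lt(abs(noisy - base), 0.5)
})
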