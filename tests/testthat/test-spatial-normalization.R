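test_that("affine transforms compose, invert and round-trip", {
  set.seed(1)
  for (i in 1:5) {
    tf <- rigid_transform(runif(3, -15, 15), runif(3, -20, 20),
                          center_mm = runif(3, -10, 10))
    inv <- affine_invert(tf)
    comp <- affine_compose(inv, tf)
    pts <- matrix(runif(30, -50, 50), ncol = 3)
    expect_lt(max(abs(affine_apply(comp, pts) - pts)), 1e-6)
  }
  expect_error(affine_transform(matrix(0, 3, 3)), "singular")
})

test_that("affine transforms serialise to a plain-text 4x4 matrix", {
  tf <- rigid_transform(c(3, -7, 11), c(4.5, -2, 8))
  f <- tempfile(fileext = ".txt")
  write_affine(tf, f)
  rt <- read_affine(f)
  expect_equal(rt$A, tf$A, tolerance = 1e-12)
  expect_equal(rt$t, tf$t, tolerance = 1e-12)
})

test_that("mirroring is an exact involution and the split conserves voxels", {
  ph <- generate_phantom(small_spec(noise_sd = 3, seed = 21))
  expect_identical(mirror_volume(mirror_volume(ph$ct))$values, ph$ct$values)

  pair <- split_and_mirror(ph$ct)
  nx <- dim(ph$ct$values)[1]
  half <- nx %/% 2
  expect_identical(dim(pair$left$values), dim(pair$right_mirrored$values))
  # conservation: left + right cover all slices (even axis: exactly)
  expect_equal(2 * half, nx)
  expect_identical(pair$left$values, ph$ct$values[1:half, , ])
  expect_identical(pair$right_mirrored$values,
                   ph$ct$values[nx:(half + 1), , ])
})

test_that("odd split axis drops exactly the central slice from both halves", {
  v <- ct_volume(array(seq_len(17 * 12 * 12), c(17, 12, 12)))
  pair <- split_and_mirror(v)
  expect_identical(dim(pair$left$values)[1], 8L)
  expect_identical(pair$left$values, v$values[1:8, , ])
  expect_identical(pair$right_mirrored$values, v$values[17:10, , ])
  expect_equal(pair$midplane, 9)
})

test_that("a symmetric phantom splits into identical hemispheres", {
  ph <- generate_phantom(small_spec(seed = 5))   # noise-free, no lesion
  pair <- split_and_mirror(ph$ct)
  expect_identical(pair$left$values, pair$right_mirrored$values)
})

test_that("self-registration recovers a near-identity transform", {
  tmpl <- small_template()
  reg <- align_to_template(tmpl, tmpl)
  rot_deg <- acos(pmin(1, (sum(diag(reg$transform$A)) - 1) / 2)) * 180 / pi
  expect_lt(rot_deg, 0.5)
  expect_lt(sqrt(sum(reg$transform$t^2)), 0.5)
  expect_lte(reg$metric["final"], reg$metric["identity"] + 1e-9)
})

test_that("a known rigid transform applied to the phantom is recovered", {
  tmpl <- small_template()
  ph <- generate_phantom(small_spec(noise_sd = 2, seed = 31))
  ctr <- ph$ct$origin + (dim(ph$ct$values) - 1) / 2 * ph$ct$spacing
  tf0 <- rigid_transform(c(5, -3, 2), c(4, -3, 2), center_mm = ctr)
  moved <- apply_affine(ph$ct, tf0, ph$ct)
  reg <- align_to_template(moved, tmpl)
  comp <- affine_compose(reg$transform, tf0)
  pts <- as.matrix(expand.grid(c(20, 36, 52), c(24, 44, 64), c(18, 32, 46)))
  err <- sqrt(rowSums((affine_apply(comp, pts) - pts)^2))
  expect_lt(max(err), 1)
})

test_that("registration of non-overlapping volumes raises a convergence error", {
  tmpl <- small_template()
  far <- ct_volume(array(35, c(16, 16, 16)), origin = c(5000, 5000, 5000))
  expect_error(align_to_template(far, tmpl), "overlap")
})

test_that("mask mapping: identity, pure translation, and round trip", {
  m <- array(FALSE, c(40, 40, 40))
  m[10:20, 12:22, 14:24] <- TRUE
  mask <- binary_mask(m)
  # identity
  out <- map_mask_affine(mask, affine_identity(), mask)
  expect_identical(out$values, mask$values)
  # 10 mm translation along x moves the centroid by 10 voxels at 1 mm
  tf <- rigid_transform(c(0, 0, 0), c(10, 0, 0))
  big <- binary_mask(array(FALSE, c(40, 40, 40)))
  shifted <- map_mask_affine(mask, tf, big)
  c0 <- colMeans(which(mask$values == 1, arr.ind = TRUE))
  c1 <- colMeans(which(shifted$values == 1, arr.ind = TRUE))
  expect_equal(unname(c1 - c0), c(10, 0, 0), tolerance = 0.5)
  # forward-then-inverse keeps Dice high on >= 1000-voxel cuboids
  set.seed(7)
  for (i in 1:5) {
    tfr <- rigid_transform(runif(3, -8, 8), runif(3, -6, 6),
                           center_mm = c(20, 20, 20))
    fwd <- map_mask_affine(mask, tfr, big)
    back <- map_mask_affine(fwd, affine_invert(tfr), big)
    expect_gte(dice(back, mask), 0.95)
  }
})
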