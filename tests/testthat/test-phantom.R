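test_that("phantom generation is bitwise deterministic per seed", {
  sp <- small_lesion_spec(uptake = 12, noise_sd = 3, seed = 99)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$gt_mask$values, b$gt_mask$values)
  # a different seed gives a different realisation
  c2 <- generate_phantom(small_lesion_spec(uptake = 12, noise_sd = 3, seed = 100))
  expect_false(identical(a$ct$values, c2$ct$values))
})

test_that("noise-free lesion-free phantom is exactly mirror-symmetric", {
  ph <- generate_phantom(small_spec(seed = 3))
  v <- ph$ct$values
  expect_identical(v, v[dim(v)[1]:1, , ])
  expect_identical(sum(ph$gt_mask$values), 0L)
  expect_false(ph$lesion_present)
})

test_that("implanted density ratio reproduces the requested uptake exactly", {
  for (w in c(5, 12, 20)) {
    ph <- generate_phantom(small_spec(
      lesion_center_mm = c(-14, -5, 2), lesion_radii_mm = c(10, 12, 9),
      uptake_percent = w, seed = 41))
    measured <- phantom_measured_nwu(ph)
    expect_lt(abs(measured - w), 0.1)
    expect_equal(ph$gt_nwu, w)
    # mean-HU ratio inside the mask vs its mirror
    m <- ph$gt_mask$values != 0
    mm <- m[dim(m)[1]:1, , ]
    ratio <- mean(ph$ct$values[m]) / mean(ph$ct$values[mm])
    expect_lt(abs(ratio - (1 - w / 100)) * 35, 0.1)   # within 0.1 HU at 35 HU
  }
})

test_that("infeasible lesion specifications are rejected", {
  expect_error(generate_phantom(small_spec(
    lesion_center_mm = c(-3, 0, 0), lesion_radii_mm = c(8, 8, 8),
    uptake_percent = 10)), "midplane")
  expect_error(generate_phantom(small_spec(
    lesion_center_mm = c(-25, 0, 0), lesion_radii_mm = c(12, 30, 12),
    uptake_percent = 10)), "outside")
  expect_error(phantom_spec(uptake_percent = 40), "uptake")
  expect_error(phantom_spec(noise_sd = -1), "noise")
})

test_that("phantom suites are reproducible and respect requested ranges", {
  s1 <- phantom_suite(n = 4, uptake = c(0, 10, 15), volume_ml = c(3, 8),
                      noise_sd = c(0, 2), base_spec = small_spec(), seed = 6)
  s2 <- phantom_suite(n = 4, uptake = c(0, 10, 15), volume_ml = c(3, 8),
                      noise_sd = c(0, 2), base_spec = small_spec(), seed = 6)
  expect_identical(s1$table, s2$table)
  for (i in seq_len(4))
    expect_identical(s1$cases[[i]]$ct$values, s2$cases[[i]]$ct$values)

  tab <- s1$table
  expect_identical(nrow(tab), 4L)
  # uptake 0 rows are flagged lesion-absent
  expect_identical(tab$lesion_present, tab$uptake > 0)
  present <- tab$lesion_present
  expect_true(all(tab$nominal_volume_ml[present] >= 3 - 1e-9))
  expect_true(all(tab$nominal_volume_ml[present] <= 8 + 1e-9))
  # achieved volume close to nominal (voxelisation + possible ventricle
  # exclusion make it slightly smaller)
  expect_true(all(abs(tab$achieved_volume_ml[present] -
                      tab$nominal_volume_ml[present]) /
                  tab$nominal_volume_ml[present] < 0.25))
  expect_true(all(tab$noise_sd >= 0 & tab$noise_sd <= 2))
})

test_that("lesions stay inside one hemisphere's parenchyma across a suite", {
  s <- phantom_suite(n = 5, uptake = c(8, 15), volume_ml = c(3, 10),
                     noise_sd = c(0, 0), base_spec = small_spec(), seed = 17)
  for (case in s$cases) {
    m <- case$gt_mask$values
    nx <- dim(m)[1]
    idx <- which(m != 0, arr.ind = TRUE)
    expect_gt(nrow(idx), 0)
    onleft <- all(idx[, 1] <= nx / 2)
    onright <- all(idx[, 1] >= nx / 2 + 1)
    expect_true(onleft || onright)
    # every lesion voxel is parenchyma-range HU (well below bone, above CSF)
    vals <- case$ct$values[m != 0]
    expect_true(all(vals > 14 & vals < 60))
  }
})
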