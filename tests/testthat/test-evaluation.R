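mk_mask <- function(d, ranges = NULL) {
  m <- array(FALSE, d)
  if (!is.null(ranges)) m[ranges[[1]], ranges[[2]], ranges[[3]]] <- TRUE
  binary_mask(m)
}

test_that("Dice: identity, disjoint, half-overlap, symmetry, empties", {
  d <- c(20, 20, 20)
  a <- mk_mask(d, list(1:10, 1:10, 1:1))    # 100 voxels
  expect_equal(dice(a, a), 1)
  b <- mk_mask(d, list(11:20, 11:20, 2:2))
  expect_equal(dice(a, b), 0)
  # |a|=|b|=100, |intersection|=50
  c1 <- mk_mask(d, list(1:10, 1:10, 1:1))
  c2 <- mk_mask(d, list(6:15, 1:10, 1:1))
  expect_equal(dice(c1, c2), 0.5)
  expect_equal(dice(c2, c1), dice(c1, c2))
  expect_equal(dice(mk_mask(d), mk_mask(d)), 1)   # agreement on absence
  wrong <- mk_mask(c(10, 10, 10))
  expect_error(dice(a, wrong), "grid")
})

test_that("bounding-box IoU: identity, nesting, translation invariance", {
  d <- c(30, 30, 30)
  a <- mk_mask(d, list(5:14, 5:14, 5:14))
  expect_equal(bounding_box_iou(a, a), 1)
  # nested box with half the volume
  b <- mk_mask(d, list(5:14, 5:14, 5:9))
  expect_equal(bounding_box_iou(a, b), 0.5)
  # only one empty -> 0; both empty -> 1
  expect_equal(bounding_box_iou(a, mk_mask(d)), 0)
  expect_equal(bounding_box_iou(mk_mask(d), mk_mask(d)), 1)
  # joint translation leaves the IoU unchanged
  a2 <- mk_mask(d, list(10:19, 8:17, 11:20))
  b2 <- mk_mask(d, list(12:21, 8:17, 11:20))
  a3 <- mk_mask(d, list(15:24, 13:22, 16:25))
  b3 <- mk_mask(d, list(17:26, 13:22, 16:25))
  expect_equal(bounding_box_iou(a2, b2), bounding_box_iou(a3, b3))
  # the 3D detection threshold constant
  expect_equal(iou_threshold_3d(), 0.5^(3 / 2))
  expect_equal(iou_threshold_3d(), 0.35355, tolerance = 1e-4)
})

test_that("mAP is the fraction of cases above threshold and monotone in it", {
  expect_equal(mean_average_precision(c(0.9, 0.8, 0.7)), 1)
  expect_equal(mean_average_precision(c(0.1, 0.2, 0.3)), 0)
  expect_equal(mean_average_precision(c(0.9, 0.1)), 0.5)
  expect_error(mean_average_precision(numeric(0)), "no cases")
  ious <- c(0.1, 0.3, 0.36, 0.5, 0.9)
  maps <- vapply(c(0.1, 0.3, 0.5, 0.7),
                 function(t) mean_average_precision(ious, t), numeric(1))
  expect_true(all(diff(maps) <= 0))
  # strict inequality at the threshold
  expect_equal(mean_average_precision(c(0.5), 0.5), 0)
})

test_that("NWU error statistics reproduce worked examples and MAE >= |ME|", {
  s1 <- nwu_error_stats(c(5, 10), c(5, 10))
  expect_equal(s1$mae, 0)
  expect_equal(s1$me, 0)
  s2 <- nwu_error_stats(c(12, 8), c(10, 10))
  expect_equal(s2$mae, 2)
  expect_equal(s2$me, 0)
  s3 <- nwu_error_stats(c(11, 13, 16), c(10, 10, 10))
  expect_equal(s3$median_ae, 3)
  expect_error(nwu_error_stats(NA_real_, 5), "no complete pairs")
  set.seed(3)
  for (i in 1:20) {
    s <- nwu_error_stats(rnorm(15, 10, 4), rnorm(15, 10, 2))
    expect_gte(s$mae, abs(s$me))
  }
})

test_that("case and cohort metrics assemble the panel correctly", {
  d <- c(20, 20, 20)
  ref <- mk_mask(d, list(5:14, 5:14, 5:14))
  pred <- mk_mask(d, list(6:15, 5:14, 5:14))
  cm <- case_metrics(pred, ref, 11, 10)
  expect_true(cm$detected)
  expect_equal(cm$nwu_error, 1)
  expect_gt(cm$dice, 0.8)

  # perfect predictions give a perfect panel
  rows <- do.call(rbind, lapply(1:3, function(i)
    case_metrics(ref, ref, 10 + i, 10 + i)))
  s <- cohort_metrics(rows)
  expect_equal(s$detection_rate, 1)
  expect_equal(s$dice_median, 1)
  expect_equal(s$mae, 0)
  expect_equal(s$map_at_threshold, 1)

  # dilated predictions: detection stays 1, Dice drops below 1
  dil <- morph_ball(ref, 1, "dilate")
  cm2 <- case_metrics(dil, ref)
  expect_true(cm2$detected)
  expect_lt(cm2$dice, 1)
  expect_gt(cm2$dice, 0.7)
  expect_error(cohort_metrics(data.frame()), "no cases")
})
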