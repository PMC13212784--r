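#' Dice similarity coefficient
#'
#' `2|A∩B| / (|A|+|B|)`. Two empty masks agree perfectly on the absence of
#' a lesion and score 1.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  stop_if_grid_mismatch(a, b, "masks")
  na <- sum(a$values); nb <- sum(b$values)
  if (na == 0 && nb == 0) return(1)
  2 * sum(a$values & b$values) / (na + nb)
}

#' Intersection-over-union of axis-aligned bounding boxes
#'
#' IoU of the voxel bounding boxes of two masks. Both empty: 1 (perfect
#' agreement on absence); exactly one empty: 0.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return Bounding-box IoU in [0, 1].
#' @export
bounding_box_iou <- function(a, b) {
  stop_if_grid_mismatch(a, b, "masks")
  ea <- sum(a$values) == 0; eb <- sum(b$values) == 0
  if (ea && eb) return(1)
  if (ea || eb) return(0)
  bbox <- function(m) {
    w <- which(m$values != 0, arr.ind = TRUE)
    rbind(lo = apply(w, 2, min), hi = apply(w, 2, max))
  }
  ba <- bbox(a); bb <- bbox(b)
  inter <- prod(pmax(0, pmin(ba["hi", ], bb["hi", ]) -
                       pmax(ba["lo", ], bb["lo", ]) + 1))
  va <- prod(ba["hi", ] - ba["lo", ] + 1)
  vb <- prod(bb["hi", ] - bb["lo", ] + 1)
  inter / (va + vb - inter)
}

#' Detection threshold for 3D bounding-box IoU
#'
#' The 2D convention of IoU > 0.5 extended to 3D: `0.5^(3/2)`.
#' @return The numeric threshold, about 0.35355.
#' @export
iou_threshold_3d <- function() 0.5^(3 / 2)

#' Mean average precision at a fixed IoU threshold
#'
#' In this single-detection-per-case pipeline there is no confidence
#' ranking, so mAP reduces to the fraction of cases whose bounding-box IoU
#' strictly exceeds the threshold.
#'
#' @param bbox_ious numeric vector of per-case bounding-box IoUs.
#' @param iou_threshold detection threshold (default [iou_threshold_3d()]).
#' @return Fraction of cases counted as correct detections.
#' @export
mean_average_precision <- function(bbox_ious, iou_threshold = iou_threshold_3d()) {
  if (length(bbox_ious) == 0) stop("mean_average_precision: no cases")
  mean(bbox_ious > iou_threshold)
}

#' NWU error statistics over a cohort
#'
#' Errors are computed minus reference, in percentage points.
#'
#' @param computed,reference numeric vectors of NWU values (%).
#' @return List with `mae`, `mae_sd`, `me`, `me_sd`, `median_ae`,
#'   `ae_iqr` (25th/75th percentiles of the absolute error) and `n`.
#' @export
nwu_error_stats <- function(computed, reference) {
  ok <- is.finite(computed) & is.finite(reference)
  if (!any(ok)) stop("nwu_error_stats: no complete pairs")
  e <- computed[ok] - reference[ok]
  ae <- abs(e)
  list(mae = mean(ae), mae_sd = stats::sd(ae),
       me = mean(e), me_sd = stats::sd(e),
       median_ae = stats::median(ae),
       ae_iqr = unname(stats::quantile(ae, c(0.25, 0.75))),
       n = sum(ok))
}

#' Per-case evaluation of a computed lesion mask
#'
#' @param pred,ref [binary_mask()] objects on the same grid.
#' @param nwu_computed,nwu_reference NWU values (%), may be NA.
#' @return One-row data frame of case metrics.
#' @export
case_metrics <- function(pred, ref, nwu_computed = NA_real_,
                         nwu_reference = NA_real_) {
  inter <- sum(pred$values & ref$values)
  detected <- if (sum(pred$values) == 0 && sum(ref$values) == 0) TRUE
              else inter >= 1
  data.frame(dice = dice(pred, ref),
             detected = detected,
             bbox_iou = bounding_box_iou(pred, ref),
             nwu_computed = nwu_computed,
             nwu_reference = nwu_reference,
             nwu_error = nwu_computed - nwu_reference,
             volume_pred_ml = mask_volume_ml(pred),
             volume_ref_ml = mask_volume_ml(ref))
}

#' Cohort summary of case metrics
#'
#' Detection rate (any-voxel overlap), NWU error statistics, Dice
#' median/IQR, and mAP at the 3D IoU threshold.
#'
#' @param cases data frame with rows from [case_metrics()].
#' @param iou_threshold detection threshold for mAP.
#' @return List of cohort metrics.
#' @export
cohort_metrics <- function(cases, iou_threshold = iou_threshold_3d()) {
  if (nrow(cases) == 0) stop("cohort_metrics: no cases")
  err <- tryCatch(nwu_error_stats(cases$nwu_computed, cases$nwu_reference),
                  error = function(e) NULL)
  list(n = nrow(cases),
       detection_rate = mean(cases$detected),
       mae = if (!is.null(err)) err$mae else NA_real_,
       me = if (!is.null(err)) err$me else NA_real_,
       median_ae = if (!is.null(err)) err$median_ae else NA_real_,
       ae_iqr = if (!is.null(err)) err$ae_iqr else c(NA_real_, NA_real_),
       dice_median = stats::median(cases$dice),
       dice_iqr = unname(stats::quantile(cases$dice, c(0.25, 0.75))),
       map_at_threshold = mean_average_precision(cases$bbox_iou, iou_threshold),
       iou_threshold = iou_threshold)
}
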