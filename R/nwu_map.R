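#' Net water uptake of two mean densities
#'
#' `NWU = (1 - mean_A / mean_B) * 100`, the percentage density reduction of
#' the ischemic region A relative to its contralateral counterpart B.
#'
#' @param mean_a mean HU of the (candidate) ischemic region.
#' @param mean_b mean HU of the contralateral region; must be > 0.
#' @return NWU in percent.
#' @export
nwu_scalar <- function(mean_a, mean_b) {
  if (!is.numeric(mean_a) || !is.numeric(mean_b) || anyNA(mean_a) || anyNA(mean_b))
    stop("nwu_scalar: inputs must be numeric and non-missing")
  if (any(mean_b <= 0))
    stop("nwu_scalar: contralateral mean HU must be > 0 (undefined denominator)")
  (1 - mean_a / mean_b) * 100
}

#' Hemisphere parenchyma mask
#'
#' Brain-parenchyma voxels of one hemisphere: positive HU, inside the
#' parenchyma HU band (above CSF, below bone), and away from strong edges
#' (3D Sobel gradient magnitude below a threshold, which removes skull
#' interfaces and other non-parenchymal structure). The voxels removed by
#' each rule are counted for diagnostics.
#'
#' @param hemi a hemisphere [ct_volume()] in HU.
#' @param config mask section of [nwu_config()]: `csf_hu`, `bone_hu`,
#'   `edge_threshold` (Sobel magnitude in HU per voxel, unnormalised
#'   weights).
#' @return A list of class `parenchyma_mask` with `mask` (a
#'   [binary_mask()]) and `exclusions` (voxels removed per rule).
#' @export
parenchyma_mask <- function(hemi, config = nwu_config()$mask) {
  if (!is_ct_volume(hemi)) stop("parenchyma_mask: need a ct_volume")
  cfg <- utils::modifyList(nwu_config()$mask, as.list(config))
  v <- hemi$values
  pos <- v > 0
  band <- (v > cfg$csf_hu) & (v < cfg$bone_hu)
  sob <- array(cpp_sobel_magnitude(as.numeric(v), as.integer(dim(v))), dim(v))
  edge_ok <- sob < cfg$edge_threshold
  keep <- pos & band & edge_ok
  if (!any(keep))
    stop("parenchyma_mask: no parenchyma voxels found")
  structure(list(
    mask = binary_mask(keep, hemi$spacing, hemi$origin),
    exclusions = c(non_positive = sum(!pos),
                   outside_hu_band = sum(pos & !band),
                   edge = sum(pos & band & !edge_ok))),
    class = "parenchyma_mask")
}

#' Masked 3D average pooling
#'
#' For every voxel, the mean HU over in-mask voxels within a centred
#' kernel window (default 11 x 11 x 11 mm). Windows are truncated at the
#' volume border and outside-volume positions count as out-of-mask; a
#' voxel is valid only when the in-mask count reaches `min_count`
#' (default 10% of the nominal kernel volume, i.e. 133 voxels for an
#' 11-voxel kernel at 1 mm).
#'
#' @param vol a [ct_volume()].
#' @param mask a [binary_mask()] on the same grid.
#' @param kernel_mm kernel extents in mm (odd number of voxels per axis).
#' @param min_fraction minimum in-mask fraction of the nominal kernel
#'   volume for validity.
#' @param min_count absolute voxel-count override of `min_fraction`.
#' @return Object of class `pooled_field`: `mean` (3D array, NA where the
#'   window holds no mask voxel), `count`, `valid` (logical array),
#'   `min_count`, plus grid metadata.
#' @export
masked_average_pool <- function(vol, mask, kernel_mm = c(11, 11, 11),
                                min_fraction = 0.10, min_count = NULL) {
  stop_if_grid_mismatch(vol, mask, "volume and mask")
  kvox <- round(kernel_mm / vol$spacing)
  if (any(kvox %% 2 == 0))
    stop("masked_average_pool: kernel must span an odd number of voxels per axis")
  if (any(kvox > vol_dim(vol)))
    stop("masked_average_pool: kernel larger than the volume")
  nominal <- prod(kvox)
  if (is.null(min_count)) min_count <- floor(min_fraction * nominal)
  r <- (kvox - 1) / 2
  res <- cpp_masked_pool(as.numeric(vol$values), as.integer(mask$values),
                         as.integer(vol_dim(vol)),
                         as.integer(r[1]), as.integer(r[2]), as.integer(r[3]))
  d <- vol_dim(vol)
  cnt <- array(res$count, d)
  structure(list(mean = array(res$mean, d), count = cnt,
                 valid = cnt >= min_count, min_count = min_count,
                 kernel_voxels = kvox, spacing = vol$spacing,
                 origin = vol$origin),
            class = "pooled_field")
}

#' Voxel-wise NWU map from pooled hemisphere fields
#'
#' Applies the NWU formula per voxel to corresponding window means of the
#' left and (deformably warped, mirrored) right hemisphere, in both sign
#' conventions: `nwu_left` treats the left window as the candidate
#' ischemic region A (positive where the left side is hypodense), and
#' `nwu_right` the converse. Values are defined only where both pooled
#' fields are valid and the respective denominator is positive, and are
#' clipped to a configured range.
#'
#' @param left_pooled,right_pooled `pooled_field` objects on the same grid
#'   (left hemisphere and warped mirrored right hemisphere).
#' @param clip length-2 clipping range in percent.
#' @return Object of class `nwu_map`: arrays `nwu_left`, `nwu_right`,
#'   logical validity arrays `valid_left`, `valid_right`, their
#'   intersection `valid`, and grid metadata.
#' @export
compute_nwu_map <- function(left_pooled, right_pooled, clip = c(-30, 30)) {
  if (!inherits(left_pooled, "pooled_field") ||
      !inherits(right_pooled, "pooled_field"))
    stop("compute_nwu_map: need pooled_field inputs")
  if (!identical(dim(left_pooled$mean), dim(right_pooled$mean)))
    stop("compute_nwu_map: pooled fields are on different grids")
  L <- left_pooled$mean
  R <- right_pooled$mean
  both <- left_pooled$valid & right_pooled$valid
  valid_left <- both & !is.na(R) & R > 0    # denominator = right
  valid_right <- both & !is.na(L) & L > 0   # denominator = left
  if (!any(valid_left) && !any(valid_right))
    stop("compute_nwu_map: no voxel with joint validity")
  nl <- array(NA_real_, dim(L))
  nr <- array(NA_real_, dim(L))
  nl[valid_left] <- pmin(pmax((1 - L[valid_left] / R[valid_left]) * 100,
                              clip[1]), clip[2])
  nr[valid_right] <- pmin(pmax((1 - R[valid_right] / L[valid_right]) * 100,
                               clip[1]), clip[2])
  structure(list(nwu_left = nl, nwu_right = nr,
                 valid_left = valid_left, valid_right = valid_right,
                 valid = valid_left & valid_right, clip = clip,
                 spacing = left_pooled$spacing, origin = left_pooled$origin),
            class = "nwu_map")
}

#' @export
print.nwu_map <- function(x, ...) {
  cat(sprintf("<nwu_map> %s, %d valid voxels\n",
              paste(dim(x$nwu_left), collapse = " x "), sum(x$valid)))
  if (any(x$valid))
    cat(sprintf("  left-as-A NWU range [%.2f, %.2f] %%\n",
                min(x$nwu_left[x$valid_left]), max(x$nwu_left[x$valid_left])))
  invisible(x)
}
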