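#' Otsu threshold of a value collection
#'
#' Histogram-based threshold maximising the between-class variance over
#' 256 bins spanning the observed range. Returns the bin edge separating
#' the two classes; invariant to duplicating the data (only proportions
#' matter).
#'
#' @param values numeric vector (e.g. positive NWU percentages).
#' @param bins histogram resolution (default 256).
#' @return The threshold (a bin edge) in the units of `values`.
#' @export
otsu_threshold <- function(values, bins = 256) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2)
    stop("otsu_threshold: need at least two distinct values (degenerate histogram)")
  lo <- min(v); hi <- max(v)
  edges <- seq(lo, hi, length.out = bins + 1)
  idx <- pmin(bins, pmax(1L, findInterval(v, edges, rightmost.closed = TRUE)))
  counts <- tabulate(idx, nbins = bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  w0 <- cumsum(p)[-bins]
  mu0 <- cumsum(p * mids)[-bins]
  mu_t <- sum(p * mids)
  denom <- w0 * (1 - w0)
  sigma_b2 <- ifelse(denom > 0, (mu_t * w0 - mu0)^2 / denom, -Inf)
  # well-separated classes give a plateau of equally optimal edges across
  # the empty gap; the plateau midpoint is returned (classic convention)
  best <- max(sigma_b2)
  k <- which(sigma_b2 >= best - 1e-12 * max(best, 1))
  mean(edges[k + 1])
}

ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

#' Largest connected component of a binary mask
#'
#' Under 6- or 26-connectivity. Ties in component size are broken
#' deterministically in favour of the component containing the smallest
#' linear voxel index. An empty input yields an empty output.
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6 or 26.
#' @return A [binary_mask()] containing only the largest component.
#' @export
largest_connected_component <- function(mask, connectivity = 26) {
  if (!is_binary_mask(mask)) stop("largest_connected_component: need a binary_mask")
  if (!connectivity %in% c(6, 26))
    stop("largest_connected_component: connectivity must be 6 or 26")
  if (sum(mask$values) == 0) return(mask)
  labels <- cpp_label_components(as.integer(mask$values),
                                 as.integer(vol_dim(mask)),
                                 as.integer(connectivity))
  sizes <- tabulate(labels)
  # labels are assigned in scan order, so which.max's first-maximum rule
  # realises the smallest-minimum-index tie-break
  best <- which.max(sizes)
  binary_mask(array(labels == best, vol_dim(mask)), mask$spacing, mask$origin)
}

count_components <- function(vals, dim3, connectivity = 26) {
  if (!any(vals != 0)) return(0L)
  max(cpp_label_components(as.integer(vals), as.integer(dim3),
                           as.integer(connectivity)))
}

#' Binary erosion/dilation with a ball structuring element
#'
#' @param mask a [binary_mask()].
#' @param radius ball radius in voxels.
#' @param op `"erode"` or `"dilate"`.
#' @return The transformed [binary_mask()].
#' @export
morph_ball <- function(mask, radius, op = c("erode", "dilate")) {
  op <- match.arg(op)
  if (radius <= 0) return(mask)
  offs <- ball_offsets(radius)
  out <- cpp_binary_morph(as.integer(mask$values), as.integer(vol_dim(mask)),
                          offs, op == "erode")
  binary_mask(array(out != 0, vol_dim(mask)), mask$spacing, mask$origin)
}

#' Fill enclosed cavities in a binary mask
#'
#' Background voxels not 6-connected to the volume border become
#' foreground (interior flood fill).
#'
#' @param mask a [binary_mask()].
#' @return The filled [binary_mask()].
#' @export
fill_holes <- function(mask) {
  out <- cpp_fill_holes(as.integer(mask$values), as.integer(vol_dim(mask)))
  binary_mask(array(out != 0, vol_dim(mask)), mask$spacing, mask$origin)
}

#' Extract the lesion mask from an NWU map
#'
#' Pools the positive valid NWU values of both sign conventions, derives
#' an Otsu threshold, and keeps voxels at or above
#' `max(otsu, lower_cutoff)` on the side whose candidate is larger. The
#' candidate is reduced to its largest connected component, refined by
#' ball erosion then dilation, restricted again to a single component, and
#' interior-flood-filled. Candidates below the minimum reportable volume
#' give an empty mask ("no lesion") — an empty result is a valid outcome,
#' not an error.
#'
#' @param nwu an `nwu_map` from [compute_nwu_map()].
#' @param config lesion section of [nwu_config()]: `lower_cutoff` (%),
#'   `erosion_radius`, `dilation_radius` (voxels), `connectivity`,
#'   `min_volume_ml`.
#' @return Object of class `lesion_candidate`: `mask` (hemisphere-grid
#'   [binary_mask()]), `side` ("left"/"right"/"none"), `otsu_threshold`
#'   (NA when degenerate), `threshold` actually applied, and
#'   `component_count` of the thresholded candidate.
#' @export
extract_lesion_mask <- function(nwu, config = nwu_config()$lesion) {
  if (!inherits(nwu, "nwu_map")) stop("extract_lesion_mask: need an nwu_map")
  cfg <- utils::modifyList(nwu_config()$lesion, as.list(config))
  d <- dim(nwu$nwu_left)
  if (!any(nwu$valid_left) && !any(nwu$valid_right))
    stop("extract_lesion_mask: NWU map has no valid voxel")
  empty <- function(otsu = NA_real_, thr = NA_real_, ncomp = 0L) {
    structure(list(mask = binary_mask(array(FALSE, d), nwu$spacing, nwu$origin),
                   side = "none", otsu_threshold = otsu, threshold = thr,
                   component_count = ncomp),
              class = "lesion_candidate")
  }
  pos <- c(nwu$nwu_left[nwu$valid_left & !is.na(nwu$nwu_left) & nwu$nwu_left > 0],
           nwu$nwu_right[nwu$valid_right & !is.na(nwu$nwu_right) & nwu$nwu_right > 0])
  if (length(pos) < 2) return(empty())
  # the lower cutoff removes the (large) background-noise class before
  # Otsu separates lesion plateau from boundary skirt; otherwise the
  # noise class dominates the histogram and drags the threshold into the
  # skirt, inflating the candidate and diluting the total NWU
  fg <- pos[pos >= cfg$lower_cutoff]
  if (length(fg) == 0) return(empty())
  otsu <- tryCatch(otsu_threshold(fg), error = function(e) NA_real_)
  if (is.na(otsu)) return(empty(thr = cfg$lower_cutoff))
  thr <- max(otsu, cfg$lower_cutoff)
  cand_left <- nwu$valid_left & !is.na(nwu$nwu_left) & nwu$nwu_left >= thr
  cand_right <- nwu$valid_right & !is.na(nwu$nwu_right) & nwu$nwu_right >= thr
  if (!any(cand_left) && !any(cand_right)) return(empty(otsu, thr))
  side <- if (sum(cand_left) >= sum(cand_right)) "left" else "right"
  cand <- if (side == "left") cand_left else cand_right
  ncomp <- count_components(cand, d, cfg$connectivity)
  m <- binary_mask(array(cand, d), nwu$spacing, nwu$origin)
  m <- largest_connected_component(m, cfg$connectivity)
  m <- morph_ball(m, cfg$erosion_radius, "erode")
  if (sum(m$values) == 0) return(empty(otsu, thr, ncomp))
  m <- morph_ball(m, cfg$dilation_radius, "dilate")
  m <- largest_connected_component(m, cfg$connectivity)
  m <- fill_holes(m)
  if (mask_volume_ml(m) < cfg$min_volume_ml) return(empty(otsu, thr, ncomp))
  structure(list(mask = m, side = side, otsu_threshold = otsu, threshold = thr,
                 component_count = ncomp),
            class = "lesion_candidate")
}

#' Final lesion report: side, volume and total NWU
#'
#' Computes the total NWU of the extracted lesion by the NWU formula: A is
#' the mean HU over the lesion in the affected hemisphere, B the mean HU
#' over the corresponding contralateral voxels (mirror plus deformable
#' correspondence, i.e. the warped mirrored hemisphere). For an empty
#' lesion the side is "none", the volume 0, and the NWU undefined (NA).
#'
#' @param pair the `hemisphere_pair` of the aligned volume.
#' @param right_warped the mirrored right hemisphere warped onto the left
#'   ([ct_volume()]), as used for pooling.
#' @param lesion a `lesion_candidate` from [extract_lesion_mask()].
#' @return Object of class `lesion_result`: `side`, `volume_ml`,
#'   `nwu_total`, `otsu_threshold`, `component_count`, `mask`
#'   (hemisphere grid), `mean_hu_lesion`, `mean_hu_contralateral`.
#' @export
lesion_report <- function(pair, right_warped, lesion) {
  if (!inherits(lesion, "lesion_candidate"))
    stop("lesion_report: need a lesion_candidate")
  m <- lesion$mask$values != 0
  if (!any(m)) {
    return(structure(list(side = "none", volume_ml = 0, nwu_total = NA_real_,
                          otsu_threshold = lesion$otsu_threshold,
                          component_count = lesion$component_count,
                          mask = lesion$mask,
                          mean_hu_lesion = NA_real_,
                          mean_hu_contralateral = NA_real_),
                     class = "lesion_result"))
  }
  left_vals <- pair$left$values[m]
  right_vals <- right_warped$values[m]
  if (lesion$side == "left") {
    a <- mean(left_vals); b <- mean(right_vals)
  } else {
    a <- mean(right_vals); b <- mean(left_vals)
  }
  if (!is.finite(b) || b <= 0)
    stop("lesion_report: contralateral region empty or non-positive after mapping")
  structure(list(side = lesion$side,
                 volume_ml = mask_volume_ml(lesion$mask),
                 nwu_total = nwu_scalar(a, b),
                 otsu_threshold = lesion$otsu_threshold,
                 component_count = lesion$component_count,
                 mask = lesion$mask,
                 mean_hu_lesion = a, mean_hu_contralateral = b),
            class = "lesion_result")
}

#' @export
print.lesion_result <- function(x, ...) {
  if (x$side == "none") {
    cat("<lesion_result> no lesion detected\n")
  } else {
    cat(sprintf("<lesion_result> side %s, volume %.1f mL, total NWU %.2f %%\n",
                x$side, x$volume_ml, x$nwu_total))
  }
  invisible(x)
}
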