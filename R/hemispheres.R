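#' Mirror a volume about its central sagittal plane
#'
#' Reverses the left-right (first) axis. An exact involution:
#' `mirror_volume(mirror_volume(x))` is identical to `x`.
#'
#' @param vol a [ct_volume()] or [binary_mask()].
#' @return Object of the same class, mirrored.
#' @export
mirror_volume <- function(vol) {
  d <- vol_dim(vol)
  v <- vol$values[d[1]:1, , , drop = FALSE]
  if (is_binary_mask(vol)) binary_mask(v != 0, vol$spacing, vol$origin)
  else ct_volume(v, vol$spacing, vol$origin)
}

#' Split an aligned volume into hemispheres and mirror one
#'
#' Splits along the mid-sagittal plane of the (template-aligned) grid: the
#' lower half of the first axis is the "left" hemisphere, the upper half
#' the "right", which is reflected about the midplane so both share the
#' same grid and voxel (i,j,k) in `left` faces voxel (i,j,k) in
#' `right_mirrored`. For an odd-sized split axis the central slice is
#' excluded from both hemispheres, so no midline structure is counted
#' twice; no other voxel is lost or duplicated.
#'
#' @param aligned a template-aligned [ct_volume()].
#' @return An object of class `hemisphere_pair` with elements `left`,
#'   `right_mirrored` (both [ct_volume()] on identical grids), `midplane`
#'   (index of the excluded central slice, or the half-integer boundary for
#'   an even axis), and `n_x` (original first-axis size).
#' @export
split_and_mirror <- function(aligned) {
  if (!is_ct_volume(aligned)) stop("split_and_mirror: need a ct_volume")
  d <- vol_dim(aligned)
  nx <- d[1]
  half <- nx %/% 2L
  if (half < 4L) stop("split_and_mirror: volume too thin along the split axis")
  left_vals <- aligned$values[seq_len(half), , , drop = FALSE]
  right_idx <- seq.int(nx - half + 1L, nx)
  right_vals <- aligned$values[right_idx, , , drop = FALSE]
  right_mirrored <- right_vals[half:1, , , drop = FALSE]
  left <- ct_volume(left_vals, aligned$spacing, aligned$origin)
  rightm <- ct_volume(right_mirrored, aligned$spacing, aligned$origin)
  structure(list(left = left, right_mirrored = rightm,
                 midplane = if (nx %% 2L == 0L) half + 0.5 else half + 1L,
                 n_x = nx, spacing = aligned$spacing, origin = aligned$origin),
            class = "hemisphere_pair")
}

#' @export
print.hemisphere_pair <- function(x, ...) {
  d <- vol_dim(x$left)
  cat(sprintf("<hemisphere_pair> %d x %d x %d per hemisphere (split axis %d%s)\n",
              d[1], d[2], d[3], x$n_x,
              if (x$n_x %% 2L) ", central slice excluded" else ""))
  invisible(x)
}

# Place a hemisphere-grid mask back into the full aligned grid.
# `side` is "left" or "right"; for the right side the mask is reflected
# back across the midplane. `field`, when given, is first used to undo the
# hemisphere deformation with a first-order inverse (mask warped by the
# negated field, nearest-neighbour).
hemisphere_mask_to_full <- function(mask_vals, pair, side, field = NULL) {
  half <- dim(mask_vals)[1]
  nx <- pair$n_x
  full <- array(0L, dim = c(nx, dim(mask_vals)[2:3]))
  m <- mask_vals
  if (side == "right") {
    if (!is.null(field)) {
      w <- cpp_warp(as.numeric(m), as.integer(dim(m)), pair$spacing,
                    -as.numeric(field$ux), -as.numeric(field$uy),
                    -as.numeric(field$uz), FALSE, 0)
      m <- array(as.integer(w != 0), dim = dim(m))
    }
    full[seq.int(nx - half + 1L, nx), , ] <- m[half:1, , , drop = FALSE]
  } else {
    full[seq_len(half), , ] <- m
  }
  full
}

# Extract the hemisphere-frame view of a full-grid mask for a given side
# ("left": lower half as is; "right": upper half mirrored). `field`, when
# given, maps the right-side view into the left hemisphere's anatomy
# (nearest-neighbour forward warp, matching the warped right hemisphere).
full_mask_to_hemisphere <- function(full_vals, pair, side, field = NULL) {
  nx <- pair$n_x
  half <- nx %/% 2L
  if (side == "right") {
    m <- full_vals[seq.int(nx - half + 1L, nx), , , drop = FALSE][half:1, , ,
                                                                  drop = FALSE]
    if (!is.null(field)) {
      w <- cpp_warp(as.numeric(m), as.integer(dim(m)), pair$spacing,
                    as.numeric(field$ux), as.numeric(field$uy),
                    as.numeric(field$uz), FALSE, 0)
      m <- array(as.integer(w != 0), dim = dim(m))
    }
    m
  } else {
    full_vals[seq_len(half), , , drop = FALSE]
  }
}
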