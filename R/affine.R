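#' Affine world-coordinate transform
#'
#' Represents `x_fixed = A %*% x_moving + t` in world mm, the convention
#' used for template alignment: the transform maps moving-image world
#' coordinates into the fixed (template) frame.
#'
#' @param A 3x3 linear part (invertible).
#' @param t length-3 translation in mm.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(A = diag(3), t = c(0, 0, 0)) {
  A <- matrix(as.numeric(A), 3, 3)
  t <- as.numeric(t)
  if (length(t) != 3L || anyNA(A) || anyNA(t))
    stop("affine_transform: invalid A or t")
  if (abs(det(A)) < 1e-8)
    stop("affine_transform: linear part is (near-)singular")
  structure(list(A = A, t = t), class = "affine_transform")
}

#' Identity affine transform
#' @return An [affine_transform()] with `A = I`, `t = 0`.
#' @export
affine_identity <- function() affine_transform(diag(3), c(0, 0, 0))

#' Apply an affine transform to points
#'
#' @param tf an [affine_transform()].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of transformed coordinates.
#' @export
affine_apply <- function(tf, pts) {
  pts <- matrix(pts, ncol = 3)
  t(tf$A %*% t(pts) + tf$t)
}

#' Compose two affine transforms
#'
#' `affine_compose(a, b)` returns the transform applying `b` first, then
#' `a`.
#'
#' @param a,b [affine_transform()] objects.
#' @return The composed [affine_transform()].
#' @export
affine_compose <- function(a, b) {
  affine_transform(a$A %*% b$A, as.numeric(a$A %*% b$t) + a$t)
}

#' Invert an affine transform
#' @param tf an [affine_transform()].
#' @return The inverse [affine_transform()].
#' @export
affine_invert <- function(tf) {
  Ai <- solve(tf$A)
  affine_transform(Ai, -as.numeric(Ai %*% tf$t))
}

#' Build a rigid (or similarity) transform from parameters
#'
#' Euler angles in degrees (applied as Rz Ry Rx), translation in mm, and an
#' optional isotropic scale, rotating about a given centre:
#' `x' = s * R (x - c) + c + t`.
#'
#' @param angles_deg length-3 rotation angles about x, y, z in degrees.
#' @param translation_mm length-3 translation in mm.
#' @param center_mm rotation centre in world mm.
#' @param scale isotropic scale factor (default 1).
#' @return An [affine_transform()].
#' @export
rigid_transform <- function(angles_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0), scale = 1) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  A <- scale * (Rz %*% Ry %*% Rx)
  t <- as.numeric(center_mm + translation_mm - A %*% center_mm)
  affine_transform(A, t)
}

#' Write an affine transform as a plain-text 4x4 matrix
#' @param tf an [affine_transform()].
#' @param path output text file.
#' @return Invisibly, `path`.
#' @export
write_affine <- function(tf, path) {
  m <- rbind(cbind(tf$A, tf$t), c(0, 0, 0, 1))
  utils::write.table(format(m, digits = 17), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an affine transform from a plain-text 4x4 matrix
#' @param path text file written by [write_affine()].
#' @return An [affine_transform()].
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (!all(dim(m) == c(4, 4)))
    stop("read_affine: expected a 4x4 matrix")
  affine_transform(m[1:3, 1:3], m[1:3, 4])
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> x_fixed = A x_moving + t\n")
  m <- rbind(cbind(x$A, x$t), c(0, 0, 0, 1))
  print(round(m, 6))
  invisible(x)
}

#' Resample a volume through an affine transform
#'
#' Samples `vol` onto `grid` (a `ct_volume`/`binary_mask` supplying the
#' output geometry), treating `tf` as the moving-to-fixed map: the output
#' at fixed-grid location `x` is `vol` evaluated at `tf^{-1}(x)`.
#'
#' @param vol moving [ct_volume()] or [binary_mask()].
#' @param tf an [affine_transform()] (moving to fixed).
#' @param grid object supplying output dims/spacing/origin.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill background fill value.
#' @return Resampled object of the same class as `vol`.
#' @export
apply_affine <- function(vol, tf, grid,
                         interpolation = c("linear", "nearest"),
                         fill = NULL) {
  interpolation <- match.arg(interpolation)
  is_mask <- is_binary_mask(vol)
  if (is_mask) interpolation <- "nearest"
  if (is.null(fill)) fill <- if (is_mask) 0 else -1000
  inv <- affine_invert(tf)
  out <- cpp_resample_affine(
    as.numeric(vol$values), as.integer(vol_dim(vol)),
    as.integer(vol_dim(grid)), inv$A, inv$t,
    vol$spacing, vol$origin, grid$spacing, grid$origin,
    interpolation == "linear", fill)
  arr <- array(out, dim = vol_dim(grid))
  if (is_mask)
    binary_mask(arr != 0, spacing = grid$spacing, origin = grid$origin)
  else
    ct_volume(arr, spacing = grid$spacing, origin = grid$origin)
}

#' Map a binary mask through an affine transform
#'
#' Nearest-neighbour resampling of a reference mask into a target grid,
#' used to carry reference lesion masks into the aligned frame.
#'
#' @param mask a [binary_mask()].
#' @param tf [affine_transform()] mapping the mask's world frame to the
#'   target frame.
#' @param grid object supplying the target grid geometry.
#' @return A [binary_mask()] on `grid`.
#' @export
map_mask_affine <- function(mask, tf, grid) {
  if (!is_binary_mask(mask)) stop("map_mask_affine: `mask` must be a binary_mask")
  apply_affine(mask, tf, grid, interpolation = "nearest", fill = 0)
}
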