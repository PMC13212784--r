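#' Read a NIfTI scalar volume
#'
#' Loads a 3D NIfTI file, reorients it to the canonical axis convention
#' (first axis left-right, third axis through the axial slices, RAS-like),
#' and returns a [ct_volume()] with spacing and origin taken from the
#' header. Voxel values are unchanged apart from storage as double.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_volume: file not found: %s", path))
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop(sprintf("read_volume: cannot read '%s' as NIfTI: %s",
                                 path, conditionMessage(e))))
  # canonical orientation so the left-right axis is always the first axis;
  # images without any xform stay as stored
  suppressWarnings(
    tryCatch(RNifti::orientation(img) <- "RAS", error = function(e) NULL))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), dim = d[1:3])
  } else if (length(d) != 3L) {
    stop(sprintf("read_volume: expected a 3D scalar volume, got %s dims",
                 length(d)))
  } else {
    img2 <- array(as.numeric(img), dim = d)
  }
  if (anyNA(img2) || any(!is.finite(img2)))
    stop("read_volume: volume contains non-finite values")
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  ct_volume(img2, spacing = sp, origin = origin)
}

#' Read a binary mask from NIfTI
#'
#' Like [read_volume()] but validates and stores the result as a
#' [binary_mask()]. Any value above 0.5 is foreground.
#'
#' @inheritParams read_volume
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$values > 0.5, spacing = v$spacing, origin = v$origin)
}

#' Write a volume or mask to NIfTI
#'
#' HU volumes are written as 32-bit float, masks as unsigned 8-bit. The
#' affine encodes the axis-aligned spacing and origin.
#'
#' @param vol a [ct_volume()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`); parent must be writable.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path)))
    stop(sprintf("write_volume: directory does not exist: %s", dirname(path)))
  is_mask <- is_binary_mask(vol)
  dtype <- if (is_mask) "uint8" else "float"
  vals <- vol$values
  attr(vals, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(vals, datatype = dtype)
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(vol$spacing)
  aff[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  ok <- tryCatch({
    RNifti::writeNifti(img, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop(sprintf("write_volume: could not write '%s'", path))
  invisible(path)
}

#' Resample a volume onto an isotropic grid
#'
#' Resamples onto a grid with equal spacing along all axes, preserving the
#' physical extent to within one target voxel per axis. HU volumes use
#' trilinear interpolation, masks must use nearest-neighbour.
#'
#' @param vol a [ct_volume()] or [binary_mask()].
#' @param target_spacing isotropic target spacing in mm (> 0); default 1.
#' @param interpolation `"linear"` (HU) or `"nearest"` (masks).
#' @param fill value for voxels outside the source extent (default -1000,
#'   air, for HU volumes; 0 for masks).
#' @return Object of the same class as `vol` on the isotropic grid.
#' @export
resample_isotropic <- function(vol, target_spacing = 1,
                               interpolation = c("linear", "nearest"),
                               fill = NULL) {
  interpolation <- match.arg(interpolation)
  if (!is.numeric(target_spacing) || length(target_spacing) != 1L ||
      !is.finite(target_spacing) || target_spacing <= 0)
    stop("resample_isotropic: target_spacing must be a positive number")
  is_mask <- is_binary_mask(vol)
  if (is_mask && interpolation != "nearest")
    stop("resample_isotropic: masks must be resampled with nearest interpolation")
  if (is.null(fill)) fill <- if (is_mask) 0 else -1000
  d <- vol_dim(vol)
  extent <- d * vol$spacing
  d_out <- pmax(1L, as.integer(round(extent / target_spacing)))
  out <- cpp_resample_affine(
    as.numeric(vol$values), as.integer(d), as.integer(d_out),
    diag(3), c(0, 0, 0),
    vol$spacing, vol$origin,
    rep(target_spacing, 3), vol$origin,
    interpolation == "linear", fill)
  arr <- array(out, dim = d_out)
  if (any(d_out < 8L))
    warning("resample_isotropic: resampled volume has fewer than 8 voxels along an axis")
  if (is_mask)
    binary_mask(arr != 0, spacing = rep(target_spacing, 3), origin = vol$origin)
  else
    ct_volume(arr, spacing = rep(target_spacing, 3), origin = vol$origin)
}
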