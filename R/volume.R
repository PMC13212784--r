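#' 3D CT volume container
#'
#' Holds a 3D grid of Hounsfield-unit values together with its geometry:
#' voxel spacing in mm and the world coordinates of the first voxel. All
#' geometric operations in the package assume a right-handed, axis-aligned
#' grid with axial slices along the third axis and the left-right direction
#' along the first axis (the canonical orientation enforced at load time).
#'
#' @param values 3D numeric array of HU values (stored as double).
#' @param spacing numeric length-3, voxel spacing in mm (strictly positive).
#' @param origin numeric length-3, world coordinates (mm) of voxel (1,1,1).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("ct_volume: `values` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("ct_volume: spacing must be three strictly positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("ct_volume: origin must be three finite numbers")
  if (anyNA(values) || any(!is.finite(values)))
    stop("ct_volume: values contain NA/NaN/Inf")
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' Binary mask on a CT grid
#'
#' A {0,1}-valued companion to a [ct_volume()], sharing its grid metadata.
#'
#' @param values 3D array coercible to 0/1 (logical or numeric).
#' @inheritParams ct_volume
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("binary_mask: `values` must be a 3D array")
  v <- values
  if (is.logical(v)) {
    storage.mode(v) <- "integer"
  } else {
    if (anyNA(v) || !all(v %in% c(0, 1)))
      stop("binary_mask: values must be 0/1")
    storage.mode(v) <- "integer"
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("binary_mask: spacing must be three strictly positive numbers")
  structure(list(values = v, spacing = spacing, origin = origin),
            class = "binary_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%.1f, %.1f, %.1f) mm\n",
              min(x$values), max(x$values),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %d foreground (%.2f mL)\n",
              d[1], d[2], d[3], sum(x$values),
              sum(x$values) * prod(x$spacing) / 1000))
  invisible(x)
}

vol_dim <- function(x) dim(x$values)

is_ct_volume <- function(x) inherits(x, "ct_volume")
is_binary_mask <- function(x) inherits(x, "binary_mask")

#' Check that two volumes/masks share a grid
#'
#' @param a,b `ct_volume` or `binary_mask` objects.
#' @param tol tolerance on spacing/origin agreement in mm.
#' @return `TRUE` or `FALSE`.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "operands") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch: %s must share dimensions, spacing and origin",
                 what))
  invisible(TRUE)
}

#' Mask volume in mL
#'
#' @param mask a `binary_mask`.
#' @return Volume of the foreground in millilitres.
#' @export
mask_volume_ml <- function(mask) {
  sum(mask$values) * prod(mask$spacing) / 1000
}

# Evaluate an expression with a temporarily fixed RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
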