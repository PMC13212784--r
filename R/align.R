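#' Affine alignment of an NCCT volume to a symmetric template
#'
#' Multi-resolution intensity-based registration standing in for AC-PC /
#' atlas alignment: the moving NCCT is registered to a left-right symmetric
#' template so that the mid-sagittal plane of the template becomes the
#' hemisphere split plane. The optimiser is Nelder-Mead over rigid (or
#' rigid-plus-scale) parameters; the metric is mean squared error by
#' default (mono-modal CT-to-CT), with a mutual-information option.
#'
#' @param vol moving [ct_volume()], isotropic (1 mm) spacing.
#' @param template fixed [ct_volume()], isotropic, left-right symmetric
#'   about its central sagittal plane.
#' @param config registration section of [nwu_config()]; recognised keys:
#'   `metric` ("mse"/"mi"), `dof` ("rigid"/"similarity"), `shrink`
#'   (integer vector of coarse-to-fine shrink factors), `max_iter`
#'   (optimiser iterations per level), `fg_threshold` (HU above which a
#'   template voxel counts as head foreground), `min_overlap` (minimum
#'   fraction of foreground that must sample inside the moving volume).
#' @return List with `aligned` (the moving volume resampled onto the
#'   template grid), `transform` (an [affine_transform()] mapping moving
#'   world coordinates into the template frame), and `metric` values at
#'   identity and at the optimum.
#' @export
align_to_template <- function(vol, template, config = nwu_config()$registration) {
  if (!is_ct_volume(vol) || !is_ct_volume(template))
    stop("align_to_template: vol and template must be ct_volume objects")
  cfg <- utils::modifyList(nwu_config()$registration, as.list(config))
  if (max(abs(vol$spacing - vol$spacing[1])) > 1e-6 ||
      max(abs(template$spacing - template$spacing[1])) > 1e-6)
    stop("align_to_template: both volumes must be isotropic; resample first")

  center <- template$origin + (vol_dim(template) - 1) / 2 * template$spacing
  n_par <- switch(cfg$dof, rigid = 6L, similarity = 7L,
                  stop("align_to_template: dof must be 'rigid' or 'similarity'"))

  par_to_tf <- function(p) {
    s <- if (n_par == 7L) exp(p[7]) else 1
    # parameters describe the fixed-to-moving resampling map; the reported
    # moving-to-fixed transform is its inverse
    rigid_transform(p[1:3], p[4:6], center_mm = center, scale = s)
  }

  metric_fun <- function(fx, mv, cfg) {
    fgmask <- fx$values > cfg$fg_threshold
    nfg <- sum(fgmask)
    if (nfg == 0) stop("align_to_template: template has no foreground voxels")
    idx <- which(fgmask, arr.ind = TRUE)
    pts <- sweep(sweep(idx - 1, 2, fx$spacing, "*"), 2, fx$origin, "+")
    storage.mode(pts) <- "double"
    fvals <- fx$values[fgmask]
    function(p) {
      tf <- par_to_tf(p)
      samp <- cpp_sample_points(as.numeric(mv$values), as.integer(vol_dim(mv)),
                                mv$spacing, mv$origin, tf$A, tf$t, pts)
      inside <- !is.na(samp)
      if (sum(inside) < cfg$min_overlap * nfg) return(Inf)
      if (cfg$metric == "mse") {
        mean((fvals[inside] - samp[inside])^2)
      } else {
        -mutual_information(fvals[inside], samp[inside])
      }
    }
  }

  p <- rep(0, n_par)
  id_metric <- NA_real_
  final <- NA_real_
  shrinks <- sort(cfg$shrink, decreasing = TRUE)
  for (li in seq_along(shrinks)) {
    shrink <- shrinks[li]
    sp <- template$spacing[1] * shrink
    fx <- if (shrink > 1) downsample_volume(template, sp) else template
    mv <- if (shrink > 1) downsample_volume(vol, sp) else vol
    f <- metric_fun(fx, mv, cfg)
    if (is.na(id_metric)) {
      id_metric <- f(rep(0, n_par))
      if (!is.finite(id_metric))
        stop("align_to_template: empty overlap between volume and template")
    }
    maxit <- cfg$max_iter[min(li, length(cfg$max_iter))]
    best <- f(p)
    # a fresh simplex from the current optimum guards against premature
    # Nelder-Mead collapse; restarts run at the coarse levels only (cheap)
    # while the finest level is a single polish pass
    n_starts <- if (li < length(shrinks)) 2 else 1
    for (rs in seq_len(n_starts)) {
      opt <- stats::optim(p, f, method = "Nelder-Mead",
                          control = list(maxit = maxit,
                                         reltol = 1e-7,
                                         parscale = c(rep(1, 3), rep(1, 3),
                                                      rep(0.05, n_par - 6L))))
      if (is.finite(opt$value) && opt$value < best) {
        improved <- best - opt$value > 1e-4 * max(best, 1e-12)
        p <- opt$par
        best <- opt$value
        if (!improved) break
      } else break
    }
    final <- best
  }
  if (!is.finite(final))
    stop(sprintf("align_to_template: registration failed to converge (metric %g)",
                 final))
  resample_tf <- par_to_tf(p)          # fixed world -> moving world
  moving_to_fixed <- affine_invert(resample_tf)
  aligned <- apply_affine(vol, moving_to_fixed, template,
                          interpolation = "linear", fill = -1000)
  list(aligned = aligned, transform = moving_to_fixed,
       metric = c(identity = id_metric, final = final),
       parameters = p)
}

# Smooth-then-subsample to a coarser isotropic grid (anti-aliased).
downsample_volume <- function(vol, target_spacing) {
  sig <- rep(0.5 * target_spacing / vol$spacing[1], 3)
  sm <- cpp_gaussian_smooth(as.numeric(vol$values), as.integer(vol_dim(vol)), sig)
  smv <- ct_volume(array(sm, vol_dim(vol)), vol$spacing, vol$origin)
  # coarse pyramid levels may legitimately drop below the degenerate-size
  # warning threshold of the public resampler
  suppressWarnings(resample_isotropic(smv, target_spacing, "linear"))
}

# Histogram-based mutual information between two intensity samples.
mutual_information <- function(x, y, bins = 32) {
  rx <- range(x); ry <- range(y)
  if (diff(rx) == 0 || diff(ry) == 0) return(0)
  ix <- pmin(bins, 1L + floor((x - rx[1]) / diff(rx) * bins))
  iy <- pmin(bins, 1L + floor((y - ry[1]) / diff(ry) * bins))
  joint <- tabulate(ix + bins * (iy - 1L), nbins = bins * bins)
  p <- joint / sum(joint)
  px <- rowSums(matrix(p, bins, bins))
  py <- colSums(matrix(p, bins, bins))
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (outer(px, py)[nz])))
}
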