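#' Synthetic NCCT head phantom specification
#'
#' Parameterises a digital head phantom: an ellipsoidal skull shell at bone
#' HU around brain parenchyma with smooth multiplicative texture (gray /
#' white matter contrast surrogate), a thin CSF gap, paired CSF-density
#' ventricles, and optionally a unilateral hypodense ellipsoidal lesion
#' whose density is a specified fraction below the local parenchyma — that
#' fraction is the ground-truth net water uptake. All geometry is bilaterally
#' symmetric about the mid-sagittal plane unless an asymmetry deformation is
#' requested, so the mirrored contralateral region of the lesion has, by
#' construction, exactly the pre-lesion density.
#'
#' @param dim grid dimensions in voxels.
#' @param spacing voxel spacing in mm.
#' @param brain_radii_mm semi-axes of the brain ellipsoid.
#' @param csf_gap_mm CSF gap between brain and skull.
#' @param skull_thickness_mm skull shell thickness.
#' @param skull_hu,brain_hu,csf_hu,ventricle_hu tissue densities (HU).
#' @param texture_amplitude relative amplitude of the smooth multiplicative
#'   parenchyma texture (0.05 = +/-5% HU).
#' @param texture_scale_mm spatial scale of the texture field.
#' @param ventricle_radii_mm,ventricle_center_mm paired ventricle geometry;
#'   the centre's first component is the lateral offset (mirrored).
#' @param lesion_center_mm lesion centre relative to head centre (negative
#'   first component = left hemisphere); `NULL` for no lesion.
#' @param lesion_radii_mm lesion ellipsoid semi-axes.
#' @param uptake_percent ground-truth NWU of the lesion, in [0, 30]; 0
#'   means no lesion is implanted.
#' @param edge_blur_mm Gaussian blur of the lesion boundary (0 = sharp;
#'   blurring trades the exact implanted density ratio for a more
#'   realistic subtle-hypoattenuation appearance).
#' @param noise_sd additive Gaussian HU noise standard deviation.
#' @param asymmetry_mm amplitude of a random smooth deformation breaking
#'   perfect bilateral symmetry (0 = exactly symmetric).
#' @param seed RNG seed; phantoms are bitwise reproducible per seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(120, 144, 104), spacing = c(1, 1, 1),
                         brain_radii_mm = c(50, 64, 42),
                         csf_gap_mm = 2, skull_thickness_mm = 5,
                         skull_hu = 1200, brain_hu = 35, csf_hu = 5,
                         ventricle_hu = 8,
                         texture_amplitude = 0.05, texture_scale_mm = 24,
                         ventricle_radii_mm = c(6, 15, 8),
                         ventricle_center_mm = c(10, 10, 2),
                         lesion_center_mm = NULL,
                         lesion_radii_mm = c(15, 15, 15),
                         uptake_percent = 0, edge_blur_mm = 0,
                         noise_sd = 0, asymmetry_mm = 0, seed = 1) {
  if (uptake_percent < 0 || uptake_percent > 30)
    stop("phantom_spec: uptake_percent must be in [0, 30]")
  if (noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0")
  if (asymmetry_mm < 0) stop("phantom_spec: asymmetry_mm must be >= 0")
  spec <- list(dim = as.integer(dim), spacing = as.numeric(spacing),
               brain_radii_mm = brain_radii_mm, csf_gap_mm = csf_gap_mm,
               skull_thickness_mm = skull_thickness_mm, skull_hu = skull_hu,
               brain_hu = brain_hu, csf_hu = csf_hu,
               ventricle_hu = ventricle_hu,
               texture_amplitude = texture_amplitude,
               texture_scale_mm = texture_scale_mm,
               ventricle_radii_mm = ventricle_radii_mm,
               ventricle_center_mm = ventricle_center_mm,
               lesion_center_mm = lesion_center_mm,
               lesion_radii_mm = lesion_radii_mm,
               uptake_percent = uptake_percent, edge_blur_mm = edge_blur_mm,
               noise_sd = noise_sd, asymmetry_mm = asymmetry_mm,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# Squared-normalised-distance field of an ellipsoid on centred coordinates.
ellipsoid_inside <- function(xc, yc, zc, center, radii) {
  dx2 <- ((xc - center[1]) / radii[1])^2
  dy2 <- ((yc - center[2]) / radii[2])^2
  dz2 <- ((zc - center[3]) / radii[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

# Smooth random field: white noise on a coarse grid, trilinearly upsampled,
# rescaled to unit maximum absolute value.
smooth_random_field <- function(dim3, spacing, scale_mm) {
  extent <- dim3 * spacing
  nc <- pmax(2L, as.integer(ceiling(extent / scale_mm)) + 1L)
  coarse <- array(stats::rnorm(prod(nc)), dim = nc)
  up <- cpp_resample_affine(as.numeric(coarse), nc, as.integer(dim3),
                            diag(3), c(0, 0, 0), rep(scale_mm, 3), c(0, 0, 0),
                            spacing, c(0, 0, 0), TRUE, 0)
  f <- array(up, dim3)
  f / max(abs(f), 1e-12)
}

#' Generate a phantom head from a specification
#'
#' Deterministic given the spec's seed. The lesion density is drawn as
#' `(1 - w/100)` times the local (textured) parenchyma HU before noise, so
#' with a sharp boundary, no noise and no asymmetry, the NWU formula
#' applied to the ground-truth mask and its mirror recovers the implanted
#' uptake exactly.
#'
#' @param spec a [phantom_spec()].
#' @return Object of class `phantom_case`: `ct` ([ct_volume()]),
#'   `gt_mask` ([binary_mask()]), `gt_nwu` (implanted uptake, %),
#'   `lesion_present`, and the `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("generate_phantom: need a phantom_spec")
  with_seed(spec$seed, {
    d <- spec$dim
    sp <- spec$spacing
    xc <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
    yc <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
    zc <- (seq_len(d[3]) - (d[3] + 1) / 2) * sp[3]
    ctr <- c(0, 0, 0)
    brain <- ellipsoid_inside(xc, yc, zc, ctr, spec$brain_radii_mm)
    mid_r <- spec$brain_radii_mm + spec$csf_gap_mm
    out_r <- mid_r + spec$skull_thickness_mm
    inside_mid <- ellipsoid_inside(xc, yc, zc, ctr, mid_r)
    inside_out <- ellipsoid_inside(xc, yc, zc, ctr, out_r)
    vc <- spec$ventricle_center_mm
    vent <- ellipsoid_inside(xc, yc, zc, c(vc[1], vc[2], vc[3]),
                             spec$ventricle_radii_mm) |
            ellipsoid_inside(xc, yc, zc, c(-vc[1], vc[2], vc[3]),
                             spec$ventricle_radii_mm)

    arr <- array(-1000, dim = d)
    arr[inside_out & !inside_mid] <- spec$skull_hu
    arr[inside_mid & !brain] <- spec$csf_hu

    tex <- smooth_random_field(d, sp, spec$texture_scale_mm)
    tex <- (tex + tex[d[1]:1, , , drop = FALSE]) / 2   # enforce symmetry
    tex <- tex / max(abs(tex), 1e-12)
    factor <- 1 + spec$texture_amplitude * tex
    arr[brain] <- spec$brain_hu * factor[brain]
    arr[vent] <- spec$ventricle_hu
    tissue <- brain & !vent

    gt <- array(FALSE, dim = d)
    lesion_present <- !is.null(spec$lesion_center_mm) && spec$uptake_percent > 0
    if (lesion_present) {
      lc <- spec$lesion_center_mm
      lr <- spec$lesion_radii_mm
      if (abs(lc[1]) - lr[1] < 0.5)
        stop("generate_phantom: lesion crosses the midplane")
      lv <- ellipsoid_inside(xc, yc, zc, lc, lr)
      if (any(lv & !brain))
        stop("generate_phantom: lesion extends outside the brain parenchyma")
      gt <- lv & tissue
      ind <- array(as.numeric(lv), dim = d)
      if (spec$edge_blur_mm > 0)
        ind <- array(cpp_gaussian_smooth(as.numeric(ind), as.integer(d),
                                         spec$edge_blur_mm / sp),
                     dim = d)
      lf <- 1 - spec$uptake_percent / 100 * ind
      arr[tissue] <- arr[tissue] * lf[tissue]
    }

    if (spec$asymmetry_mm > 0) {
      ux <- spec$asymmetry_mm * smooth_random_field(d, sp, 32)
      uy <- spec$asymmetry_mm * smooth_random_field(d, sp, 32)
      uz <- spec$asymmetry_mm * smooth_random_field(d, sp, 32)
      arr <- array(cpp_warp(as.numeric(arr), as.integer(d), sp,
                            as.numeric(ux), as.numeric(uy), as.numeric(uz),
                            TRUE, -1000), dim = d)
      gt <- array(cpp_warp(as.numeric(gt), as.integer(d), sp,
                           as.numeric(ux), as.numeric(uy), as.numeric(uz),
                           FALSE, 0) != 0, dim = d)
    }
    if (spec$noise_sd > 0)
      arr <- arr + array(stats::rnorm(prod(d), 0, spec$noise_sd), dim = d)

    structure(list(ct = ct_volume(arr, sp, c(0, 0, 0)),
                   gt_mask = binary_mask(gt, sp, c(0, 0, 0)),
                   gt_nwu = if (lesion_present) spec$uptake_percent else 0,
                   lesion_present = lesion_present,
                   spec = spec),
              class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s voxels, %s (seed %d)\n",
              paste(vol_dim(x$ct), collapse = " x "),
              if (x$lesion_present)
                sprintf("lesion %.1f mL at %.0f%% uptake",
                        mask_volume_ml(x$gt_mask), x$gt_nwu)
              else "no lesion",
              x$spec$seed))
  invisible(x)
}

#' Measured NWU of a phantom's ground-truth mask
#'
#' Applies the NWU formula directly to the generated volume: A is the mean
#' HU inside the ground-truth mask, B the mean over the mirrored mask.
#' Useful as an independent check of the implanted uptake.
#'
#' @param case a `phantom_case`.
#' @return Measured NWU in percent (NA when no lesion).
#' @export
phantom_measured_nwu <- function(case) {
  m <- case$gt_mask$values != 0
  if (!any(m)) return(NA_real_)
  d <- dim(m)
  mm <- m[d[1]:1, , , drop = FALSE]
  nwu_scalar(mean(case$ct$values[m]), mean(case$ct$values[mm]))
}

#' Sample a reproducible suite of phantom cases
#'
#' Draws lesion uptake, volume and noise level per case, places a feasible
#' lesion (fully inside the brain ellipsoid, strictly within one
#' hemisphere; bounded retries, error when infeasible), and generates the
#' phantoms. Uptake given as a length-2 vector is a uniform range;
#' longer vectors are discrete sets sampled with replacement (a drawn
#' uptake of 0 yields a lesion-absent case).
#'
#' @param n number of cases.
#' @param uptake uptake range or set, in percent.
#' @param volume_ml length-2 nominal lesion-volume range, in mL.
#' @param noise_sd length-2 noise range, HU.
#' @param edge_blur_mm lesion boundary blur passed to every case.
#' @param base_spec template [phantom_spec()] supplying geometry.
#' @param seed suite seed (fans out to per-case seeds).
#' @param max_retries placement retries per case before erroring.
#' @return Object of class `phantom_suite`: `cases` (list of
#'   `phantom_case`) and `table` (one row per case: seed, uptake, nominal
#'   and achieved volume, noise, side, lesion_present).
#' @export
phantom_suite <- function(n = 20, uptake = c(5, 20), volume_ml = c(2, 80),
                          noise_sd = c(0, 6), edge_blur_mm = 0,
                          base_spec = phantom_spec(), seed = 1,
                          max_retries = 200) {
  if (n < 1) stop("phantom_suite: n must be >= 1")
  with_seed(seed, {
    case_seeds <- sample.int(.Machine$integer.max - 1L, n)
    draws <- lapply(seq_len(n), function(i) {
      w <- if (length(uptake) == 2) stats::runif(1, min(uptake), max(uptake))
           else sample(uptake, 1)
      v <- stats::runif(1, min(volume_ml), max(volume_ml))
      ns <- stats::runif(1, min(noise_sd), max(noise_sd))
      list(w = w, v = v, ns = ns)
    })
    geom <- lapply(draws, function(dr) {
      if (dr$w <= 0) return(NULL)
      sample_lesion_geometry(dr$v, base_spec, max_retries)
    })
  })
  cases <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    dr <- draws[[i]]
    g <- geom[[i]]
    spec <- utils::modifyList(
      unclass(base_spec),
      list(uptake_percent = if (is.null(g)) 0 else dr$w,
           lesion_center_mm = if (is.null(g)) NULL else g$center,
           lesion_radii_mm = if (is.null(g)) base_spec$lesion_radii_mm else g$radii,
           noise_sd = dr$ns, edge_blur_mm = edge_blur_mm,
           seed = case_seeds[i]))
    class(spec) <- "phantom_spec"
    cases[[i]] <- generate_phantom(spec)
    rows[[i]] <- data.frame(
      id = i, seed = case_seeds[i],
      uptake = if (is.null(g)) 0 else dr$w,
      nominal_volume_ml = if (is.null(g)) 0 else dr$v,
      achieved_volume_ml = mask_volume_ml(cases[[i]]$gt_mask),
      noise_sd = dr$ns,
      side = if (is.null(g)) "none" else if (g$center[1] < 0) "left" else "right",
      lesion_present = !is.null(g))
  }
  structure(list(cases = cases, table = do.call(rbind, rows), seed = seed),
            class = "phantom_suite")
}

# Draw lesion radii and centre for a nominal volume, retrying until the
# ellipsoid fits inside the brain with margin and stays in one hemisphere.
sample_lesion_geometry <- function(volume_ml, base_spec, max_retries) {
  br <- base_spec$brain_radii_mm
  r0 <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
  u <- fibonacci_sphere(96)
  for (try in seq_len(max_retries)) {
    s1 <- stats::runif(1, 0.8, 1.2)
    s2 <- stats::runif(1, 0.8, 1.2)
    radii <- r0 * c(s1, s2, 1 / (s1 * s2))
    if (any(radii > 0.85 * br)) next
    lo <- radii[1] + 1.5
    hi <- br[1] - radii[1] - 1
    if (hi <= lo) next
    side <- sample(c(-1, 1), 1)
    cx <- side * stats::runif(1, lo, hi)
    cy <- stats::runif(1, -0.35, 0.35) * br[2]
    cz <- stats::runif(1, -0.35, 0.35) * br[3]
    center <- c(cx, cy, cz)
    pts <- sweep(u %*% diag(radii), 2, center, "+")
    ok_inside <- all(rowSums(sweep(pts, 2, br - 1, "/")^2) <= 1)
    ok_side <- abs(cx) - radii[1] >= 1
    if (ok_inside && ok_side)
      return(list(center = center, radii = radii))
  }
  stop(sprintf("phantom_suite: no feasible lesion geometry for %.1f mL after %d retries",
               volume_ml, max_retries))
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
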