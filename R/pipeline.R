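#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline, grouped by stage. Every
#' threshold the mask, pooling and lesion rules use is exposed here rather
#' than hard-coded.
#'
#' @return Nested list of configuration values.
#' @export
nwu_config <- function() {
  list(
    resample = list(target_spacing = 1),
    registration = list(metric = "mse", dof = "rigid", shrink = c(8, 4, 2),
                        max_iter = c(200, 200, 100), fg_threshold = -500,
                        min_overlap = 0.25),
    demons = list(iterations = 100, sigma_mm = 2, levels = 2,
                  max_disp_mm = 10, tol = 1e-4),
    mask = list(csf_hu = 14, bone_hu = 60, edge_threshold = 120),
    pooling = list(kernel_mm = c(11, 11, 11), min_fraction = 0.10),
    nwu = list(clip = c(-30, 30), pair_by_mirror_only = FALSE,
               normalize = FALSE),
    lesion = list(lower_cutoff = 2.5, erosion_radius = 1,
                  dilation_radius = 1, connectivity = 26,
                  min_volume_ml = 1),
    seed = 42)
}

#' Read a YAML configuration, merged over the defaults
#'
#' @param path YAML file with any subset of the [nwu_config()] keys.
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_config: file not found: %s", path))
  user <- yaml::read_yaml(path)
  utils::modifyList(nwu_config(), user)
}

#' Content hash of a configuration
#'
#' MD5 of the canonical (sorted-key) JSON serialisation; embedded in every
#' run report so results are traceable to the exact parameter set.
#'
#' @param config configuration list.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                         sort_keys = TRUE)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Default symmetric template from the phantom generator
#'
#' A noise-free, lesion-free, exactly symmetric phantom head serving as
#' the alignment template when no user-supplied symmetric atlas is
#' available.
#'
#' @param spec geometry [phantom_spec()]; lesion/noise/asymmetry settings
#'   are overridden to zero.
#' @return A [ct_volume()].
#' @export
default_template <- function(spec = phantom_spec()) {
  s <- utils::modifyList(unclass(spec),
                         list(uptake_percent = 0, lesion_center_mm = NULL,
                              noise_sd = 0, asymmetry_mm = 0, seed = 20260101L))
  class(s) <- "phantom_spec"
  generate_phantom(s)$ct
}

#' Run the full NWU pipeline on one NCCT volume
#'
#' Executes resampling to 1 mm, affine alignment to the symmetric
#' template, hemisphere split and mirroring, deformable hemisphere
#' registration, parenchyma masking, masked average pooling, voxel-wise
#' NWU mapping, and lesion extraction, returning the final lesion mask and
#' total NWU. Deterministic for identical inputs, configuration and seeds.
#'
#' @param input NCCT as a [ct_volume()], `phantom_case`, or NIfTI path.
#' @param template symmetric template [ct_volume()] (default: the
#'   phantom-derived template).
#' @param config configuration from [nwu_config()] / [read_config()].
#' @param keep_intermediates keep aligned volume, hemisphere pair, warped
#'   hemisphere, deformation field and NWU map in the result.
#' @return Object of class `nwu_case_result`: `side`, `volume_ml`,
#'   `nwu_total`, `otsu_threshold`, `component_count`, `lesion_mask`
#'   (full aligned grid), `transform`, `metric`, `exclusions`,
#'   `config_hash`, `timings_s`, and optionally `intermediates`.
#' @export
run_case <- function(input, template = default_template(),
                     config = nwu_config(), keep_intermediates = FALSE) {
  set.seed(config$seed)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("run_case [%s]: %s", name, conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- round(tic() - t0, 3)
    r
  }

  ct <- if (is.character(input)) stage("read", read_volume(input))
        else if (inherits(input, "phantom_case")) input$ct
        else input
  if (!is_ct_volume(ct)) stop("run_case: input must be a ct_volume or NIfTI path")
  tgt <- config$resample$target_spacing
  if (max(abs(ct$spacing - tgt)) > 1e-6)
    ct <- stage("resample", resample_isotropic(ct, tgt, "linear"))
  if (max(abs(template$spacing - tgt)) > 1e-6)
    template <- resample_isotropic(template, tgt, "linear")

  reg <- stage("align", align_to_template(ct, template, config$registration))
  aligned <- reg$aligned
  if (isTRUE(config$nwu$normalize))
    aligned <- stage("normalize", normalize_to_template(aligned, template))
  pair <- stage("split", split_and_mirror(aligned))
  if (isTRUE(config$nwu$pair_by_mirror_only)) {
    z <- array(0, vol_dim(pair$left))
    field <- deformation_field(z, z, z, pair$spacing)
    field$mse_initial <- field$mse_final <-
      mean((pair$left$values - pair$right_mirrored$values)^2)
  } else {
    field <- stage("demons", register_hemispheres(pair, config$demons))
  }
  right_warped <- apply_deformation(pair$right_mirrored, field, "linear", fill = 0)

  pm_left <- stage("mask_left", parenchyma_mask(pair$left, config$mask))
  pm_right <- stage("mask_right", parenchyma_mask(right_warped, config$mask))
  pooled_left <- stage("pool_left",
    masked_average_pool(pair$left, pm_left$mask,
                        config$pooling$kernel_mm, config$pooling$min_fraction))
  pooled_right <- stage("pool_right",
    masked_average_pool(right_warped, pm_right$mask,
                        config$pooling$kernel_mm, config$pooling$min_fraction))
  nmap <- stage("nwu_map",
                compute_nwu_map(pooled_left, pooled_right, config$nwu$clip))
  lc <- stage("lesion", extract_lesion_mask(nmap, config$lesion))
  rep <- lesion_report(pair, right_warped, lc)

  full_vals <- hemisphere_mask_to_full(lc$mask$values, pair, lc$side,
                                       if (lc$side == "right") field else NULL)
  lesion_full <- binary_mask(full_vals != 0, pair$spacing, pair$origin)

  res <- structure(list(
    side = rep$side, volume_ml = rep$volume_ml, nwu_total = rep$nwu_total,
    otsu_threshold = rep$otsu_threshold,
    component_count = rep$component_count,
    mean_hu_lesion = rep$mean_hu_lesion,
    mean_hu_contralateral = rep$mean_hu_contralateral,
    lesion_mask = lesion_full, transform = reg$transform,
    metric = reg$metric,
    exclusions = list(left = pm_left$exclusions, right = pm_right$exclusions),
    config_hash = config_hash(config), timings_s = timings),
    class = "nwu_case_result")
  if (keep_intermediates)
    res$intermediates <- list(aligned = aligned, pair = pair,
                              right_warped = right_warped, field = field,
                              nwu_map = nmap, lesion_candidate = lc)
  res
}

#' @export
print.nwu_case_result <- function(x, ...) {
  if (x$side == "none")
    cat("<nwu_case_result> no lesion detected\n")
  else
    cat(sprintf("<nwu_case_result> side %s, volume %.1f mL, NWU %.2f %% (Otsu %.2f)\n",
                x$side, x$volume_ml, x$nwu_total, x$otsu_threshold))
  invisible(x)
}

#' JSON-ready report of a case result
#'
#' @param result an `nwu_case_result`.
#' @return A list serialisable with `jsonlite::toJSON` (no volatile
#'   fields such as timings).
#' @export
case_report <- function(result) {
  list(side = result$side,
       volume_ml = result$volume_ml,
       nwu_total = if (is.na(result$nwu_total)) NULL else result$nwu_total,
       otsu_threshold = if (is.na(result$otsu_threshold)) NULL
                        else result$otsu_threshold,
       component_count = result$component_count,
       config_hash = result$config_hash)
}

#' Affine HU rescale of an aligned volume to its template
#'
#' Optional ablation step (off by default): linearly maps the volume's
#' robust brain-intensity range (5th-95th percentile of voxels above
#' 0 HU) onto the template's. A pure gain would cancel in the NWU ratio;
#' the offset component is what this step can change, which is why it is
#' exposed for ablation rather than enabled.
#'
#' @param vol aligned [ct_volume()].
#' @param template template [ct_volume()].
#' @return Rescaled [ct_volume()].
#' @export
normalize_to_template <- function(vol, template) {
  qv <- stats::quantile(vol$values[vol$values > 0], c(0.05, 0.95))
  qt <- stats::quantile(template$values[template$values > 0], c(0.05, 0.95))
  if (diff(qv) <= 0) return(vol)
  gain <- diff(qt) / diff(qv)
  out <- vol$values
  pos <- out > 0
  out[pos] <- (out[pos] - qv[1]) * gain + qt[1]
  ct_volume(out, vol$spacing, vol$origin)
}

# Eq.-1 NWU of a reference mask, using the same hemisphere correspondence
# machinery as the computed lesion: mean HU over the mask's hemisphere-frame
# voxels versus the warped contralateral hemisphere.
reference_nwu_from_mask <- function(ref_aligned, pair, right_warped, field) {
  full <- ref_aligned$values
  nx <- pair$n_x
  half <- nx %/% 2L
  n_left <- sum(full[seq_len(half), , ])
  n_right <- sum(full[seq.int(nx - half + 1L, nx), , ])
  if (n_left + n_right == 0) return(NA_real_)
  side <- if (n_left >= n_right) "left" else "right"
  m <- full_mask_to_hemisphere(full, pair, side,
                               if (side == "right") field else NULL) != 0
  if (!any(m)) return(NA_real_)
  if (side == "left")
    nwu_scalar(mean(pair$left$values[m]), mean(right_warped$values[m]))
  else
    nwu_scalar(mean(right_warped$values[m]), mean(pair$left$values[m]))
}

#' Benchmark the pipeline over a suite of cases
#'
#' Runs [run_case()] on every case, maps each reference mask into the
#' aligned frame with the recovered affine, and assembles the per-case and
#' cohort metric panel (detection rate, NWU MAE/ME/median AE, Dice
#' median/IQR, mAP at the 3D IoU threshold).
#'
#' @param cases a `phantom_suite`, a list of `phantom_case` objects, or a
#'   list of `list(ct=, reference_mask=, reference_nwu=)` entries
#'   (`reference_nwu` optional; when absent it is recomputed from the
#'   reference mask by the NWU formula).
#' @param template symmetric template [ct_volume()].
#' @param config pipeline configuration.
#' @param verbose print one progress line per case.
#' @return Object of class `benchmark_result`: `per_case` data frame and
#'   `summary` list from [cohort_metrics()].
#' @export
run_benchmark <- function(cases, template = default_template(),
                          config = nwu_config(), verbose = FALSE) {
  if (inherits(cases, "phantom_suite")) cases <- cases$cases
  if (length(cases) == 0) stop("run_benchmark: no cases to evaluate")
  rows <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    if (inherits(cs, "phantom_case")) {
      ct <- cs$ct
      ref <- cs$gt_mask
      ref_nwu <- if (cs$lesion_present) cs$gt_nwu else NA_real_
    } else {
      ct <- cs$ct
      ref <- cs$reference_mask
      ref_nwu <- if (!is.null(cs$reference_nwu)) cs$reference_nwu else NA_real_
    }
    res <- run_case(ct, template, config, keep_intermediates = TRUE)
    ref_aligned <- map_mask_affine(ref, res$transform, res$intermediates$aligned)
    if (is.na(ref_nwu) && sum(ref_aligned$values) > 0)
      ref_nwu <- reference_nwu_from_mask(ref_aligned, res$intermediates$pair,
                                         res$intermediates$right_warped,
                                         res$intermediates$field)
    row <- case_metrics(res$lesion_mask, ref_aligned, res$nwu_total, ref_nwu)
    row$id <- i
    row$side <- res$side
    rows[[i]] <- row
    if (verbose)
      message(sprintf("case %d/%d: side %s, dice %.3f, NWU %s vs ref %s",
                      i, length(cases), res$side, row$dice,
                      format(res$nwu_total, digits = 3),
                      format(ref_nwu, digits = 3)))
  }
  per_case <- do.call(rbind, rows)
  structure(list(per_case = per_case, summary = cohort_metrics(per_case)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<benchmark_result> n = %d\n", s$n))
  cat(sprintf("  detection rate %.2f, mAP@%.3f %.2f\n",
              s$detection_rate, s$iou_threshold, s$map_at_threshold))
  cat(sprintf("  NWU MAE %.2f %%, ME %.2f %%, median AE %.2f %%\n",
              s$mae, s$me, s$median_ae))
  cat(sprintf("  Dice median %.2f [%.2f, %.2f]\n",
              s$dice_median, s$dice_iqr[1], s$dice_iqr[2]))
  invisible(x)
}
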