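#' White-matter lesion segmentation configuration
#'
#' Constants of the FLAIR hyperintensity segmentation: candidate voxels must
#' exceed the brain mean by `sd_multiplier` standard deviations (1.69, a
#' value optimised for multi-centre FLAIR); surviving voxels must keep a raw
#' FLAIR z-score of at least `zscore_min` (0.95) after smoothing; the
#' smoothed, max-normalised candidate map is finally thresholded at
#' `final_threshold` (0.1). All thresholds are relative to the image's own
#' statistics, so the segmentation is invariant to global intensity scaling.
#'
#' @param sd_multiplier Candidate threshold, SD units above the brain mean.
#' @param zscore_min Minimum raw-FLAIR z-score retained after smoothing.
#' @param final_threshold Threshold on the max-normalised smoothed map.
#' @param smoothing_fwhm_voxels Gaussian smoothing FWHM, voxels.
#' @param template_min Template values must exceed this for a candidate
#'   voxel to survive (exclusive; default 0 keeps any template support).
#' @param template_multiplicative Multiply candidates by the template
#'   probabilities instead of masking by support.
#' @return A list of class `wml_seg_config`.
#' @export
wml_seg_config <- function(sd_multiplier = 1.69, zscore_min = 0.95,
                           final_threshold = 0.1, smoothing_fwhm_voxels = 1.0,
                           template_min = 0.0,
                           template_multiplicative = FALSE) {
  if (sd_multiplier <= 0) stop("'sd_multiplier' must be positive")
  if (final_threshold <= 0 || final_threshold >= 1)
    stop("'final_threshold' must lie in (0, 1)")
  structure(list(sd_multiplier = sd_multiplier, zscore_min = zscore_min,
                 final_threshold = final_threshold,
                 smoothing_fwhm_voxels = smoothing_fwhm_voxels,
                 template_min = template_min,
                 template_multiplicative = template_multiplicative),
            class = "wml_seg_config")
}

# Brain-mask intensity statistics of the raw FLAIR image.
brain_stats <- function(flair, brain_mask) {
  vals <- flair$data[brain_mask$data > 0.5]
  if (length(vals) == 0) stop("empty brain mask")
  list(mu = mean(vals), sigma = stats::sd(vals))
}

#' Stage 1: FLAIR hyperintensity candidates
#'
#' Retains original intensities at brain voxels brighter than
#' `mean + sd_multiplier * SD`, where mean and SD are computed over the
#' brain mask of the raw image; everything else is zero. A zero-variance
#' image yields an empty candidate map with a warning.
#'
#' @param flair Raw FLAIR `volume_grid`.
#' @param brain_mask Binary `volume_grid`.
#' @param cfg A [wml_seg_config()].
#' @return A `volume_grid` of candidate intensities.
#' @export
threshold_candidates <- function(flair, brain_mask, cfg = wml_seg_config()) {
  assert_same_grid(flair, brain_mask, .what = "FLAIR and brain mask")
  st <- brain_stats(flair, brain_mask)
  out <- array(0, dim(flair$data))
  if (!is.finite(st$sigma) || st$sigma == 0) {
    warning("zero-variance FLAIR image: no hyperintensity candidates")
    return(like_volume(out, flair))
  }
  keep <- brain_mask$data > 0.5 & flair$data > st$mu + cfg$sd_multiplier * st$sigma
  out[keep] <- flair$data[keep]
  like_volume(out, flair)
}

#' Stage 2: probabilistic template exclusion
#'
#' Zeroes candidate voxels lying outside the support of the lesion
#' distribution probabilistic template (template value `<= template_min`),
#' removing hyperintense areas unlikely to reflect pathology (flow
#' artefacts, sulci, temporal poles). With
#' `cfg$template_multiplicative = TRUE` candidates are instead weighted by
#' the template probabilities.
#'
#' @param candidates Candidate map from [threshold_candidates()].
#' @param template Lesion-probability `volume_grid` with values in `[0, 1]`.
#' @param cfg A [wml_seg_config()].
#' @return A `volume_grid`.
#' @export
apply_template <- function(candidates, template, cfg = wml_seg_config()) {
  assert_same_grid(candidates, template, .what = "candidates and template")
  tv <- template$data
  if (min(tv) < 0 || max(tv) > 1) stop("template values must lie in [0, 1]")
  out <- candidates$data
  if (cfg$template_multiplicative) {
    out <- out * tv
  } else {
    out[tv <= cfg$template_min] <- 0
  }
  like_volume(out, candidates)
}

#' Stage 3: smoothing, z-score and final thresholds, binarisation
#'
#' Refines the template-masked candidates: (1) Gaussian smoothing at the
#' configured FWHM; (2) removal of voxels whose z-score in the raw FLAIR
#' image (relative to brain-mask mean/SD) falls below `zscore_min`;
#' (3) max-normalisation of the smoothed map and removal of values below
#' `final_threshold`; (4) binarisation. Lesion volume is voxel count times
#' voxel volume. An empty candidate map is a valid input and yields an
#' empty mask with volume 0.
#'
#' @param candidates Output of [apply_template()].
#' @param flair_raw The raw FLAIR `volume_grid` (z-scores are computed on
#'   the raw image).
#' @param brain_mask Binary `volume_grid`.
#' @param cfg A [wml_seg_config()].
#' @param gt_lesions Optional ground-truth lesion mask; when given, a Dice
#'   coefficient is reported.
#' @return A list of class `lesion_result`: `lesion_mask`,
#'   `lesion_volume_mm3`, `intermediates` (named `volume_grid`s per stage),
#'   `dice_vs_truth` (or `NA`).
#' @export
refine_and_binarise <- function(candidates, flair_raw, brain_mask,
                                cfg = wml_seg_config(), gt_lesions = NULL) {
  assert_same_grid(candidates, flair_raw, brain_mask, .what = "refinement inputs")
  sm <- gaussian_smooth_3d(candidates$data, cfg$smoothing_fwhm_voxels)
  st <- brain_stats(flair_raw, brain_mask)
  z <- (flair_raw$data - st$mu) / st$sigma
  sm_z <- sm
  sm_z[z < cfg$zscore_min] <- 0
  mx <- max(sm_z)
  norm <- if (mx > 0) sm_z / mx else sm_z
  final <- norm
  final[final < cfg$final_threshold] <- 0
  mask <- array(as.integer(final > 0), dim(final))
  vol <- sum(mask) * voxel_volume(candidates)
  dice <- if (!is.null(gt_lesions)) dice_coefficient(mask, gt_lesions) else NA_real_
  structure(list(lesion_mask = like_volume(mask, candidates),
                 lesion_volume_mm3 = vol,
                 intermediates = list(
                   smoothed = like_volume(sm, candidates),
                   zscore_filtered = like_volume(sm_z, candidates),
                   normalised = like_volume(norm, candidates)),
                 dice_vs_truth = dice),
            class = "lesion_result")
}

#' @export
print.lesion_result <- function(x, ...) {
  cat(sprintf("<lesion_result> %d lesion voxels, %.1f mm^3%s\n",
              sum(x$lesion_mask$data), x$lesion_volume_mm3,
              if (is.finite(x$dice_vs_truth))
                sprintf(", Dice vs truth %.3f", x$dice_vs_truth) else ""))
  invisible(x)
}

#' Full FLAIR lesion segmentation
#'
#' Runs the three stages in sequence: relative intensity thresholding,
#' probabilistic template exclusion, and smoothing/re-thresholding with
#' binarisation.
#'
#' @inheritParams refine_and_binarise
#' @param flair Raw FLAIR `volume_grid`.
#' @param template Lesion-probability template in `[0, 1]`.
#' @return A `lesion_result` (see [refine_and_binarise()]); the stage-1 and
#'   stage-2 maps are added to `intermediates`.
#' @export
segment_wml <- function(flair, brain_mask, template, cfg = wml_seg_config(),
                        gt_lesions = NULL) {
  cand <- threshold_candidates(flair, brain_mask, cfg)
  masked <- apply_template(cand, template, cfg)
  res <- refine_and_binarise(masked, flair, brain_mask, cfg, gt_lesions)
  res$intermediates <- c(list(candidates = cand, template_masked = masked),
                         res$intermediates)
  res
}

#' Carry a baseline lesion mask forward to a follow-up session
#'
#' Longitudinal lesion masks start from the baseline segmentation and are
#' edited to include follow-up changes (volumes share one grid here;
#' between-session registration is out of scope). Additions are OR-ed in,
#' removals subtracted.
#'
#' @param baseline_mask Binary `volume_grid`.
#' @param additions,removals Optional binary `volume_grid`s of edit
#'   channels.
#' @return A list of class `lesion_result` with the follow-up mask and the
#'   baseline and follow-up volumes in mm^3.
#' @export
carry_forward_mask <- function(baseline_mask, additions = NULL, removals = NULL) {
  m <- baseline_mask$data > 0.5
  if (!is.null(additions)) {
    assert_same_grid(baseline_mask, additions, .what = "mask edits")
    m <- m | additions$data > 0.5
  }
  if (!is.null(removals)) {
    assert_same_grid(baseline_mask, removals, .what = "mask edits")
    m <- m & !(removals$data > 0.5)
  }
  vv <- voxel_volume(baseline_mask)
  out <- array(as.integer(m), dim(m))
  structure(list(lesion_mask = like_volume(out, baseline_mask),
                 lesion_volume_mm3 = sum(out) * vv,
                 baseline_volume_mm3 = sum(baseline_mask$data > 0.5) * vv,
                 intermediates = list(), dice_vs_truth = NA_real_),
            class = "lesion_result")
}
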