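#' Mask preparation configuration
#'
#' Probabilistic tissue segmentations are thresholded at `prob_threshold`
#' (0.5), binarised, and eroded by a sphere kernel of radius
#' `erosion_radius_mm` (1.4 mm) to suppress partial-volume voxels at tissue
#' boundaries; lesion (WML) masks are exempt from erosion, as lesions are
#' small and erosion would disproportionately remove them.
#'
#' @param prob_threshold Probability threshold in (0, 1).
#' @param erosion_radius_mm Sphere kernel radius, mm (0 disables erosion).
#' @param erode_wml Erode WML masks too (default `FALSE`, the stated
#'   exception).
#' @return A list of class `mask_prep_config`.
#' @export
mask_prep_config <- function(prob_threshold = 0.5, erosion_radius_mm = 1.4,
                             erode_wml = FALSE) {
  if (prob_threshold <= 0 || prob_threshold >= 1)
    stop("'prob_threshold' must lie in (0, 1)")
  if (erosion_radius_mm < 0) stop("'erosion_radius_mm' must be non-negative")
  structure(list(prob_threshold = prob_threshold,
                 erosion_radius_mm = erosion_radius_mm, erode_wml = erode_wml),
            class = "mask_prep_config")
}

# Spherical structuring element as integer voxel offsets with centre
# distance (in mm, using voxel_dims) <= radius.
sphere_offsets <- function(radius_mm, voxel_dims) {
  r <- floor(radius_mm / voxel_dims)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d <- sqrt((g$dx * voxel_dims[1])^2 + (g$dy * voxel_dims[2])^2 +
            (g$dz * voxel_dims[3])^2)
  g[d <= radius_mm, , drop = FALSE]
}

# Morphological erosion of a binary array by a set of offsets; voxels
# outside the grid count as background.
erode_binary <- function(mask, offsets) {
  d <- dim(mask)
  out <- mask > 0.5
  full <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (i in seq_len(nrow(offsets))) {
    off <- as.integer(offsets[i, ])
    if (all(off == 0L)) next
    shifted <- array(FALSE, d)
    src <- full
    dst <- full
    okrange <- TRUE
    for (ax in 1:3) {
      o <- off[ax]
      n <- d[ax]
      if (o > 0) { dst[[ax]] <- seq_len(n - o); src[[ax]] <- seq_len(n - o) + o }
      else if (o < 0) { dst[[ax]] <- seq_len(n + o) - o; src[[ax]] <- seq_len(n + o) }
      if (length(dst[[ax]]) == 0) okrange <- FALSE
    }
    if (!okrange) return(array(FALSE, d))
    shifted[dst[[1]], dst[[2]], dst[[3]]] <-
      (mask > 0.5)[src[[1]], src[[2]], src[[3]]]
    out <- out & shifted
  }
  out
}

#' Prepare a probabilistic mask for ROI statistics
#'
#' Threshold at `prob_threshold`, binarise, then erode with the spherical
#' kernel (skipped for WML masks unless configured otherwise). An erosion
#' that empties the mask produces a warning and an empty mask.
#'
#' @param prob_mask `volume_grid` with values in `[0, 1]`.
#' @param cfg A [mask_prep_config()].
#' @param is_wml Flag marking a lesion mask (exempt from erosion).
#' @return A binary `volume_grid`.
#' @export
prepare_mask <- function(prob_mask, cfg = mask_prep_config(), is_wml = FALSE) {
  v <- prob_mask$data
  if (min(v, na.rm = TRUE) < 0 || max(v, na.rm = TRUE) > 1)
    stop("probabilistic mask values must lie in [0, 1]")
  bin <- !is.na(v) & v > cfg$prob_threshold
  if (cfg$erosion_radius_mm > 0 && (!is_wml || cfg$erode_wml)) {
    offs <- sphere_offsets(cfg$erosion_radius_mm, prob_mask$voxel_dims)
    bin <- erode_binary(bin, offs)
    if (!any(bin) && any(v > cfg$prob_threshold))
      warning("erosion emptied the mask")
  }
  like_volume(array(as.integer(bin), dim(v)), prob_mask)
}

#' ROI summary statistics of a quantitative map
#'
#' Mean, median, interquartile range (p75 - p25, linear-interpolation
#' percentiles), sample (n-1) standard deviation, coefficient of variation
#' (`sd/mean`, undefined when the mean is 0), voxel count and volume over
#' the valid (non-`NaN`) in-mask voxels. When a weight map is supplied the
#' connection-probability-weighted mean is included. An empty mask or
#' all-invalid region yields a warning and `NULL` (no row).
#'
#' @param map A `volume_grid`.
#' @param mask Binary `volume_grid`.
#' @param roi,metric Names recorded in the output row.
#' @param weights Optional non-negative weight `volume_grid` (e.g. a tract
#'   connection-probability map).
#' @return A one-row data frame, or `NULL`.
#' @export
roi_summary <- function(map, mask, roi = "roi", metric = "metric",
                        weights = NULL) {
  assert_same_grid(map, mask, .what = "map and mask")
  idx <- which(mask$data > 0.5)
  vals <- map$data[idx]
  ok <- is.finite(vals)
  if (length(idx) == 0 || !any(ok)) {
    warning(sprintf("no valid voxels for %s/%s: row omitted", roi, metric))
    return(NULL)
  }
  vals <- vals[ok]
  wmean <- NA_real_
  if (!is.null(weights)) {
    assert_same_grid(map, weights, .what = "map and weights")
    w <- weights$data[idx][ok]
    wmean <- weighted_mean_values(vals, w)
  }
  q <- stats::quantile(vals, c(0.25, 0.75), type = 7, names = FALSE)
  mu <- mean(vals)
  s <- if (length(vals) > 1) stats::sd(vals) else 0
  data.frame(roi = roi, metric = metric,
             mean = mu, weighted_mean = wmean,
             median = stats::median(vals), iqr = q[2] - q[1], sd = s,
             cv = if (mu != 0) s / mu else NA_real_,
             voxel_count = length(vals),
             volume_mm3 = length(vals) * voxel_volume(map),
             stringsAsFactors = FALSE)
}

# Weighted mean of a value vector; errors on all-zero or negative weights.
weighted_mean_values <- function(x, w) {
  if (any(w < 0)) stop("weights must be non-negative")
  sw <- sum(w)
  if (sw == 0) stop("all-zero weights")
  sum(w * x) / sw
}

#' Connection-probability-weighted mean of a map
#'
#' `sum(w * x) / sum(w)` over valid (non-`NaN`) voxels, used for
#' tract-specific means of DTI and NODDI metrics weighted by tract
#' connection probability.
#'
#' @param map A `volume_grid`.
#' @param weight_map Non-negative `volume_grid`, not all zero.
#' @return A scalar.
#' @export
weighted_mean <- function(map, weight_map) {
  assert_same_grid(map, weight_map, .what = "map and weights")
  x <- as.vector(map$data)
  w <- as.vector(weight_map$data)
  ok <- is.finite(x) & is.finite(w)
  weighted_mean_values(x[ok], w[ok])
}

#' Volume of a binary mask
#'
#' Voxel count times voxel volume, mm^3.
#'
#' @param mask Binary `volume_grid`.
#' @return Volume in mm^3.
#' @export
mask_volume <- function(mask) {
  sum(mask$data > 0.5) * voxel_volume(mask)
}

#' Longitudinal volume change
#'
#' Signed change `followup - baseline`, mm^3, computed per tissue type.
#'
#' @param baseline,followup Volumes in mm^3.
#' @return Signed change in mm^3.
#' @export
volume_change <- function(baseline, followup) {
  followup - baseline
}
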