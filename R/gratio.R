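#' Calibrate the MTsat-to-MVF proportionality constant k
#'
#' The myelin volume fraction is modelled as `MVF = k * MTsat`; `k` is fixed
#' by assuming a known aggregate g-ratio (default 0.7) in the splenium of
#' the corpus callosum of healthy calibration subjects. Voxelwise,
#' \deqn{k = \frac{1}{\delta_{app}}\left(1 - \frac{1}{1 + c\,(1 -
#'   \nu_{iso})\,\nu_{ic}}\right), \quad c = \frac{1}{g_{target}^2} - 1}
#' where `delta_app` is the MTsat map and `vic`/`viso` the NODDI
#' intracellular and isotropic volume fractions. The voxelwise k is averaged
#' over the splenium mask per subject/session, then across
#' subjects/sessions. Lesion masks play no role here: calibration subjects
#' are healthy controls and their maps are used whole.
#'
#' @param mtsat_map,vic_map,viso_map `volume_grid`s for a single calibration
#'   subject/session (ignored when `per_subject_maps` is given).
#' @param splenium_mask Binary `volume_grid`.
#' @param g_target Assumed splenium g-ratio (default 0.7).
#' @param per_subject_maps Optional list of lists, each with elements
#'   `mtsat`, `vic`, `viso` and optionally `splenium` (else the shared
#'   `splenium_mask` is used), one per calibration subject/session.
#' @param per_voxel If `TRUE` (default) k is computed voxelwise then
#'   averaged; if `FALSE` it is computed from splenium-mean quantities.
#' @return A list of class `gratio_calibration`: `k` (pooled scalar),
#'   `per_subject_k`, `g_target`, `splenium_voxel_count`.
#' @export
calibrate_k <- function(mtsat_map = NULL, vic_map = NULL, viso_map = NULL,
                        splenium_mask, g_target = 0.7,
                        per_subject_maps = NULL, per_voxel = TRUE) {
  if (is.null(per_subject_maps))
    per_subject_maps <- list(list(mtsat = mtsat_map, vic = vic_map,
                                  viso = viso_map))
  cc <- 1 / g_target^2 - 1
  per_k <- numeric(length(per_subject_maps))
  counts <- integer(length(per_subject_maps))
  for (i in seq_along(per_subject_maps)) {
    m <- per_subject_maps[[i]]
    msk <- if (!is.null(m$splenium)) m$splenium else splenium_mask
    assert_same_grid(m$mtsat, m$vic, m$viso, msk, .what = "calibration maps")
    idx <- which(msk$data > 0.5)
    if (length(idx) == 0) stop("empty splenium mask for calibration subject ", i)
    d <- m$mtsat$data[idx]
    w <- (1 - m$viso$data[idx]) * m$vic$data[idx]
    ok <- is.finite(d) & d > 0 & is.finite(w)
    if (!any(ok)) stop("no valid MTsat voxels in the splenium for subject ", i)
    per_k[i] <- if (per_voxel)
      mean((1 / d[ok]) * (1 - 1 / (1 + cc * w[ok])))
    else
      (1 / mean(d[ok])) * (1 - 1 / (1 + cc * mean(w[ok])))
    counts[i] <- sum(ok)
  }
  structure(list(k = mean(per_k), per_subject_k = per_k, g_target = g_target,
                 splenium_voxel_count = sum(counts)),
            class = "gratio_calibration")
}

#' @export
print.gratio_calibration <- function(x, ...) {
  cat(sprintf("<gratio_calibration> k = %.5f (g_target = %g, %d voxels, %d subject-sessions)\n",
              x$k, x$g_target, x$splenium_voxel_count, length(x$per_subject_k)))
  invisible(x)
}

#' Myelin and axonal volume fraction maps
#'
#' `MVF = k * MTsat` voxelwise and `AVF = (1 - MVF)(1 - viso) * vic`.
#' Voxels with `MVF >= 1` (unphysical: myelin cannot fill the voxel) are
#' marked invalid.
#'
#' @param mtsat_map,vic_map,viso_map Co-registered `volume_grid`s.
#' @param k Calibration constant (scalar > 0, or a `gratio_calibration`).
#' @return A list of class `gratio_maps` with `mvf_map`, `avf_map`,
#'   `validity_mask`.
#' @export
compute_mvf_avf <- function(mtsat_map, vic_map, viso_map, k) {
  if (inherits(k, "gratio_calibration")) k <- k$k
  if (!is.numeric(k) || length(k) != 1 || k <= 0) stop("'k' must be a positive scalar")
  assert_same_grid(mtsat_map, vic_map, viso_map, .what = "g-ratio inputs")
  mvf <- k * mtsat_map$data
  avf <- (1 - mvf) * (1 - viso_map$data) * vic_map$data
  ok <- is.finite(mvf) & mvf >= 0 & mvf < 1 & is.finite(avf)
  mvf[!ok] <- NaN
  avf[!ok] <- NaN
  structure(list(mvf_map = like_volume(mvf, mtsat_map),
                 avf_map = like_volume(avf, mtsat_map),
                 validity_mask = like_volume(array(as.integer(ok), dim(mvf)),
                                             mtsat_map)),
            class = "gratio_maps")
}

#' Aggregate g-ratio map
#'
#' Voxel-by-voxel `g = sqrt(1 / (1 + MVF / AVF))`: the MRI aggregate
#' g-ratio, the ratio of inner (axonal) to outer (axon plus myelin) fibre
#' diameter. Limits: `MVF = 0` with `AVF > 0` gives `g = 1` (unmyelinated);
#' `AVF = 0` with `MVF > 0` gives `g = 0`, flagged invalid (no axonal
#' compartment); `MVF = AVF = 0` is invalid.
#'
#' @param m A `gratio_maps` object from [compute_mvf_avf()].
#' @return `m` with `g_map` filled and `validity_mask` updated.
#' @export
compute_gratio_map <- function(m) {
  stopifnot(inherits(m, "gratio_maps"))
  mvf <- m$mvf_map$data
  avf <- m$avf_map$data
  g <- array(NaN, dim(mvf))
  ok <- is.finite(mvf) & is.finite(avf) & avf > 0
  g[ok] <- sqrt(1 / (1 + mvf[ok] / avf[ok]))
  degen <- is.finite(mvf) & is.finite(avf) & avf == 0 & mvf > 0
  g[degen] <- 0
  valid <- ok
  m$g_map <- like_volume(g, m$mvf_map)
  m$validity_mask <- like_volume(array(as.integer(valid), dim(mvf)), m$mvf_map)
  m
}

#' ROI summaries of the g-ratio map
#'
#' G-ratio statistics are reported for normal-appearing white matter and
#' white-matter lesions only (the aggregate model is a white-matter model).
#' Delegates to [roi_summary()]; an empty lesion mask yields a warning and
#' no WML row.
#'
#' @param m A `gratio_maps` object with `g_map` filled.
#' @param masks Named list of binary `volume_grid`s containing `nawm` and
#'   optionally `wml`.
#' @return A data frame of ROI summary rows.
#' @export
gratio_roi_values <- function(m, masks) {
  stopifnot(inherits(m, "gratio_maps"), !is.null(m$g_map))
  if (is.null(masks$nawm)) stop("a 'nawm' mask is required")
  rows <- list(roi_summary(m$g_map, masks$nawm, roi = "nawm", metric = "gratio"))
  if (!is.null(masks$wml)) {
    if (sum(masks$wml$data > 0.5) == 0) {
      warning("empty WML mask: no WML g-ratio row")
    } else {
      rows <- c(rows, list(roi_summary(m$g_map, masks$wml, roi = "wml",
                                       metric = "gratio")))
    }
  }
  do.call(rbind, rows)
}
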