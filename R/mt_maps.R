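#' Magnetisation-transfer triplet container
#'
#' Holds the co-registered MT-on, MT-off and T1-weighted multi-echo spoiled
#' gradient echo volumes together with their acquisition metadata. Defaults
#' follow the sub-study protocol: TR 30/30/15 ms, flip 5/5/18 degrees,
#' echoes at 1.54, 4.55, 8.49 ms.
#'
#' @param mt_on,mt_off,t1w Lists of per-echo `volume_grid`s (length >= 1,
#'   equal length across echoes within each volume, one shared grid).
#' @param tr_on,tr_off,tr_t1w Repetition times, ms.
#' @param flip_on,flip_off,flip_t1w Excitation flip angles, degrees, in
#'   (0, 90).
#' @param te Echo times, ms.
#' @return An object of class `mt_triplet`.
#' @export
mt_triplet <- function(mt_on, mt_off, t1w,
                       tr_on = 30, tr_off = 30, tr_t1w = 15,
                       flip_on = 5, flip_off = 5, flip_t1w = 18,
                       te = c(1.54, 4.55, 8.49)) {
  for (nm in c("mt_on", "mt_off", "t1w")) {
    v <- get(nm)
    if (!is.list(v) || length(v) == 0 || !all(vapply(v, is_volume_grid, TRUE)))
      stop("'", nm, "' must be a non-empty list of volume_grids")
  }
  do.call(assert_same_grid, c(mt_on, mt_off, t1w, list(.what = "MT triplet volumes")))
  flips <- c(flip_on, flip_off, flip_t1w)
  if (any(flips <= 0 | flips >= 90)) stop("flip angles must lie in (0, 90) degrees")
  if (any(c(tr_on, tr_off, tr_t1w) <= 0)) stop("TR values must be positive")
  structure(list(mt_on = mt_on, mt_off = mt_off, t1w = t1w,
                 tr_on = tr_on, tr_off = tr_off, tr_t1w = tr_t1w,
                 flip_on = flip_on, flip_off = flip_off, flip_t1w = flip_t1w,
                 te = te),
            class = "mt_triplet")
}

#' Sum multi-echo volumes
#'
#' Voxelwise sum over the echoes of a multi-echo acquisition, used to
#' increase SNR before MTR/MTsat computation.
#'
#' @param multi_echo A list of same-grid `volume_grid`s (or a single one,
#'   returned unchanged).
#' @return A `volume_grid`.
#' @export
sum_echoes <- function(multi_echo) {
  if (is_volume_grid(multi_echo)) return(multi_echo)
  if (!is.list(multi_echo) || length(multi_echo) == 0)
    stop("'multi_echo' must be a non-empty list of volume_grids")
  do.call(assert_same_grid, c(multi_echo, list(.what = "echoes")))
  acc <- multi_echo[[1L]]$data
  for (v in multi_echo[-1L]) acc <- acc + v$data
  like_volume(acc, multi_echo[[1L]])
}

#' Magnetisation transfer ratio
#'
#' `MTR = (S_off - S_on) / S_off`, as a fraction, from echo-summed MT-off
#' and MT-on volumes. Voxels with non-positive MT-off signal are undefined
#' (`NaN`). No range restriction is applied here; pass the result through
#' [range_threshold()] before ROI statistics to discard implausible voxels.
#'
#' @param mt_on,mt_off Echo-summed `volume_grid`s.
#' @return A `volume_grid` of MTR fractions.
#' @export
compute_mtr <- function(mt_on, mt_off) {
  assert_same_grid(mt_on, mt_off, .what = "MT volumes")
  off <- mt_off$data
  mtr <- (off - mt_on$data) / off
  mtr[!(off > 0)] <- NaN
  like_volume(mtr, mt_off)
}

#' Apparent R1 and amplitude from a dual flip-angle pair
#'
#' Solves the rational spoiled-gradient-echo approximation
#' `S = A * alpha * TR * R1 / (TR * R1 + alpha^2 / 2)` for the apparent
#' longitudinal relaxation rate R1 and amplitude A from two acquisitions
#' with different flip angle / TR:
#' \deqn{R_1 = \tfrac12\,\frac{S_{T1}\alpha_{T1}/TR_{T1} -
#'   S_{PD}\alpha_{PD}/TR_{PD}}{S_{PD}/\alpha_{PD} - S_{T1}/\alpha_{T1}}}
#' \deqn{A = S_{PD} S_{T1}\,\frac{TR_{PD}\alpha_{T1}/\alpha_{PD} -
#'   TR_{T1}\alpha_{PD}/\alpha_{T1}}{S_{T1} TR_{PD}\alpha_{T1} -
#'   S_{PD} TR_{T1}\alpha_{PD}}}
#' The PD-weighted input is the echo-summed MT-off volume (low flip angle),
#' the T1-weighted input the high-flip-angle volume. R1 is invariant to
#' global signal scaling; A is equivariant. Voxels with non-finite or
#' non-positive R1 are invalid (`NaN` in both outputs).
#'
#' @param s_pd,s_t1 Echo-summed `volume_grid`s.
#' @param alpha_pd,alpha_t1 Flip angles in radians.
#' @param tr_pd,tr_t1 Repetition times in ms.
#' @return A list with `r1app_map` (1/ms), `amplitude_map` (signal units)
#'   and `validity_mask` `volume_grid`s.
#' @export
helms_r1_amplitude <- function(s_pd, s_t1, alpha_pd, alpha_t1, tr_pd, tr_t1) {
  assert_same_grid(s_pd, s_t1, .what = "R1 inputs")
  if (isTRUE(all.equal(c(alpha_pd, tr_pd), c(alpha_t1, tr_t1))))
    stop("identical flip angle and TR for both inputs: system underdetermined")
  spd <- s_pd$data
  st1 <- s_t1$data
  r1 <- 0.5 * (st1 * alpha_t1 / tr_t1 - spd * alpha_pd / tr_pd) /
    (spd / alpha_pd - st1 / alpha_t1)
  a <- spd * st1 * (tr_pd * alpha_t1 / alpha_pd - tr_t1 * alpha_pd / alpha_t1) /
    (st1 * tr_pd * alpha_t1 - spd * tr_t1 * alpha_pd)
  ok <- is.finite(r1) & r1 > 0 & is.finite(a)
  r1[!ok] <- NaN
  a[!ok] <- NaN
  list(r1app_map = like_volume(r1, s_pd),
       amplitude_map = like_volume(a, s_pd),
       validity_mask = like_volume(array(as.integer(ok), dim(spd)), s_pd))
}

#' Magnetisation transfer saturation map
#'
#' Per-excitation saturation
#' `delta = (A * alpha / S_MT - 1) * R1 * TR - alpha^2 / 2`,
#' from the echo-summed MT-on volume and the apparent R1/amplitude maps.
#' Stored as a fraction; invariant to global scaling of all input signals.
#' Voxels with non-positive MT-on signal or invalid R1/A are `NaN`. Apply
#' [range_threshold()] afterwards to discard implausible values.
#'
#' @param mt_on Echo-summed MT-on `volume_grid`.
#' @param r1app_map,amplitude_map Outputs of [helms_r1_amplitude()].
#' @param alpha_mt MT-on flip angle, radians.
#' @param tr_mt MT-on repetition time, ms.
#' @return A `volume_grid` of MTsat fractions.
#' @export
compute_mtsat <- function(mt_on, r1app_map, amplitude_map, alpha_mt, tr_mt) {
  assert_same_grid(mt_on, r1app_map, amplitude_map, .what = "MTsat inputs")
  s <- mt_on$data
  delta <- (amplitude_map$data * alpha_mt / s - 1) * r1app_map$data * tr_mt -
    alpha_mt^2 / 2
  delta[!(s > 0)] <- NaN
  like_volume(delta, mt_on)
}

#' Exclude map values outside a validity range
#'
#' Values outside `[lo, hi]` are set to `NaN` (excluded from downstream ROI
#' statistics), not clamped; used to discard implausible MTR/MTsat voxels
#' before summarisation.
#'
#' @param map A `volume_grid`.
#' @param lo,hi Range bounds, `lo < hi`.
#' @return A `volume_grid`.
#' @export
range_threshold <- function(map, lo = 0, hi = 1) {
  if (lo >= hi) stop("'lo' must be smaller than 'hi'")
  x <- map$data
  x[!is.na(x) & (x < lo | x > hi)] <- NaN
  like_volume(x, map)
}

#' Full MT map computation from a triplet
#'
#' Convenience wrapper: sums echoes, computes MTR, solves for apparent
#' R1/amplitude from the MT-off (PD-weighted) and T1-weighted volumes, and
#' derives the MTsat map; MTR and MTsat are range-thresholded to `[0, 1]`.
#'
#' @param triplet An [mt_triplet()].
#' @param threshold Apply the 0-1 [range_threshold()] to MTR and MTsat.
#' @return A list with `mtr_map`, `mtsat_map`, `r1app_map`,
#'   `amplitude_map`, `validity_mask`.
#' @export
compute_mt_maps <- function(triplet, threshold = TRUE) {
  stopifnot(inherits(triplet, "mt_triplet"))
  s_on <- sum_echoes(triplet$mt_on)
  s_off <- sum_echoes(triplet$mt_off)
  s_t1 <- sum_echoes(triplet$t1w)
  mtr <- compute_mtr(s_on, s_off)
  ra <- helms_r1_amplitude(s_off, s_t1,
                           alpha_pd = triplet$flip_off * pi / 180,
                           alpha_t1 = triplet$flip_t1w * pi / 180,
                           tr_pd = triplet$tr_off, tr_t1 = triplet$tr_t1w)
  mtsat <- compute_mtsat(s_on, ra$r1app_map, ra$amplitude_map,
                         alpha_mt = triplet$flip_on * pi / 180,
                         tr_mt = triplet$tr_on)
  if (threshold) {
    mtr <- range_threshold(mtr, 0, 1)
    mtsat <- range_threshold(mtsat, 0, 1)
  }
  list(mtr_map = mtr, mtsat_map = mtsat, r1app_map = ra$r1app_map,
       amplitude_map = ra$amplitude_map, validity_mask = ra$validity_mask)
}
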