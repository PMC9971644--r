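#' Quantitative T2 map from a dual-echo pair
#'
#' Inverts mono-exponential decay between the two echoes:
#' \deqn{T_2 = \frac{TE_1 - TE_2}{\log S_{T2w} - \log S_{PD}}}
#' where the short-TE echo is the proton-density-weighted image and the
#' long-TE echo the T2-weighted image. Natural logarithms. Voxels with
#' non-positive signal in either echo, or with non-decaying signal
#' (`S_T2w >= S_PD`, which would imply infinite or negative T2), are marked
#' invalid and carry `NaN`.
#'
#' @param pd_echo,t2w_echo `volume_grid`s of the short- and long-TE echoes.
#' @param te1,te2 Echo times in ms, `te1 < te2` (defaults 9.6 and 96 ms).
#' @return A list with `t2_map` (ms) and `validity_mask` `volume_grid`s.
#' @export
#' @examples
#' pd <- volume_grid(array(1000, c(4, 4, 4)))
#' t2w <- volume_grid(array(1000 * exp(-(96 - 9.6) / 80), c(4, 4, 4)))
#' t2map_from_dual_echo(pd, t2w)$t2_map$data[1, 1, 1]  # 80 ms
t2map_from_dual_echo <- function(pd_echo, t2w_echo, te1 = 9.6, te2 = 96) {
  assert_same_grid(pd_echo, t2w_echo, .what = "dual-echo volumes")
  if (te1 == te2) stop("'te1' and 'te2' must differ")
  if (te1 > te2) stop("'te1' must be the shorter echo time")
  spd <- pd_echo$data
  st2 <- t2w_echo$data
  ok <- spd > 0 & st2 > 0 & st2 < spd
  t2 <- array(NaN, dim(spd))
  t2[ok] <- (te1 - te2) / (log(st2[ok]) - log(spd[ok]))
  list(t2_map = like_volume(t2, pd_echo),
       validity_mask = like_volume(array(as.integer(ok), dim(spd)), pd_echo))
}

#' Approximate quantitative T1 map from the MT-off / T1-weighted pair
#'
#' Applies the dual-flip-angle apparent-R1 solve ([helms_r1_amplitude()])
#' to the echo-summed MT-off (low flip) and T1-weighted (high flip) spoiled
#' gradient echo volumes and reports `T1 = 1/R1` in ms. Invariant to global
#' signal scaling. Voxels with invalid (non-positive or non-finite) R1 carry
#' `NaN`.
#'
#' @param mt_off,t1w Echo-summed `volume_grid`s, or an [mt_triplet()] passed
#'   as `mt_off` (in which case `t1w` and the acquisition parameters are
#'   taken from it).
#' @param flip_off,flip_t1w Flip angles in degrees.
#' @param tr_off,tr_t1w Repetition times in ms.
#' @return A list with `t1_map` (ms), `r1app_map` (1/ms) and
#'   `validity_mask`.
#' @export
t1map_from_mt_pair <- function(mt_off, t1w = NULL,
                               flip_off = 5, flip_t1w = 18,
                               tr_off = 30, tr_t1w = 15) {
  if (inherits(mt_off, "mt_triplet")) {
    trip <- mt_off
    mt_off <- sum_echoes(trip$mt_off)
    t1w <- sum_echoes(trip$t1w)
    flip_off <- trip$flip_off; flip_t1w <- trip$flip_t1w
    tr_off <- trip$tr_off; tr_t1w <- trip$tr_t1w
  }
  ra <- helms_r1_amplitude(mt_off, t1w,
                           alpha_pd = flip_off * pi / 180,
                           alpha_t1 = flip_t1w * pi / 180,
                           tr_pd = tr_off, tr_t1 = tr_t1w)
  t1 <- 1 / ra$r1app_map$data
  list(t1_map = like_volume(t1, mt_off),
       r1app_map = ra$r1app_map,
       validity_mask = ra$validity_mask)
}
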