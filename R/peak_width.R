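#' Sample a scalar map on the white-matter skeleton
#'
#' Collects metric values at skeleton voxels passing the FA filters: an FA
#' threshold of 0.2 excludes predominantly non-WM voxels and a further
#' threshold of 0.3 reduces CSF partial-volume contamination (the second
#' subsumes the first; both are applied for fidelity to the published
#' procedure). `NaN` metric values are dropped and counted.
#'
#' @param metric_map,fa_map,skeleton_mask Co-registered `volume_grid`s.
#' @param source_metric Name recorded with the sample (e.g. `"MD"`).
#' @param fa_skeleton_threshold,fa_masking_threshold The two FA cutoffs.
#' @return A list of class `skeleton_sample`: `values`, `source_metric`,
#'   `n_dropped_nan`, the thresholds used.
#' @export
build_skeleton_values <- function(metric_map, fa_map, skeleton_mask,
                                  source_metric = "metric",
                                  fa_skeleton_threshold = 0.2,
                                  fa_masking_threshold = 0.3) {
  assert_same_grid(metric_map, fa_map, skeleton_mask,
                   .what = "skeleton sampling inputs")
  sel <- skeleton_mask$data > 0.5 &
    !is.na(fa_map$data) &
    fa_map$data >= fa_skeleton_threshold &
    fa_map$data >= fa_masking_threshold
  vals <- metric_map$data[sel]
  nan <- !is.finite(vals)
  vals <- vals[!nan]
  if (length(vals) == 0)
    stop("no skeleton voxels survive the FA thresholds for '", source_metric, "'")
  structure(list(values = vals, source_metric = source_metric,
                 n_dropped_nan = sum(nan),
                 fa_skeleton_threshold = fa_skeleton_threshold,
                 fa_masking_threshold = fa_masking_threshold),
            class = "skeleton_sample")
}

#' Peak width of a skeletonized sample
#'
#' The difference between the 95th and 5th percentiles of the voxel-based
#' skeleton values (PSMD when the metric is MD, and analogously PSAD, PSRD,
#' PSFA, PSICVF, PSISOVF, PSODI), using the linear-interpolation percentile
#' convention. Translation invariant; scales linearly with the data. Fewer
#' than 20 samples triggers a warning (percentiles are unstable).
#'
#' @param sample A `skeleton_sample` (or a bare numeric vector).
#' @param probs The two percentile probabilities.
#' @return A scalar in the units of the source metric.
#' @export
peak_width <- function(sample, probs = c(0.05, 0.95)) {
  vals <- if (inherits(sample, "skeleton_sample")) sample$values else sample
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop("empty sample")
  if (length(vals) < 20)
    warning("fewer than 20 skeleton samples: percentiles are unstable")
  q <- stats::quantile(vals, probs = probs, type = 7, names = FALSE)
  q[2] - q[1]
}

#' Peak-width metrics for a set of scalar maps
#'
#' Convenience wrapper computing [peak_width()] for each named metric map
#' over one skeleton.
#'
#' @param metric_maps Named list of `volume_grid`s.
#' @param fa_map,skeleton_mask As in [build_skeleton_values()].
#' @param ... Passed to [build_skeleton_values()].
#' @return A data frame with columns `metric`, `n_samples`, `peak_width`.
#' @export
peak_width_table <- function(metric_maps, fa_map, skeleton_mask, ...) {
  rows <- lapply(names(metric_maps), function(nm) {
    s <- build_skeleton_values(metric_maps[[nm]], fa_map, skeleton_mask,
                               source_metric = nm, ...)
    data.frame(metric = nm, n_samples = length(s$values),
               peak_width = peak_width(s), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
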