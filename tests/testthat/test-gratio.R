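# Scalar oracle for the calibration constant, evaluated longhand.
k_oracle <- function(delta, vic, viso, g_target = 0.7) {
  cc <- 1 / g_target^2 - 1
  w <- (1 - viso) * vic
  (1 / delta) * (1 - 1 / (1 + cc * w))
}

test_that("calibration constant matches the closed form and its averaging rules", {
  # worked scalar case: delta 0.04, vic 0.6, viso 0.1 -> k ~ 8.995
  expect_equal(k_oracle(0.04, 0.6, 0.1), 8.99530, tolerance = 1e-5)

  spl <- uvol(1)
  cal <- calibrate_k(uvol(0.04), uvol(0.6), uvol(0.1), spl)
  expect_equal(cal$k, k_oracle(0.04, 0.6, 0.1), tolerance = 1e-12)
  expect_equal(cal$splenium_voxel_count, 64L)

  # uniform maps: per-voxel k identical, mean equals the voxel value; and
  # the splenium-mean variant agrees exactly in the uniform case
  cal2 <- calibrate_k(uvol(0.04), uvol(0.6), uvol(0.1), spl, per_voxel = FALSE)
  expect_equal(cal2$k, cal$k, tolerance = 1e-12)

  # two subjects pool by the plain average
  subj <- list(list(mtsat = uvol(0.03), vic = uvol(0.5), viso = uvol(0.1)),
               list(mtsat = uvol(0.05), vic = uvol(0.7), viso = uvol(0.2)))
  cal3 <- calibrate_k(splenium_mask = spl, per_subject_maps = subj)
  expect_equal(cal3$k, mean(c(k_oracle(0.03, 0.5, 0.1),
                              k_oracle(0.05, 0.7, 0.2))), tolerance = 1e-12)
  expect_equal(cal3$per_subject_k,
               c(k_oracle(0.03, 0.5, 0.1), k_oracle(0.05, 0.7, 0.2)))

  empty <- uvol(0)
  expect_error(calibrate_k(uvol(0.04), uvol(0.6), uvol(0.1), empty), "empty")
})

test_that("MVF/AVF maps follow their defining formulas", {
  k <- k_oracle(0.04, 0.6, 0.1)
  m <- compute_mvf_avf(uvol(0.04), uvol(0.6), uvol(0.1), k)
  expect_equal(m$mvf_map$data[1, 1, 1], 0.3598, tolerance = 1e-4)
  expect_equal(m$avf_map$data[1, 1, 1], 0.3457, tolerance = 1e-4)

  m0 <- compute_mvf_avf(uvol(0), uvol(0.6), uvol(0.1), k)
  expect_equal(m0$mvf_map$data[1, 1, 1], 0)
  expect_equal(m0$avf_map$data[1, 1, 1], 0.9 * 0.6, tolerance = 1e-12)

  mfree <- compute_mvf_avf(uvol(0.02), uvol(0.6), uvol(1), k)  # free water
  expect_equal(mfree$avf_map$data[1, 1, 1], 0, tolerance = 1e-12)

  # unphysical MVF >= 1 is invalidated
  mbad <- compute_mvf_avf(uvol(0.2), uvol(0.6), uvol(0.1), 10)
  expect_true(all(is.nan(mbad$mvf_map$data)))
})

test_that("aggregate g-ratio map: calibration chain and limits", {
  k <- k_oracle(0.04, 0.6, 0.1)
  g <- compute_gratio_map(compute_mvf_avf(uvol(0.04), uvol(0.6), uvol(0.1), k))
  expect_equal(g$g_map$data[1, 1, 1], 0.7, tolerance = 1e-10)

  g1 <- compute_gratio_map(compute_mvf_avf(uvol(0), uvol(0.6), uvol(0.1), k))
  expect_equal(g1$g_map$data[1, 1, 1], 1)  # unmyelinated limit

  # MVF = AVF is the sqrt(1/2) symmetry point
  m <- compute_mvf_avf(uvol(0.04), uvol(0.6), uvol(0.1), k)
  m$avf_map <- m$mvf_map
  expect_equal(compute_gratio_map(m)$g_map$data[1, 1, 1], sqrt(0.5),
               tolerance = 1e-12)
})

test_that("g-ratio monotonicity in MVF and in neurite density", {
  k <- 9
  deltas <- seq(0.01, 0.06, by = 0.01)
  gs <- vapply(deltas, function(d)
    compute_gratio_map(compute_mvf_avf(uvol(d), uvol(0.6), uvol(0.1), k)
                       )$g_map$data[1, 1, 1], numeric(1))
  expect_true(all(diff(gs) < 0))  # more myelin, lower g
  vics <- seq(0.3, 0.8, by = 0.1)
  gs2 <- vapply(vics, function(v)
    compute_gratio_map(compute_mvf_avf(uvol(0.04), uvol(v), uvol(0.1), k)
                       )$g_map$data[1, 1, 1], numeric(1))
  expect_true(all(diff(gs2) > 0))  # more axon, higher g
})

test_that("self-consistency: calibrate then map returns the target g in the splenium", {
  # uniform maps: identity to numerical precision
  cal <- calibrate_k(uvol(0.04), uvol(0.6), uvol(0.1), uvol(1))
  g <- compute_gratio_map(compute_mvf_avf(uvol(0.04), uvol(0.6), uvol(0.1), cal))
  expect_equal(mean(g$g_map$data), 0.7, tolerance = 1e-6)

  # heterogeneous noiseless phantom: within the Jensen-gap tolerance
  cfg <- small_cfg(snr = Inf, seed = 17)   # default 2% within-tissue variation
  gt <- make_labelmap(cfg)
  cal2 <- calibrate_k(gt$mtsat_map, gt$vic_map, gt$viso_map, gt$splenium_mask)
  g2 <- compute_gratio_map(compute_mvf_avf(gt$mtsat_map, gt$vic_map,
                                           gt$viso_map, cal2))
  spl <- gt$splenium_mask$data > 0
  expect_equal(mean(g2$g_map$data[spl]), 0.7, tolerance = 1e-3)
})

test_that("ROI reporting is restricted to NAWM and WML", {
  gval <- 0.72
  sh <- c(6, 6, 6)
  nawm <- volume_grid(array(as.integer(seq_len(prod(sh)) %% 2 == 0), sh))
  g <- structure(list(mvf_map = uvol(0.3, sh), avf_map = uvol(0.3, sh),
                      g_map = uvol(gval, sh),
                      validity_mask = uvol(1, sh)), class = "gratio_maps")
  tab <- gratio_roi_values(g, list(nawm = nawm))
  expect_equal(tab$roi, "nawm")
  expect_equal(tab$mean, gval)
  expect_equal(tab$sd, 0)
  expect_equal(tab$cv, 0)

  expect_warning(gratio_roi_values(g, list(nawm = nawm, wml = uvol(0, sh))),
                 "empty WML")
  expect_error(gratio_roi_values(g, list()), "nawm")
})
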