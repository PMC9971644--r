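test_that("echo summing adds voxelwise and matches analytic decay sums", {
  ones <- uvol(1)
  expect_equal(sum_echoes(list(ones, ones, ones))$data, array(3, c(4, 4, 4)))
  expect_equal(sum_echoes(list(ones))$data, ones$data)

  te <- c(1.54, 4.55, 8.49); t2s <- 50; s0 <- 123.4
  echoes <- lapply(te, function(t) uvol(s0 * exp(-t / t2s)))
  expect_equal(sum_echoes(echoes)$data[1, 1, 1], s0 * sum(exp(-te / t2s)),
               tolerance = 1e-12)
  expect_error(sum_echoes(list(ones, uvol(1, c(3, 3, 3)))), "grid mismatch")
  expect_error(sum_echoes(list()), "non-empty")
})

test_that("MTR arithmetic and no-transfer symmetry", {
  expect_equal(compute_mtr(uvol(60), uvol(100))$data[1, 1, 1], 0.4)
  expect_equal(compute_mtr(uvol(77), uvol(77))$data[1, 1, 1], 0)
  expect_true(all(is.nan(compute_mtr(uvol(1), uvol(0))$data)))
})

test_that("MTR rank-orders tissues like the generating MTsat", {
  ph <- noiseless_small()
  mt <- compute_mt_maps(ph$mt)
  lab <- ph$gt$label_map$data
  tp <- tissue_defaults()
  mtr_means <- vapply(tp$label, function(l)
    mean(mt$mtr_map$data[lab == l], na.rm = TRUE), numeric(1))
  expect_equal(cor(mtr_means, tp$mtsat, method = "spearman"), 1)
})

test_that("apparent R1/amplitude solve inverts the forward model", {
  ph <- noiseless_small()
  gt <- ph$gt
  mt <- compute_mt_maps(ph$mt, threshold = FALSE)
  brain <- gt$brain_mask$data > 0
  expect_equal(mt$r1app_map$data[brain], 1 / gt$t1_map$data[brain],
               tolerance = 1e-9)
  # amplitude equals PD up to one global scale (the echo-sum factor)
  ratio <- mt$amplitude_map$data[brain] / gt$pd_map$data[brain]
  expect_lt(diff(range(ratio)), 1e-9 * mean(ratio))

  # scale-equivariance: signals x c -> R1 unchanged, A x c
  off <- sum_echoes(ph$mt$mt_off); t1w <- sum_echoes(ph$mt$t1w)
  a <- helms_r1_amplitude(off, t1w, 5 * pi / 180, 18 * pi / 180, 30, 15)
  b <- helms_r1_amplitude(volume_grid(off$data * 3, off$voxel_dims),
                          volume_grid(t1w$data * 3, t1w$voxel_dims),
                          5 * pi / 180, 18 * pi / 180, 30, 15)
  expect_equal(b$r1app_map$data[brain], a$r1app_map$data[brain], tolerance = 1e-10)
  expect_equal(b$amplitude_map$data[brain], 3 * a$amplitude_map$data[brain],
               tolerance = 1e-10)

  # zero signal is invalid; identical acquisitions are rejected
  z <- helms_r1_amplitude(uvol(0), uvol(0), 0.1, 0.3, 30, 15)
  expect_true(all(is.nan(z$r1app_map$data)))
  expect_error(helms_r1_amplitude(uvol(1), uvol(1), 0.1, 0.1, 30, 30),
               "underdetermined")
})

test_that("MTsat map inverts the generator and is scale invariant", {
  ph <- noiseless_small()
  gt <- ph$gt
  mt <- compute_mt_maps(ph$mt, threshold = FALSE)
  brain <- gt$brain_mask$data > 0
  expect_equal(mt$mtsat_map$data[brain], gt$mtsat_map$data[brain],
               tolerance = 1e-10)

  # delta = 0 phantom yields a zero MTsat map
  cfg <- small_cfg(snr = Inf, tissue_cv = 0, seed = 4)
  gt0 <- make_labelmap(cfg)
  gt0$mtsat_map$data[] <- 0
  mt0 <- compute_mt_maps(make_mt_triplet(gt0, cfg), threshold = FALSE)
  b0 <- gt0$brain_mask$data > 0
  expect_equal(mt0$mtsat_map$data[b0], rep(0, sum(b0)), tolerance = 1e-12)

  # global scaling of all three inputs leaves delta unchanged
  scaled <- ph$mt
  for (nm in c("mt_on", "mt_off", "t1w"))
    scaled[[nm]] <- lapply(scaled[[nm]], function(v)
      volume_grid(v$data * 7, v$voxel_dims))
  mt_s <- compute_mt_maps(scaled, threshold = FALSE)
  expect_equal(mt_s$mtsat_map$data[brain], mt$mtsat_map$data[brain],
               tolerance = 1e-10)
})

test_that("range threshold excludes rather than clamps", {
  v <- uvol(0.35)
  v$data[1, 1, 1] <- 1.2
  v$data[2, 1, 1] <- -0.4
  out <- range_threshold(v)
  expect_true(is.nan(out$data[1, 1, 1]))
  expect_true(is.nan(out$data[2, 1, 1]))
  expect_equal(out$data[3, 3, 3], 0.35)
  ok <- uvol(0.5)
  expect_equal(range_threshold(ok)$data, ok$data)
  expect_error(range_threshold(v, 1, 0), "smaller")
})
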