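test_that("label map geometry, lesion placement and determinism", {
  cfg0 <- small_cfg(n_lesions = 0, snr = Inf, tissue_cv = 0)
  gt0 <- make_labelmap(cfg0)
  expect_equal(sum(gt0$lesion_mask$data), 0)

  cfg <- small_cfg(snr = Inf, tissue_cv = 0, seed = 5)
  gt <- make_labelmap(cfg)
  # connected-component oracle: as many lesions as requested
  expect_equal(count_components(gt$lesion_mask$data), cfg$n_lesions)
  # lesions live inside the former NAWM shell (now labelled 6)
  expect_true(all(gt$label_map$data[gt$lesion_mask$data > 0] == 6L))

  gt2 <- make_labelmap(cfg)
  expect_identical(gt$label_map$data, gt2$label_map$data)
  expect_identical(gt$mtsat_map$data, gt2$mtsat_map$data)
})

test_that("noiseless FLAIR is piecewise constant with usable lesion contrast", {
  ph <- noiseless_small()
  tp <- tissue_defaults()
  vals <- unique(as.vector(ph$flair$data))
  expect_true(all(vals %in% c(0, tp$flair)))

  brain <- ph$gt$brain_mask$data > 0
  mu <- mean(ph$flair$data[brain])
  sigma <- sd(ph$flair$data[brain])
  lesion_mean <- mean(ph$flair$data[ph$gt$lesion_mask$data > 0])
  expect_gt(lesion_mean, mu + 1.69 * sigma)
})

test_that("Rician noise matches its analytic magnitude expectation", {
  # Monte-Carlo check of the noise model: over seeds, the noisy NAWM mean
  # approaches the Rician mean sqrt(mu^2 + sigma^2) (high-SNR form), which
  # at SNR 20 differs from the clean mean by the sigma^2/(2 mu) bias
  # inherent to magnitude reconstruction.
  snr <- 20
  per_seed <- vapply(1:10, function(s) {
    cfg <- small_cfg(snr = snr, tissue_cv = 0, seed = 100 + s)
    gt <- make_labelmap(cfg)
    fl <- make_flair(gt, cfg)
    mean(fl$data[gt$label_map$data == 2L])
  }, numeric(1))
  mu <- tissue_defaults()$flair[tissue_defaults()$tissue == "nawm"]
  sigma <- mu / snr
  expected <- sqrt(mu^2 + sigma^2)
  se <- sd(per_seed) / sqrt(length(per_seed))
  expect_lt(abs(mean(per_seed) - expected), 2 * se + 0.01 * sigma)
  expect_error(make_flair(make_labelmap(small_cfg()), small_cfg(), snr = -1),
               "positive")
})

test_that("dual-echo forward model is exact mono-exponential decay", {
  ph <- noiseless_small()
  gt <- ph$gt
  brain <- gt$brain_mask$data > 0
  pred1 <- gt$pd_map$data * exp(-9.6 / gt$t2_map$data)
  pred2 <- gt$pd_map$data * exp(-96 / gt$t2_map$data)
  expect_equal(ph$dual_echo$pd_echo$data[brain], pred1[brain], tolerance = 1e-12)
  expect_equal(ph$dual_echo$t2w_echo$data[brain], pred2[brain], tolerance = 1e-12)
})

test_that("MT triplet: zero saturation collapses MT-on onto MT-off; scale passes through", {
  cfg <- small_cfg(snr = Inf, tissue_cv = 0, seed = 9)
  gt <- make_labelmap(cfg)
  gt$mtsat_map$data[] <- 0
  trip <- make_mt_triplet(gt, cfg)
  for (e in 1:3)
    expect_equal(trip$mt_on[[e]]$data, trip$mt_off[[e]]$data, tolerance = 1e-14)

  # doubling the amplitude doubles every signal but leaves MTsat untouched
  gt2 <- make_labelmap(cfg)
  gtX <- gt2
  gtX$pd_map$data <- 2 * gt2$pd_map$data
  t1 <- make_mt_triplet(gt2, cfg)
  t2 <- make_mt_triplet(gtX, cfg)
  expect_equal(t2$mt_on[[1]]$data, 2 * t1$mt_on[[1]]$data, tolerance = 1e-12)
  d1 <- compute_mt_maps(t1, threshold = FALSE)$mtsat_map$data
  d2 <- compute_mt_maps(t2, threshold = FALSE)$mtsat_map$data
  brain <- gt2$brain_mask$data > 0
  expect_equal(d1[brain], d2[brain], tolerance = 1e-10)
})

test_that("diffusion series has the protocol shell structure and exact attenuation", {
  ph <- noiseless_small()
  scheme <- ph$dwi$scheme
  expect_equal(sum(!scheme$reverse), 151)
  tab <- shell_table(scheme)
  expect_equal(tab$bval, c(0, 200, 500, 1000, 2000))
  expect_equal(tab$n_volumes, c(14, 3, 6, 64, 64))
  expect_equal(sum(scheme$reverse), 3)

  # isotropic tensor: S/S0 = exp(-b d) in every direction
  cfg <- small_cfg(snr = Inf, tissue_cv = 0)
  gt <- make_labelmap(cfg)
  gt$tensor_field[, , , 1:3] <- 0.7e-3
  gt$tensor_field[, , , 4:6] <- 0
  dwi <- make_dwi(gt, cfg)
  i1000 <- which(dwi$scheme$bvals == 1000)
  vox <- which(gt$pd_map$data > 0)[1]
  s0 <- gt$pd_map$data[vox]
  for (i in i1000[1:5])
    expect_equal(dwi$series[[i]]$data[vox] / s0, exp(-0.7), tolerance = 1e-12)
})

test_that("template, skeleton and tract maps respect their construction invariants", {
  ph <- noiseless_small()
  gt <- ph$gt
  expect_true(all(gt$template$data >= 0 & gt$template$data <= 1))
  expect_true(all(gt$template$data[gt$lesion_mask$data > 0] > 0))
  # skeleton is a subset of NAWM
  expect_true(all(gt$label_map$data[gt$skeleton_mask$data > 0] == 2L))
  for (tr in gt$tract_prob_maps) {
    expect_true(all(tr$data >= 0 & tr$data <= 1))
    tot <- sum(tr$data)
    expect_true(is.finite(tot) && tot > 0)
  }
})
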