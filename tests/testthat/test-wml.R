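test_that("candidate thresholding keeps exactly the voxels above mean + 1.69 SD", {
  set.seed(1)
  sh <- c(10, 10, 10)
  img <- volume_grid(array(rnorm(prod(sh), 100, 10), sh))
  brain <- uvol(1, sh)
  cand <- threshold_candidates(img, brain)
  mu <- mean(img$data); sigma <- sd(img$data)
  manual <- img$data > mu + 1.69 * sigma
  expect_equal(cand$data > 0, manual)
  expect_equal(cand$data[manual], img$data[manual])  # intensities retained

  # constant image: zero variance, empty candidates with warning
  expect_warning(c0 <- threshold_candidates(uvol(5, sh), brain), "zero-variance")
  expect_equal(sum(c0$data), 0)
})

test_that("phantom lesion voxels all survive candidate thresholding", {
  ph <- noiseless_small()
  cand <- threshold_candidates(ph$flair, ph$masks$brain)
  expect_true(all(cand$data[ph$gt$lesion_mask$data > 0] > 0))
})

test_that("template exclusion masks by support", {
  sh <- c(8, 8, 8)
  cand <- volume_grid(array(runif(prod(sh)), sh))
  expect_equal(apply_template(cand, uvol(1, sh))$data, cand$data)
  expect_equal(sum(apply_template(cand, uvol(0, sh))$data), 0)

  # artefact blob outside template support is removed, lesions retained
  templ <- uvol(0, sh); templ$data[1:4, , ] <- 1
  out <- apply_template(cand, templ)
  expect_equal(sum(out$data[5:8, , ]), 0)
  expect_equal(out$data[1:4, , ], cand$data[1:4, , ])

  bad <- uvol(2, sh)
  expect_error(apply_template(cand, bad), "\\[0, 1\\]")
})

test_that("refinement handles empty input and recovers the noiseless phantom exactly", {
  sh <- c(8, 8, 8)
  res <- refine_and_binarise(uvol(0, sh), uvol(1, sh), uvol(1, sh))
  expect_equal(sum(res$lesion_mask$data), 0)
  expect_equal(res$lesion_volume_mm3, 0)

  ph <- noiseless_small()
  seg <- segment_wml(ph$flair, ph$masks$brain, ph$gt$template,
                     gt_lesions = ph$gt$lesion_mask)
  expect_equal(seg$dice_vs_truth, 1.0)
  expect_equal(seg$lesion_volume_mm3,
               sum(ph$gt$lesion_mask$data) * voxel_volume(ph$flair))
})

test_that("noisy recovery: median Dice over 10 seeds at SNR 40 is at least 0.8", {
  dices <- vapply(1:10, function(s) {
    cfg <- small_cfg(seed = 400 + s)   # default SNR 40
    gt <- make_labelmap(cfg)
    fl <- make_flair(gt, cfg)
    segment_wml(fl, gt$brain_mask, gt$template,
                gt_lesions = gt$lesion_mask)$dice_vs_truth
  }, numeric(1))
  expect_gte(stats::median(dices), 0.8)
})

test_that("stage supports shrink monotonically and the mask is scale invariant", {
  cfg <- small_cfg(seed = 8)           # noisy: exercises every threshold
  gt <- make_labelmap(cfg)
  fl <- make_flair(gt, cfg)
  cand <- threshold_candidates(fl, gt$brain_mask)
  masked <- apply_template(cand, gt$template)
  res <- refine_and_binarise(masked, fl, gt$brain_mask)
  expect_true(all(masked$data[cand$data == 0] == 0))
  expect_true(all(res$intermediates$zscore_filtered$data[
    res$intermediates$smoothed$data == 0] == 0))
  # the final mask needs candidate support after smoothing only, so compare
  # against the smoothed support
  expect_true(all(res$lesion_mask$data[res$intermediates$smoothed$data == 0] == 0))

  for (c in c(0.25, 40)) {
    fl_c <- volume_grid(fl$data * c, fl$voxel_dims)
    res_c <- segment_wml(fl_c, gt$brain_mask, gt$template)
    res_1 <- segment_wml(fl, gt$brain_mask, gt$template)
    expect_identical(res_c$lesion_mask$data, res_1$lesion_mask$data)
  }
})

test_that("longitudinal mask carry-forward applies edits additively", {
  sh <- c(8, 8, 8)
  base <- uvol(0, sh); base$data[2:3, 2:3, 2:3] <- 1
  vv <- voxel_volume(base)
  same <- carry_forward_mask(base)
  expect_identical(same$lesion_mask$data, array(as.integer(base$data), sh))

  add <- uvol(0, sh); add$data[6, 6, 6:8] <- 1   # a 3-voxel blob
  grown <- carry_forward_mask(base, additions = add)
  expect_equal(grown$lesion_volume_mm3, grown$baseline_volume_mm3 + 3 * vv)

  rem <- uvol(0, sh); rem$data[2:3, 2:3, 2:3] <- 1
  shrunk <- carry_forward_mask(base, removals = rem)
  expect_equal(shrunk$lesion_volume_mm3, 0)
})
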