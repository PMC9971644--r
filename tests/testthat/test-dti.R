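test_that("noiseless tensor fit is an exact inversion", {
  ph <- noiseless_small()
  tm <- fit_tensor(ph$dwi$series, ph$dwi$scheme, mask = ph$gt$brain_mask)
  brain <- array(ph$gt$brain_mask$data > 0, c(dim(ph$gt$brain_mask$data), 6))
  expect_lt(max(abs(tm$tensor_field[brain] - ph$gt$tensor_field[brain])), 1e-12)

  sc <- tensor_scalars(tm)
  nawm <- ph$gt$label_map$data == 2L
  lam <- c(1.0e-3, 0.45e-3, 0.45e-3)
  md <- mean(lam)
  fa <- sqrt(1.5 * sum((lam - md)^2) / sum(lam^2))
  # most NAWM voxels carry the plain NAWM tensor (tubes override a few)
  expect_equal(stats::median(sc$md_map$data[nawm]), md, tolerance = 1e-10)
  expect_equal(stats::median(sc$fa_map$data[nawm]), fa, tolerance = 1e-8)
  expect_equal(stats::median(sc$ad_map$data[nawm]), lam[1], tolerance = 1e-10)
  expect_equal(stats::median(sc$rd_map$data[nawm]), lam[2], tolerance = 1e-10)
})

test_that("tensor scalars match their closed forms and limits", {
  mk <- function(lam) {
    tf <- array(0, c(1, 1, 1, 6))
    tf[1, 1, 1, 1:3] <- lam
    tensor_scalars(tf, voxel_dims = c(1, 1, 1))
  }
  lam <- c(1.7, 0.2, 0.2) * 1e-3
  sc <- mk(lam)
  md <- mean(lam)
  expect_equal(sc$md_map$data[1, 1, 1], 0.7e-3, tolerance = 1e-12)
  expect_equal(sc$ad_map$data[1, 1, 1], 1.7e-3, tolerance = 1e-12)
  expect_equal(sc$rd_map$data[1, 1, 1], 0.2e-3, tolerance = 1e-12)
  expect_equal(sc$fa_map$data[1, 1, 1],
               sqrt(1.5 * sum((lam - md)^2) / sum(lam^2)), tolerance = 1e-10)
  expect_equal(mk(c(1, 1, 1) * 1e-3)$fa_map$data[1, 1, 1], 0, tolerance = 1e-10)
  expect_equal(mk(c(1e-3, 0, 0))$fa_map$data[1, 1, 1], 1, tolerance = 1e-8)
  expect_equal(mk(c(0, 0, 0))$fa_map$data[1, 1, 1], 0)
})

test_that("FA/MD are invariant under joint rotation of directions and tensor", {
  cfg <- small_cfg(snr = Inf, tissue_cv = 0, seed = 21)
  gt <- make_labelmap(cfg)
  dwi <- make_dwi(gt, cfg)
  base <- tensor_scalars(fit_tensor(dwi$series, dwi$scheme, mask = gt$brain_mask))

  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  # rotate the ground-truth tensors
  gtR <- gt
  tf <- gt$tensor_field
  d <- dim(tf)[1:3]
  comp <- matrix(tf, ncol = 6)
  for (i in seq_len(nrow(comp))) {
    D <- matrix(c(comp[i, 1], comp[i, 4], comp[i, 5],
                  comp[i, 4], comp[i, 2], comp[i, 6],
                  comp[i, 5], comp[i, 6], comp[i, 3]), 3, 3)
    DR <- R %*% D %*% t(R)
    comp[i, ] <- c(DR[1, 1], DR[2, 2], DR[3, 3], DR[1, 2], DR[1, 3], DR[2, 3])
  }
  gtR$tensor_field <- array(comp, c(d, 6))
  dwiR <- make_dwi(gtR, cfg)
  rot <- tensor_scalars(fit_tensor(dwiR$series, dwiR$scheme, mask = gt$brain_mask))
  brain <- gt$brain_mask$data > 0
  expect_lt(max(abs(rot$fa_map$data[brain] - base$fa_map$data[brain])), 1e-10)
  expect_lt(max(abs(rot$md_map$data[brain] - base$md_map$data[brain])), 1e-10)
})

test_that("vectorised fit agrees with a per-voxel lm/eigen oracle", {
  ph <- noiseless_small()
  sc <- tensor_scalars(fit_tensor(ph$dwi$series, ph$dwi$scheme,
                                  mask = ph$gt$brain_mask))
  vox <- which(ph$gt$brain_mask$data > 0)
  vox <- vox[seq(1, length(vox), length.out = 60)]
  orc <- fit_tensor_oracle(ph$dwi$series, ph$dwi$scheme, vox)
  expect_lt(max(abs(sc$fa_map$data[vox] - orc[, "fa"])), 1e-3)
  expect_lt(max(abs(sc$md_map$data[vox] - orc[, "md"])), 1e-9)
  expect_lt(max(abs(sc$ad_map$data[vox] - orc[, "ad"])), 1e-9)
  expect_lt(max(abs(sc$rd_map$data[vox] - orc[, "rd"])), 1e-9)
})

test_that("noisy single-shell fit: median FA bias in the high-FA tube < 0.03", {
  truth_fa <- local({
    lam <- c(1.7, 0.2, 0.2) * 1e-3
    sqrt(1.5 * sum((lam - mean(lam))^2) / sum(lam^2))
  })
  biases <- vapply(1:10, function(s) {
    cfg <- small_cfg(snr = 30, tissue_cv = 0, seed = 300 + s)
    gt <- make_labelmap(cfg)
    dwi <- make_dwi(gt, cfg)
    tube <- gt$tensor_field[, , , 1] == 1.7e-3 | gt$tensor_field[, , , 2] == 1.7e-3 |
      gt$tensor_field[, , , 3] == 1.7e-3
    mask <- volume_grid(array(as.integer(tube), cfg$grid_shape), cfg$voxel_dims)
    sc <- tensor_scalars(fit_tensor(dwi$series, dwi$scheme, shells = 1000,
                                    mask = mask))
    stats::median(sc$fa_map$data[tube], na.rm = TRUE) - truth_fa
  }, numeric(1))
  expect_lt(abs(stats::median(biases)), 0.03)
})

test_that("degenerate designs and voxels are rejected or invalidated", {
  ph <- noiseless_small()
  expect_error(fit_tensor(ph$dwi$series[1:5], diffusion_scheme(
    ph$dwi$scheme$bvals[1:5], ph$dwi$scheme$bvecs[, 1:5],
    ph$dwi$scheme$reverse[1:5])), "at least 7")
  # all-zero voxels (background) are invalid
  tm <- fit_tensor(ph$dwi$series, ph$dwi$scheme)
  bg <- which(ph$gt$brain_mask$data == 0)[1]
  expect_equal(tm$validity_mask$data[bg], 0L)
  expect_true(is.nan(tm$tensor_field[, , , 1][bg]))
})
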