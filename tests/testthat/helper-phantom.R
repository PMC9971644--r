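# Shared fixtures and independent brute-force oracles. Phantoms are built in
# code at test time and cached per session so repeated tests stay fast.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A 32^3 configuration: lesion radii scaled to the thinner NAWM shell.
small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(grid_shape = c(32, 32, 32), n_lesions = 3,
                   lesion_radius = c(1.5, 2.5))
  do.call(phantom_config, utils::modifyList(defaults, args))
}

noiseless_small <- function() cached("noiseless_small", {
  build_phantom(small_cfg(snr = Inf, tissue_cv = 0, seed = 42), with_dwi = TRUE)
})

# uniform volume helper
uvol <- function(value, shape = c(4, 4, 4), vd = c(1, 1, 1))
  volume_grid(array(value, shape), vd)

# Connected components of a binary array, 6-connectivity, by flood fill.
# Independent oracle for lesion counting.
count_components <- function(mask) {
  m <- mask > 0.5
  d <- dim(m)
  lab <- array(0L, d)
  nc <- 0L
  idx <- which(m & lab == 0L)
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))
  while (length(idx <- which(m & lab == 0L)) > 0) {
    nc <- nc + 1L
    queue <- idx[1L]
    lab[queue] <- nc
    while (length(queue) > 0) {
      i <- queue[1L]; queue <- queue[-1L]
      z <- (i - 1L) %/% (d[1] * d[2]) + 1L
      rem <- (i - 1L) %% (d[1] * d[2])
      y <- rem %/% d[1] + 1L
      x <- rem %% d[1] + 1L
      for (k in 1:6) {
        p <- c(x, y, z) + offsets[k, ]
        if (any(p < 1) || any(p > d)) next
        j <- (p[3] - 1L) * d[1] * d[2] + (p[2] - 1L) * d[1] + p[1]
        if (m[j] && lab[j] == 0L) { lab[j] <- nc; queue <- c(queue, j) }
      }
    }
  }
  nc
}

# Linear-interpolation percentile, written out longhand as an independent
# oracle for the quantile convention.
percentile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Brute-force binary erosion oracle: triple loop over voxels and offsets.
erode_oracle <- function(mask, radius_mm, voxel_dims) {
  d <- dim(mask)
  out <- array(FALSE, d)
  r <- floor(radius_mm / voxel_dims)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (mask[x, y, z] < 0.5) next
    keep <- TRUE
    for (dx in -r[1]:r[1]) for (dy in -r[2]:r[2]) for (dz in -r[3]:r[3]) {
      if (sqrt((dx * voxel_dims[1])^2 + (dy * voxel_dims[2])^2 +
               (dz * voxel_dims[3])^2) > radius_mm) next
      p <- c(x + dx, y + dy, z + dz)
      if (any(p < 1) || any(p > d) || mask[p[1], p[2], p[3]] < 0.5) {
        keep <- FALSE; break
      }
    }
    out[x, y, z] <- keep
  }
  out
}

# Per-voxel tensor fit oracle: lm() on the log signal, eigen() for scalars.
# Fully independent of the vectorised solver and the closed-form eigenvalues.
fit_tensor_oracle <- function(series, scheme, voxels) {
  keep <- !scheme$reverse
  b <- scheme$bvals[keep]
  g <- scheme$bvecs[, keep, drop = FALSE]
  df <- data.frame(x1 = -b * g[1, ]^2, x2 = -b * g[2, ]^2, x3 = -b * g[3, ]^2,
                   x4 = -2 * b * g[1, ] * g[2, ], x5 = -2 * b * g[1, ] * g[3, ],
                   x6 = -2 * b * g[2, ] * g[3, ])
  t(vapply(voxels, function(v) {
    s <- vapply(which(keep), function(i) series[[i]]$data[v], numeric(1))
    fit <- stats::lm(log(s) ~ x1 + x2 + x3 + x4 + x5 + x6, data = df)
    cf <- stats::coef(fit)
    D <- matrix(c(cf[2], cf[5], cf[6],
                  cf[5], cf[3], cf[7],
                  cf[6], cf[7], cf[4]), 3, 3)
    lam <- pmax(sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
                     decreasing = TRUE), 0)
    md <- mean(lam)
    fa <- if (sum(lam^2) > 0)
      sqrt(1.5 * sum((lam - md)^2) / sum(lam^2)) else 0
    c(fa = fa, md = md, ad = lam[1], rd = (lam[2] + lam[3]) / 2)
  }, numeric(4)))
}
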