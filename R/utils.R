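# Internal helpers shared across stages.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards, so generators never perturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Rician magnitude noise: sqrt((S + n1)^2 + n2^2) with n1, n2 ~ N(0, sd).
# The standard magnitude-reconstruction noise model for MR data.
add_rician_noise <- function(x, sd) {
  if (sd <= 0) return(x)
  n <- length(x)
  sqrt((x + stats::rnorm(n, 0, sd))^2 + stats::rnorm(n, 0, sd)^2)
}

# Approximately uniform unit directions on the sphere: Fibonacci spiral,
# optionally rotated by a random rotation so repeated shells differ.
# Returns a 3 x n matrix of unit columns.
sphere_directions <- function(n, rotate = TRUE) {
  if (n < 1) return(matrix(numeric(0), nrow = 3))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  golden <- pi * (1 + sqrt(5))
  theta <- golden * i
  m <- rbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  if (rotate && n > 1) {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    m <- q %*% m
  }
  m
}

# Separable 3D Gaussian smoothing by shift-and-add, zero-padded at the
# borders. `fwhm` is in voxels (may be a scalar or per-axis length 3).
gaussian_smooth_3d <- function(arr, fwhm) {
  fwhm <- rep(as.numeric(fwhm), length.out = 3L)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  out <- arr
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    out <- shift_add(out, k, r, ax)
  }
  out
}

# Convolve `arr` along axis `ax` with kernel `k` (radius r), zero padding.
shift_add <- function(arr, k, r, ax) {
  d <- dim(arr)
  acc <- array(0, d)
  idx_full <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- idx_full
    dst <- idx_full
    n <- d[ax]
    if (off > 0) { dst[[ax]] <- seq_len(n - off) + off; src[[ax]] <- seq_len(n - off) }
    else if (off < 0) { dst[[ax]] <- seq_len(n + off); src[[ax]] <- seq_len(n + off) - off }
    if (length(dst[[ax]]) == 0) next
    acc[dst[[1]], dst[[2]], dst[[3]]] <- acc[dst[[1]], dst[[2]], dst[[3]]] +
      k[j] * arr[src[[1]], src[[2]], src[[3]]]
  }
  acc
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; returns `NaN` when both masks are empty.
#'
#' @param a,b Binary `volume_grid`s (or logical/numeric arrays).
#' @return A scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  xa <- if (is_volume_grid(a)) a$data else a
  xb <- if (is_volume_grid(b)) b$data else b
  xa <- xa > 0.5
  xb <- xb > 0.5
  denom <- sum(xa) + sum(xb)
  if (denom == 0) return(NaN)
  2 * sum(xa & xb) / denom
}

# Coordinate arrays (1-based voxel indices) for a grid shape.
coord_arrays <- function(shape) {
  list(x = array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), shape),
       y = array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]), shape),
       z = array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), shape))
}
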