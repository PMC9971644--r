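#' Fit the diffusion tensor by log-linear least squares
#'
#' Voxelwise solve of `ln S = ln S0 - b g' D g` over the selected forward
#' volumes (reverse-phase-encode volumes are always excluded). The design
#' matrix is shared across voxels, so the ordinary least-squares solution is
#' a single matrix product; an optional one-iteration weighted refit with
#' weights `S^2` (the standard heteroscedasticity correction for
#' log-transformed magnitudes) is available. Voxels with any non-positive
#' signal among the fitted volumes are invalid (`NaN` tensors).
#'
#' @param series List of `volume_grid`s in acquisition order.
#' @param scheme The matching [diffusion_scheme()].
#' @param shells Optional numeric vector of b-values to fit (b = 0 volumes
#'   are always included); default uses every forward shell.
#' @param mask Optional binary `volume_grid` restricting the fit.
#' @param weighted One-iteration `S^2`-weighted refit after the OLS solve.
#' @return A list of class `tensor_maps` with `tensor_field` (4D array, 6
#'   components xx, yy, zz, xy, xz, yz, mm^2/s), `s0_map`, `validity_mask`,
#'   `voxel_dims`; pass to [tensor_scalars()] for FA/MD/AD/RD.
#' @export
fit_tensor <- function(series, scheme, shells = NULL, mask = NULL,
                       weighted = FALSE) {
  stopifnot(inherits(scheme, "diffusion_scheme"))
  if (length(series) != length(scheme$bvals))
    stop("series length does not match the diffusion scheme")
  do.call(assert_same_grid, c(series, list(.what = "diffusion volumes")))
  keep <- !scheme$reverse
  if (!is.null(shells)) keep <- keep & (scheme$bvals == 0 | scheme$bvals %in% shells)
  b <- scheme$bvals[keep]
  g <- scheme$bvecs[, keep, drop = FALSE]
  if (sum(keep) < 7) stop("need at least 7 volumes (6 directions plus b0) to fit a tensor")
  X <- cbind(1, -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
             -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
             -2 * b * g[2, ] * g[3, ])
  if (qr(X)$rank < 7) stop("rank-deficient design matrix: directions are not independent")
  sh <- dim(series[[1L]]$data)
  vd <- series[[1L]]$voxel_dims
  voxels <- if (!is.null(mask)) which(mask$data > 0.5) else seq_len(prod(sh))
  S <- vapply(series[keep], function(v) v$data[voxels],
              numeric(length(voxels)))  # nvox x nvol
  if (is.null(dim(S))) S <- matrix(S, nrow = length(voxels))
  ok <- rowSums(S <= 0) == 0
  beta <- matrix(NaN, length(voxels), 7)
  if (any(ok)) {
    lnS <- log(S[ok, , drop = FALSE])
    beta[ok, ] <- lnS %*% X %*% solve(crossprod(X))
    if (weighted) {
      w <- S[ok, , drop = FALSE]^2
      bw <- beta[ok, , drop = FALSE]
      for (i in seq_len(nrow(bw))) {
        wi <- w[i, ]
        xtw <- t(X * wi)
        bw[i, ] <- solve(xtw %*% X, xtw %*% lnS[i, ])
      }
      beta[ok, ] <- bw
    }
  }
  tf <- array(NaN, c(sh, 6L))
  s0 <- array(NaN, sh)
  valid <- array(0L, sh)
  npx <- prod(sh)
  for (k in 1:6) tf[voxels + (k - 1) * npx] <- beta[, k + 1]
  s0[voxels] <- exp(beta[, 1])
  valid[voxels[ok]] <- 1L
  structure(list(tensor_field = tf,
                 s0_map = volume_grid(s0, vd),
                 validity_mask = volume_grid(valid, vd),
                 voxel_dims = vd),
            class = "tensor_maps")
}

# Closed-form eigenvalues of symmetric 3x3 matrices, vectorised over voxels
# (trigonometric solution of the characteristic polynomial). `comp` is an
# n x 6 matrix (xx, yy, zz, xy, xz, yz); returns n x 3, descending.
sym3_eigenvalues <- function(comp) {
  a11 <- comp[, 1]; a22 <- comp[, 2]; a33 <- comp[, 3]
  a12 <- comp[, 4]; a13 <- comp[, 5]; a23 <- comp[, 6]
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  lam <- matrix(q, nrow = length(q), ncol = 3)  # isotropic/degenerate default
  nz <- which(p > 0 & is.finite(p))
  if (length(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b13 <- a13[nz] / p[nz]; b23 <- a23[nz] / p[nz]
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1 <- q[nz] + 2 * p[nz] * cos(phi)
    l3 <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    lam[nz, 1] <- l1
    lam[nz, 3] <- l3
    lam[nz, 2] <- 3 * q[nz] - l1 - l3
  }
  lam
}

#' Rotationally invariant tensor scalars
#'
#' Computes the eigenvalue-based scalar maps from a fitted tensor field:
#' mean diffusivity `MD = (l1+l2+l3)/3`, axial diffusivity `AD = l1`,
#' radial diffusivity `RD = (l2+l3)/2`, and fractional anisotropy
#' `FA = sqrt(3/2) * sqrt(sum((l_i - MD)^2)) / sqrt(sum(l_i^2))`.
#' Negative eigenvalues (a noise artefact) are clamped to zero before the
#' scalars are formed; the zero tensor has FA defined as 0.
#'
#' @param t A `tensor_maps` object from [fit_tensor()], or a bare 4D
#'   tensor-component array.
#' @param voxel_dims Voxel dimensions, required when `t` is a bare array.
#' @return The `tensor_maps` object with `fa_map`, `md_map`, `ad_map`,
#'   `rd_map` `volume_grid`s filled in (or a fresh list when given an
#'   array).
#' @export
tensor_scalars <- function(t, voxel_dims = NULL) {
  if (is.array(t)) {
    if (is.null(voxel_dims)) stop("'voxel_dims' required for a bare tensor array")
    t <- structure(list(tensor_field = t, voxel_dims = voxel_dims),
                   class = "tensor_maps")
  }
  tf <- t$tensor_field
  sh <- dim(tf)[1:3]
  comp <- matrix(tf, nrow = prod(sh), ncol = 6)
  lam <- sym3_eigenvalues(comp)
  lam <- pmax(lam, 0)
  dim(lam) <- c(prod(sh), 3)
  md <- rowMeans(lam)
  ad <- lam[, 1]
  rd <- (lam[, 2] + lam[, 3]) / 2
  ss <- lam[, 1]^2 + lam[, 2]^2 + lam[, 3]^2
  dev <- (lam[, 1] - md)^2 + (lam[, 2] - md)^2 + (lam[, 3] - md)^2
  fa <- ifelse(ss > 0, sqrt(1.5) * sqrt(dev) / sqrt(ss), 0)
  fa[!is.finite(comp[, 1])] <- NaN
  md[!is.finite(comp[, 1])] <- NaN
  ad[!is.finite(comp[, 1])] <- NaN
  rd[!is.finite(comp[, 1])] <- NaN
  vd <- t$voxel_dims
  t$fa_map <- volume_grid(array(fa, sh), vd)
  t$md_map <- volume_grid(array(md, sh), vd)
  t$ad_map <- volume_grid(array(ad, sh), vd)
  t$rd_map <- volume_grid(array(rd, sh), vd)
  t
}
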