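#' Default per-tissue generating parameters for the phantom
#'
#' One row per tissue class, giving the piecewise-constant FLAIR intensity
#' and the means of the quantitative ground-truth parameters: T2 and T1 (ms),
#' proton density (arbitrary units), MTsat (per-excitation saturation,
#' fraction), NODDI fractions (vic, viso, ODI) and tensor eigenvalues
#' (`d_ax`, `d_rd`, mm^2/s; equal values mean an isotropic tensor). Values
#' are typical 3T white/grey matter literature values; lesions are FLAIR
#' hyperintense with prolonged T2/T1 and reduced MTsat and neurite density,
#' as seen in demyelinating disease.
#'
#' @return A data frame with one row per tissue label (1 CSF, 2 NAWM,
#'   3 cortical GM, 4 subcortical GM, 5 brainstem, 6 WML).
#' @export
tissue_defaults <- function() {
  data.frame(
    tissue = c("csf", "nawm", "cortical_gm", "subcortical_gm", "brainstem", "wml"),
    label  = 1:6,
    flair  = c(20, 100, 120, 110, 100, 250),
    t2     = c(2000, 80, 100, 90, 80, 120),
    pd     = c(1000, 700, 850, 800, 700, 900),
    t1     = c(4000, 1000, 1400, 1200, 1000, 1500),
    mtsat  = c(0.001, 0.040, 0.025, 0.030, 0.038, 0.020),
    vic    = c(0.02, 0.60, 0.45, 0.50, 0.55, 0.45),
    viso   = c(0.95, 0.10, 0.15, 0.15, 0.10, 0.25),
    odi    = c(0.90, 0.20, 0.50, 0.40, 0.25, 0.30),
    d_ax   = c(3.0, 1.0, 0.8, 0.8, 1.0, 1.0) * 1e-3,
    d_rd   = c(3.0, 0.45, 0.8, 0.8, 0.5, 0.7) * 1e-3,
    stringsAsFactors = FALSE
  )
}

#' Phantom configuration
#'
#' Parameters of the synthetic multi-modal phantom. Defaults are the study
#' conditions every downstream stage is tested under: a 64^3 grid at 1 mm
#' isotropic resolution, Rician noise at SNR 40 (tissue mean over Gaussian
#' channel SD), 2% within-tissue biological variation on the quantitative
#' parameter maps, five lesions of 2-4 voxel radius, the dual-echo TEs
#' 9.6/96 ms, the MT triplet settings TR 30/30/15 ms, flip 5/5/18 deg, TE
#' 1.54/4.55/8.49 ms, and the multi-shell diffusion scheme
#' b = 0rev(3), 0(14), 200(3), 500(6), 1000(64), 2000(64) s/mm^2.
#'
#' @param grid_shape Integer length-3; each dimension at least 32.
#' @param voxel_dims Voxel dimensions in mm.
#' @param n_lesions Number of spherical white-matter lesions.
#' @param lesion_radius Length-2 range of lesion radii, voxels.
#' @param snr Signal-to-noise ratio of generated images (reference tissue
#'   mean divided by the Gaussian channel SD of the Rician model); `Inf`
#'   disables noise.
#' @param tissue_cv Coefficient of within-tissue Gaussian variation applied
#'   to the quantitative ground-truth maps (not to the FLAIR image, which is
#'   piecewise constant per tissue so segmentation identities are exact).
#' @param seed Integer seed; the phantom is reproducible from (config, seed).
#' @param tissue_params Data frame as [tissue_defaults()].
#' @param t2star_ms Global effective T2* (ms) driving multi-echo decay of the
#'   MT triplet; a single constant, so echo summing rescales all three MT
#'   volumes by one global factor.
#' @param dual_echo_te Dual-echo TEs, ms.
#' @param mt_acq List of MT acquisition settings (`tr_on`, `tr_off`,
#'   `tr_t1w` ms; `flip_on`, `flip_off`, `flip_t1w` degrees; `te` ms).
#' @param dwi_shells Named list mapping b-value to direction count for the
#'   forward-acquired weighted shells, plus `n_b0` forward and `n_b0_rev`
#'   reverse b = 0 volumes.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 64),
                           voxel_dims = c(1, 1, 1),
                           n_lesions = 5,
                           lesion_radius = c(2, 4),
                           snr = 40,
                           tissue_cv = 0.02,
                           seed = 1L,
                           tissue_params = tissue_defaults(),
                           t2star_ms = 50,
                           dual_echo_te = c(9.6, 96),
                           mt_acq = list(tr_on = 30, tr_off = 30, tr_t1w = 15,
                                         flip_on = 5, flip_off = 5, flip_t1w = 18,
                                         te = c(1.54, 4.55, 8.49)),
                           dwi_shells = list(n_b0_rev = 3, n_b0 = 14,
                                             weighted = c("200" = 3, "500" = 6,
                                                          "1000" = 64, "2000" = 64))) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 32L))
    stop("'grid_shape' must be three integers, each at least 32")
  if (length(lesion_radius) != 2L || any(lesion_radius <= 0) ||
      lesion_radius[1] > lesion_radius[2])
    stop("'lesion_radius' must be an increasing positive range")
  if (snr <= 0) stop("'snr' must be positive (use Inf for noiseless)")
  structure(list(grid_shape = grid_shape, voxel_dims = as.numeric(voxel_dims),
                 n_lesions = n_lesions, lesion_radius = lesion_radius,
                 snr = snr, tissue_cv = tissue_cv, seed = as.integer(seed),
                 tissue_params = tissue_params, t2star_ms = t2star_ms,
                 dual_echo_te = dual_echo_te, mt_acq = mt_acq,
                 dwi_shells = dwi_shells),
            class = "phantom_config")
}

# Tissue geometry: normalised ellipsoidal radius r for every voxel, plus the
# stalk cylinder. Concentric shells define CSF core, subcortical GM, NAWM and
# cortical GM rim; a cylindrical brainstem stalk extends below the ellipsoid.
phantom_geometry <- function(cfg) {
  sh <- cfg$grid_shape
  co <- coord_arrays(sh)
  ctr <- (sh + 1) / 2
  semi <- c(0.92 * sh[1] / 2, 0.85 * sh[2] / 2, 0.70 * sh[3] / 2)
  r <- sqrt(((co$x - ctr[1]) / semi[1])^2 +
            ((co$y - ctr[2]) / semi[2])^2 +
            ((co$z - ctr[3]) / semi[3])^2)
  stalk <- sqrt((co$x - ctr[1])^2 + (co$y - ctr[2])^2) <= max(3, 0.07 * sh[1]) &
    co$z >= 2 & co$z <= ctr[3] - 0.55 * semi[3]
  list(r = r, stalk = stalk, coords = co, centre = ctr, semi = semi)
}

# Periventricular lesion-probability template: smoothed indicator of the
# inner NAWM band, peak-normalised to [0, 1]. Emulates a lesion distribution
# prior concentrated around the ventricles.
periventricular_template <- function(label, r) {
  ind <- array(0, dim(label))
  ind[label == 2 & r <= 0.62] <- 1
  sm <- gaussian_smooth_3d(ind, fwhm = 4)
  mx <- max(sm)
  if (mx > 0) sm <- sm / mx
  sm
}

#' Generate the phantom label map and ground-truth parameter maps
#'
#' Builds the concentric-ellipsoid tissue layout (CSF core, subcortical GM,
#' NAWM shell, cortical GM rim, brainstem stalk), places spherical WM lesions
#' inside NAWM where the periventricular template exceeds 0.5, and fills the
#' per-tissue ground-truth parameter maps (T2, PD, T1, MTsat, NODDI
#' fractions, diffusion tensors) from the configured tissue means, with
#' optional within-tissue Gaussian variation.
#'
#' @param cfg A [phantom_config()].
#' @return A ground-truth list with `label_map`, `lesion_mask`, `template`,
#'   `splenium_mask`, the parameter maps (`t2_map`, `pd_map`, `t1_map`,
#'   `mtsat_map`, `vic_map`, `viso_map`, `odi_map`), `tensor_field`
#'   (4D array, 6 unique components xx, yy, zz, xy, xz, yz in mm^2/s) and
#'   `brain_mask`.
#' @export
make_labelmap <- function(cfg) {
  sh <- cfg$grid_shape
  geo <- phantom_geometry(cfg)
  r <- geo$r
  label <- array(0L, sh)
  label[r <= 1] <- 3L          # cortical GM rim
  label[r <= 0.78] <- 2L       # NAWM shell
  label[r <= 0.40] <- 4L       # subcortical GM
  label[r <= 0.24] <- 1L       # CSF core
  label[geo$stalk & label == 0L] <- 5L

  template <- periventricular_template(label, r)

  lesion <- array(0L, sh)
  with_seed(cfg$seed, {
    if (cfg$n_lesions > 0) {
      rmax <- cfg$lesion_radius[2]
      cand <- which(label == 2L & template > 0.5)
      if (length(cand) == 0) stop("no template-supported NAWM for lesion placement")
      co <- geo$coords
      centres <- matrix(numeric(0), ncol = 3)
      placed <- 0
      attempts <- 0
      while (placed < cfg$n_lesions) {
        attempts <- attempts + 1
        if (attempts > 500 * cfg$n_lesions)
          stop("lesion radius exceeds the available NAWM shell thickness")
        rad <- stats::runif(1, cfg$lesion_radius[1], cfg$lesion_radius[2])
        i <- cand[sample.int(length(cand), 1)]
        cx <- co$x[i]; cy <- co$y[i]; cz <- co$z[i]
        if (nrow(centres) > 0 &&
            min(sqrt(rowSums(sweep(centres, 2, c(cx, cy, cz))^2))) < 2 * rmax + 2)
          next
        sph <- sphere_index(sh, c(cx, cy, cz), rad)
        if (length(sph) == 0 || any(label[sph] != 2L)) next  # sphere must sit in NAWM
        lesion[sph] <- 1L
        label[sph] <- 6L
        centres <- rbind(centres, c(cx, cy, cz))
        placed <- placed + 1
      }
    }
  })

  # splenium: compact posterior NAWM blob used for g-ratio calibration
  ctr <- geo$centre
  sp_ctr <- c(ctr[1], ctr[2] + 0.55 * geo$semi[2], ctr[3])
  sp <- sphere_index(sh, sp_ctr, 3.5)
  sp <- sp[label[sp] == 2L]
  splenium <- array(0L, sh)
  splenium[sp] <- 1L

  gt <- list(label_map = volume_grid(label, cfg$voxel_dims),
             lesion_mask = volume_grid(lesion, cfg$voxel_dims),
             template = volume_grid(template, cfg$voxel_dims),
             splenium_mask = volume_grid(splenium, cfg$voxel_dims),
             brain_mask = volume_grid(array(as.integer(label > 0L), sh),
                                      cfg$voxel_dims))
  gt <- fill_parameter_maps(gt, cfg)
  gt$tensor_field <- build_tensor_field(gt, cfg, geo)
  gt$geometry <- geo
  gt
}

# Voxel indices of a sphere (Euclidean voxel distance <= radius) clipped to
# the grid.
sphere_index <- function(sh, centre, radius) {
  rr <- ceiling(radius)
  xs <- max(1, floor(centre[1] - rr)):min(sh[1], ceiling(centre[1] + rr))
  ys <- max(1, floor(centre[2] - rr)):min(sh[2], ceiling(centre[2] + rr))
  zs <- max(1, floor(centre[3] - rr)):min(sh[3], ceiling(centre[3] + rr))
  g <- expand.grid(x = xs, y = ys, z = zs)
  d2 <- (g$x - centre[1])^2 + (g$y - centre[2])^2 + (g$z - centre[3])^2
  g <- g[d2 <= radius^2, , drop = FALSE]
  (g$z - 1L) * sh[1] * sh[2] + (g$y - 1L) * sh[1] + g$x
}

# Fill per-tissue parameter maps from tissue means (+ within-tissue Gaussian
# variation at cfg$tissue_cv, seeded); fractions are clipped to [0, 1].
fill_parameter_maps <- function(gt, cfg) {
  label <- gt$label_map$data
  tp <- cfg$tissue_params
  params <- c("t2", "pd", "t1", "mtsat", "vic", "viso", "odi")
  frac <- c(mtsat = TRUE, vic = TRUE, viso = TRUE, odi = TRUE,
            t2 = FALSE, pd = FALSE, t1 = FALSE)
  bgval <- c(t2 = 1000, pd = 0, t1 = 1000, mtsat = 0, vic = 0, viso = 0, odi = 0)
  with_seed(cfg$seed + 1L, {
    for (p in params) {
      m <- array(bgval[[p]], dim(label))
      for (k in seq_len(nrow(tp))) {
        idx <- label == tp$label[k]
        n <- sum(idx)
        if (n == 0) next
        mu <- tp[[p]][k]
        vals <- if (cfg$tissue_cv > 0)
          mu * (1 + cfg$tissue_cv * stats::rnorm(n)) else rep(mu, n)
        vals <- pmax(vals, 1e-6 * max(mu, 1e-12))
        if (frac[[p]]) vals <- pmin(vals, 1)
        m[idx] <- vals
      }
      gt[[paste0(p, "_map")]] <- volume_grid(m, cfg$voxel_dims)
    }
  })
  gt
}

# Per-voxel diffusion tensors: diag(d_ax, d_rd, d_rd) with the principal axis
# along x for the oriented tissues (NAWM, brainstem, WML); GM and CSF are
# isotropic. Three high-FA tubes (x-, y- and z-oriented) are embedded in the
# NAWM shell; these double as tract cores.
build_tensor_field <- function(gt, cfg, geo) {
  sh <- cfg$grid_shape
  label <- gt$label_map$data
  tp <- cfg$tissue_params
  tf <- array(0, c(sh, 6L))  # xx, yy, zz, xy, xz, yz
  for (k in seq_len(nrow(tp))) {
    idx <- label == tp$label[k]
    if (!any(idx)) next
    ax <- tp$d_ax[k]; rd <- tp$d_rd[k]
    comp <- if (tp$tissue[k] %in% c("nawm", "brainstem", "wml"))
      c(ax, rd, rd) else c((ax + 2 * rd) / 3, (ax + 2 * rd) / 3, (ax + 2 * rd) / 3)
    tf[, , , 1][idx] <- comp[1]
    tf[, , , 2][idx] <- comp[2]
    tf[, , , 3][idx] <- comp[3]
  }
  for (tube in phantom_tubes(cfg, geo)) {
    idx <- tube$core & label == 2L
    ev <- c(1.7e-3, 0.2e-3)
    d <- c(ev[2], ev[2], ev[2]); d[tube$axis] <- ev[1]
    tf[, , , 1][idx] <- d[1]
    tf[, , , 2][idx] <- d[2]
    tf[, , , 3][idx] <- d[3]
  }
  tf
}

# Tube definitions shared by the tensor field and the tract probability maps.
phantom_tubes <- function(cfg, geo) {
  sh <- cfg$grid_shape
  co <- geo$coords
  ctr <- geo$centre
  semi <- geo$semi
  mk <- function(axis, c1, c2, name) {
    ax2 <- setdiff(1:3, axis)
    p <- list(co$x, co$y, co$z)
    d2 <- (p[[ax2[1]]] - c1)^2 + (p[[ax2[2]]] - c2)^2
    list(name = name, axis = axis, core = d2 <= 2^2, dist2 = d2)
  }
  list(mk(1, ctr[2] + 0.55 * semi[2], ctr[3], "splenium_tract"),
       mk(2, ctr[1] - 0.30 * semi[1], ctr[3], "arcuate"),
       mk(3, ctr[1] + 0.30 * semi[1], ctr[2], "corticospinal"))
}

#' Generate template, skeleton and tract probability maps for a phantom
#'
#' Completes a ground-truth object with the lesion-distribution probabilistic
#' template (smoothed periventricular NAWM indicator in `[0, 1]`), a
#' white-matter skeleton mask (medial shell of the NAWM compartment), and a
#' small set of tract connection-probability maps (tubes with Gaussian
#' cross-section profiles in `[0, 1]`).
#'
#' @param gt Ground truth from [make_labelmap()].
#' @param cfg The [phantom_config()] used to build it.
#' @return `gt` with `template`, `skeleton_mask` and `tract_prob_maps` set.
#' @export
make_template_skeleton_tracts <- function(gt, cfg) {
  geo <- if (!is.null(gt$geometry)) gt$geometry else phantom_geometry(cfg)
  label <- gt$label_map$data
  r <- geo$r
  gt$template <- volume_grid(periventricular_template(label, r), cfg$voxel_dims)
  skel <- array(0L, cfg$grid_shape)
  skel[label == 2L & r >= 0.55 & r <= 0.64] <- 1L
  gt$skeleton_mask <- volume_grid(skel, cfg$voxel_dims)
  tracts <- list()
  for (tube in phantom_tubes(cfg, geo)) {
    prob <- exp(-tube$dist2 / (2 * 1.5^2))
    prob[label == 0L] <- 0
    prob[tube$dist2 > 4^2] <- 0
    tracts[[tube$name]] <- volume_grid(prob, cfg$voxel_dims)
  }
  gt$tract_prob_maps <- tracts
  gt
}

#' Simulate a FLAIR image from phantom ground truth
#'
#' Piecewise-constant tissue intensities with CSF suppressed and lesions
#' hyperintense, plus Rician noise at the configured SNR (reference: NAWM
#' mean intensity). Noiseless generation (`snr = Inf`) yields an exactly
#' piecewise-constant image.
#'
#' @param gt Ground truth from [make_labelmap()].
#' @param cfg A [phantom_config()].
#' @param snr Override of `cfg$snr`.
#' @return A `volume_grid`.
#' @export
make_flair <- function(gt, cfg, snr = cfg$snr) {
  if (snr <= 0) stop("'snr' must be positive")
  label <- gt$label_map$data
  tp <- cfg$tissue_params
  img <- array(0, dim(label))
  for (k in seq_len(nrow(tp))) img[label == tp$label[k]] <- tp$flair[k]
  sd <- tp$flair[tp$tissue == "nawm"] / snr
  if (is.finite(snr))
    img <- with_seed(cfg$seed + 2L, array(add_rician_noise(img, sd), dim(label)))
  volume_grid(img, cfg$voxel_dims)
}

#' Simulate the dual-echo (PD-weighted / T2-weighted) pair
#'
#' Mono-exponential decay `S(TE) = PD * exp(-TE / T2)` evaluated at the two
#' configured echo times (defaults 9.6 and 96 ms), with optional Rician
#' noise.
#'
#' @inheritParams make_flair
#' @return A list with `pd_echo` (short TE) and `t2w_echo` (long TE)
#'   `volume_grid`s and the echo times `te`.
#' @export
make_dual_echo <- function(gt, cfg, snr = cfg$snr) {
  t2 <- gt$t2_map$data
  pd <- gt$pd_map$data
  if (any(t2 <= 0)) stop("ground-truth T2 must be strictly positive")
  te <- cfg$dual_echo_te
  s1 <- pd * exp(-te[1] / t2)
  s2 <- pd * exp(-te[2] / t2)
  if (is.finite(snr)) {
    sd <- mean(s1[gt$label_map$data == 2L]) / snr
    with_seed(cfg$seed + 3L, {
      s1 <- array(add_rician_noise(s1, sd), dim(t2))
      s2 <- array(add_rician_noise(s2, sd), dim(t2))
    })
  }
  list(pd_echo = volume_grid(s1, cfg$voxel_dims),
       t2w_echo = volume_grid(s2, cfg$voxel_dims),
       te = te)
}

#' Simulate the MT-on / MT-off / T1-weighted multi-echo triplet
#'
#' Per-echo signals follow the rational spoiled-gradient-echo approximation
#' `S = A * alpha * TR * R1 / (TR * R1 + alpha^2 / 2 + delta)` with
#' `delta = 0` for the MT-off and T1-weighted volumes and
#' `delta = gt$mtsat_map` for MT-on; `alpha` in radians, `R1 = 1/T1` in 1/ms.
#' Echoes decay by `exp(-TE / T2*)` with a single global T2*, so echo
#' summing rescales all three volumes by one common factor and the
#' downstream inversion recovers MTsat and R1 exactly (amplitude up to that
#' global scale).
#'
#' @inheritParams make_flair
#' @return An [mt_triplet()] carrying the per-echo volumes and the
#'   acquisition metadata from `cfg$mt_acq`.
#' @export
make_mt_triplet <- function(gt, cfg, snr = cfg$snr) {
  acq <- cfg$mt_acq
  if (any(c(acq$tr_on, acq$tr_off, acq$tr_t1w) <= 0)) stop("TR must be positive")
  if (any(c(acq$flip_on, acq$flip_off, acq$flip_t1w) <= 0)) stop("flip angle must be positive")
  a <- gt$pd_map$data
  r1 <- 1 / gt$t1_map$data
  delta <- gt$mtsat_map$data
  base <- function(alpha_deg, tr, dl) {
    al <- alpha_deg * pi / 180
    a * al * tr * r1 / (tr * r1 + al^2 / 2 + dl)
  }
  decay <- exp(-acq$te / cfg$t2star_ms)
  mk <- function(sig) lapply(decay, function(f)
    volume_grid(sig * f, cfg$voxel_dims))
  on  <- mk(base(acq$flip_on,  acq$tr_on,  delta))
  off <- mk(base(acq$flip_off, acq$tr_off, 0))
  t1w <- mk(base(acq$flip_t1w, acq$tr_t1w, 0))
  if (is.finite(snr)) {
    sd <- mean(off[[1L]]$data[gt$label_map$data == 2L]) / snr
    noisify <- function(vols) lapply(vols, function(v) {
      v$data <- array(add_rician_noise(v$data, sd), dim(v$data)); v
    })
    with_seed(cfg$seed + 4L, {
      on <- noisify(on); off <- noisify(off); t1w <- noisify(t1w)
    })
  }
  mt_triplet(mt_on = on, mt_off = off, t1w = t1w,
             tr_on = acq$tr_on, tr_off = acq$tr_off, tr_t1w = acq$tr_t1w,
             flip_on = acq$flip_on, flip_off = acq$flip_off,
             flip_t1w = acq$flip_t1w, te = acq$te)
}

#' Simulate the multi-shell diffusion series
#'
#' Generates `S = S0 * exp(-b * g' D g)` per volume from the ground-truth
#' tensor field, with the configured shell structure (defaults: 3 reverse
#' b=0 + 14 forward b=0 + 3/6/64/64 directions at b = 200/500/1000/2000
#' s/mm^2, i.e. 151 forward volumes). Per-shell directions are approximately
#' uniform on the sphere (Fibonacci spiral with a seeded random rotation).
#' Reverse-phase-encode b=0 volumes are plain b=0 copies flagged in the
#' scheme.
#'
#' @inheritParams make_flair
#' @return A list with `series` (list of `volume_grid`s, acquisition order:
#'   reverse b0s first) and `scheme` (a [diffusion_scheme()]).
#' @export
make_dwi <- function(gt, cfg, snr = cfg$snr) {
  sh <- cfg$grid_shape
  tf <- gt$tensor_field
  if (min(tf[, , , 1:3]) < 0) stop("ground-truth tensors must be positive semi-definite")
  s0 <- gt$pd_map$data
  shl <- cfg$dwi_shells
  bvals <- c(rep(0, shl$n_b0_rev), rep(0, shl$n_b0))
  reverse <- c(rep(TRUE, shl$n_b0_rev), rep(FALSE, shl$n_b0))
  bvecs <- matrix(0, 3, length(bvals))
  dirs <- with_seed(cfg$seed + 5L, {
    lapply(shl$weighted, function(n) sphere_directions(n))
  })
  for (i in seq_along(shl$weighted)) {
    b <- as.numeric(names(shl$weighted)[i])
    n <- shl$weighted[[i]]
    bvals <- c(bvals, rep(b, n))
    reverse <- c(reverse, rep(FALSE, n))
    bvecs <- cbind(bvecs, dirs[[i]])
  }
  scheme <- diffusion_scheme(bvals, bvecs, reverse)
  dxx <- tf[, , , 1]; dyy <- tf[, , , 2]; dzz <- tf[, , , 3]
  dxy <- tf[, , , 4]; dxz <- tf[, , , 5]; dyz <- tf[, , , 6]
  sd <- if (is.finite(snr)) mean(s0[gt$label_map$data == 2L]) / snr else 0
  series <- with_seed(cfg$seed + 6L, {
    lapply(seq_along(bvals), function(v) {
      b <- bvals[v]; g <- bvecs[, v]
      s <- if (b == 0) s0 else {
        q <- g[1]^2 * dxx + g[2]^2 * dyy + g[3]^2 * dzz +
          2 * g[1] * g[2] * dxy + 2 * g[1] * g[3] * dxz + 2 * g[2] * g[3] * dyz
        s0 * exp(-b * q)
      }
      if (sd > 0) s <- array(add_rician_noise(s, sd), sh)
      volume_grid(s, cfg$voxel_dims)
    })
  })
  list(series = series, scheme = scheme)
}

#' Build a complete phantom
#'
#' Runs every generator: label map and ground truth, template/skeleton/tract
#' maps, FLAIR, dual-echo pair, MT triplet and diffusion series, plus the
#' named mask set consumed by the ROI statistics stage.
#'
#' @param cfg A [phantom_config()].
#' @param with_dwi Generate the (largest) diffusion series; disable for
#'   stages that do not need it.
#' @return A list with `gt`, `flair`, `dual_echo`, `mt`, `dwi` (or `NULL`)
#'   and `masks` (named list of binary `volume_grid`s).
#' @export
build_phantom <- function(cfg = phantom_config(), with_dwi = TRUE) {
  gt <- make_labelmap(cfg)
  gt <- make_template_skeleton_tracts(gt, cfg)
  label <- gt$label_map$data
  tiss_mask <- function(lab) volume_grid(array(as.integer(label == lab),
                                               cfg$grid_shape), cfg$voxel_dims)
  masks <- list(brain = gt$brain_mask,
                csf = tiss_mask(1L), nawm = tiss_mask(2L),
                cortical_gm = tiss_mask(3L), subcortical_gm = tiss_mask(4L),
                brainstem = tiss_mask(5L), wml = gt$lesion_mask,
                splenium = gt$splenium_mask, skeleton = gt$skeleton_mask)
  list(gt = gt,
       flair = make_flair(gt, cfg),
       dual_echo = make_dual_echo(gt, cfg),
       mt = make_mt_triplet(gt, cfg),
       dwi = if (with_dwi) make_dwi(gt, cfg) else NULL,
       masks = masks,
       cfg = cfg)
}
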