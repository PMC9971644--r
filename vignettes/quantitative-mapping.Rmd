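---
title: "Quantitative MRI mapping with msqmap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MRI mapping with msqmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msqmap)
```

# Scope

`msqmap` implements the quantitative processing stages of a longitudinal
multi-centre brain-MRI protocol for relapsing-remitting multiple sclerosis:
dual-echo T2 relaxometry, magnetisation-transfer ratio (MTR) and saturation
(MTsat) mapping, diffusion-tensor scalar maps, splenium-calibrated aggregate
g-ratio maps, FLAIR white-matter-lesion (WML) segmentation,
peak-width-of-skeletonized diffusion metrics, and ROI statistics and
volumetrics. Spatial preprocessing — registration, distortion correction,
brain extraction, cortical parcellation, NODDI fitting, tractography, TBSS
skeleton projection — is deliberately out of scope: those steps are performed
by established external tools, and `msqmap` consumes their outputs as
co-registered NIfTI-1 volumes on one voxel grid. Every multi-volume operation
asserts that shared grid before computing.

Because no imaging data are deposited with the source protocol, the package
ships a synthetic phantom generator with known ground truth. The phantom is
first-class, tested code: each processing stage is validated by exact
forward–inverse identities on noiseless phantoms and by Monte-Carlo
tolerances on noisy ones.

# Models

## Dual-echo T2

A spin-echo pair at echo times $TE_1 < TE_2$ with mono-exponential decay
$S(TE) = PD\,e^{-TE/T_2}$ gives

$$T_2 = \frac{TE_1 - TE_2}{\ln S_{T2w} - \ln S_{PD}},$$

with the short-TE echo as the PD-weighted image. Default echo times are
9.6 and 96 ms. Voxels with non-positive signal or non-decaying intensity
($S_{T2w} \ge S_{PD}$) are excluded (`NaN`), never clamped, so downstream ROI
statistics are not silently biased. Maps are stored in ms.

## MTR, apparent R1, amplitude and MTsat

The MT stage consumes a multi-echo spoiled-gradient-echo triplet — MT-on,
MT-off and a T1-weighted acquisition (defaults TR 30/30/15 ms, flip
5/5/18°, echoes 1.54/4.55/8.49 ms). Echoes are summed to raise SNR.
MTR is the fractional signal drop $(S_{off}-S_{on})/S_{off}$.

For MTsat, the rational small-flip-angle approximation of the spoiled
gradient echo signal,

$$S \approx A\,\alpha\,\frac{TR\,R_1}{TR\,R_1 + \alpha^2/2 + \delta},$$

is solved for the apparent relaxation rate $R_1$ and amplitude $A$ from the
two $\delta = 0$ acquisitions (MT-off as the PD-weighted, low-flip input; the
18° volume as the T1-weighted input), then inverted for the per-excitation
saturation of the MT-on volume:

$$\delta = \left(\frac{A\,\alpha}{S_{MT}} - 1\right) R_1\,TR - \frac{\alpha^2}{2}.$$

$\delta$ and $R_1$ are invariant to global signal scaling; $A$ is
equivariant — properties the test suite asserts directly. MTsat is stored as
a fraction; the CLI offers percent units for display. MTR and MTsat maps are
range-thresholded to $[0, 1]$ by exclusion, discarding implausible voxels
before ROI statistics. The quantitative T1 map is $1/R_1$ from the same
solve, in ms. No B1 correction is attempted (a known limitation of MTR/MTsat
at 3T).

The phantom generates MT signals from this same rational approximation, so
noiseless recovery of $\delta$, $R_1$ and (up to one global scale from echo
summing) $A$ is exact by construction. This separates implementation
correctness from model-approximation error, which would otherwise be
entangled in every tolerance.

## Diffusion tensor

With $\ln S = \ln S_0 - b\,g^T D g$, the tensor is estimated by ordinary
least squares on the log signal with a design matrix shared across voxels
(one matrix product for the whole volume), with an optional one-iteration
$S^2$-weighted refit. Reverse-phase-encode volumes are excluded; all forward
shells (b = 200–2000 s/mm²) enter the default fit, with a shell selector
available since protocols differ on whether high-b shells belong in a tensor
fit. Eigenvalues come from the closed-form trigonometric solution for
symmetric 3×3 matrices, vectorised over voxels; negative eigenvalues are
clamped to zero before the scalars

$$MD = \bar\lambda, \quad AD = \lambda_1, \quad RD = \tfrac{\lambda_2+\lambda_3}{2},
\quad FA = \sqrt{\tfrac32}\,\frac{\|\lambda - \bar\lambda\|}{\|\lambda\|},$$

and FA of the zero tensor is defined as 0. Tests compare this vectorised
path against an independent per-voxel `lm()` + `base::eigen()` route
(agreement below $10^{-3}$ in FA) and assert rotation invariance at
$10^{-10}$.

## Aggregate g-ratio

The aggregate g-ratio combines the MTsat map with NODDI volume fractions
(intracellular `vic`, isotropic `viso`, supplied as inputs). Myelin volume
fraction is modelled as $MVF = k\,\delta$; the constant $k$ is calibrated by
assuming $g = 0.7$ in the splenium of the corpus callosum:

$$k = \frac{1}{\delta_{app}}\left(1 - \frac{1}{1 + c\,(1-\nu_{iso})\,\nu_{ic}}\right),
\qquad c = \frac{1}{0.7^2} - 1,$$

computed voxelwise over the splenium mask, averaged per subject/session,
then across calibration subjects (the splenium-mean alternative is available
via `per_voxel = FALSE`; the voxelwise reading is the default as the closest
reading of "mean k across the splenium"). Then

$$AVF = (1 - MVF)(1 - \nu_{iso})\,\nu_{ic}, \qquad
g = \sqrt{\frac{1}{1 + MVF/AVF}}.$$

The square-root form is the standard aggregate g-ratio and is the only form
algebraically consistent with the calibration constant: at $g = 0.7$,
$MVF/AVF = 1/0.7^2 - 1$ exactly. The test suite reproduces this identity
end to end: calibrating and then mapping returns mean splenium $g = 0.7$ to
$10^{-6}$ for uniform maps and to $10^{-3}$ for heterogeneous maps (the gap
being Jensen's inequality acting on the voxelwise average of $k$).
Calibration ignores lesion masks by design — calibration subjects are
healthy controls. G-ratio ROI statistics are restricted to NAWM and WML,
where the underlying white-matter model is meaningful.

## FLAIR lesion segmentation

Candidates are brain voxels brighter than $\mu + 1.69\sigma$, with $\mu$ and
$\sigma$ computed over the brain mask of the raw image (lesions included).
A lesion-distribution probabilistic template excludes hyperintensities where
pathology is unlikely; the default reads the template as a support mask
(value $> 0$), with probability-weighted multiplication available by
configuration, since the published wording is exclusionary. Refinement
smooths the candidate map (Gaussian, FWHM 1 voxel by default — the smallest
kernel that regularises single-voxel noise without erasing 2-voxel-radius
lesions; the width is configurable as the source protocol does not state
it), removes voxels whose raw-FLAIR z-score is below 0.95, max-normalises
the smoothed map and removes values below 0.1, then binarises. The 0.1
threshold is interpreted on the max-normalised map because raw FLAIR units
are scanner-arbitrary; a fixed raw-intensity reading would be meaningless
across scanners. The z-score and 0.1 thresholds are applied sequentially, as
printed. All thresholds are relative, so the mask is exactly invariant to
global intensity scaling, and each stage's support is a subset of the
previous one — both tested properties.

## Peak width of skeletonized metrics

Scalar maps are sampled on a supplied white-matter skeleton at voxels with
FA ≥ 0.2 (non-WM exclusion) and FA ≥ 0.3 (CSF partial-volume exclusion; the
second subsumes the first, but both are applied for fidelity to the
published two-step procedure). The metric is the 95th minus 5th percentile
of the sampled values (PSMD for MD, and analogues for AD, RD, FA, ICVF,
ISOVF, ODI) under the linear-interpolation percentile convention (R
`quantile` type 7) — recorded explicitly because percentile conventions
differ across ecosystems and change results at small sample sizes.

## ROI statistics and volumes

Probabilistic masks are thresholded at 0.5, binarised, and eroded by a
1.4 mm spherical kernel (voxel offsets with centre distance ≤ 1.4 mm; at
1 mm isotropic voxels this is the 6-connected cross, since diagonal
neighbours lie at $\sqrt2 \approx 1.414$ mm), with WML masks exempt from
erosion. Summaries are mean, median, IQR (p75 − p25, linear interpolation),
sample ($n-1$) standard deviation — population SD would also have been
defensible; sample SD is the default of the surrounding analysis
ecosystems — and CV = sd/mean; weighted means use tract
connection-probability maps as weights. `NaN` (invalid) voxels are excluded
throughout, never zero-filled. Volumes are voxel count × voxel volume in
mm³; longitudinal change is follow-up minus baseline, signed.

# The phantom

The generator emulates the protocol's inputs on one 64³ grid at 1 mm
isotropic (all stages assume co-registration, so a single grid loses
nothing). Geometry is a concentric-ellipsoid head — CSF core, subcortical
GM, NAWM shell, cortical GM rim, a brainstem stalk — with spherical lesions
(default five, radius 2–4 voxels) placed where a periventricular
probabilistic template exceeds 0.5, entirely inside NAWM. Three high-FA
tubes embedded in the NAWM shell serve as tracts and as the high-anisotropy
target for noisy FA-bias tests; a medial NAWM shell provides the skeleton; a
compact posterior NAWM blob provides the splenium calibration region.

Tissue parameter means are typical 3T literature values
(`tissue_defaults()`): e.g. NAWM T2 80 ms, T1 1000 ms, MTsat 4%,
vic 0.6, viso 0.1, tensor eigenvalues (1.0, 0.45, 0.45)×10⁻³ mm²/s; lesions
are FLAIR-hyperintense with prolonged relaxation times and reduced MTsat and
neurite density. Quantitative maps carry 2% within-tissue Gaussian variation
by default — enough heterogeneity to exercise averaging code without
dominating Jensen gaps; the FLAIR image itself is piecewise constant per
tissue so that the noiseless segmentation identity is exact. Noise is
Rician (two independent Gaussian channels on the complex signal before
magnitude), the standard model for magnitude MR images, at SNR 40 by
default, defined as reference-tissue mean over the Gaussian channel SD. The
diffusion scheme reproduces the protocol's shell structure — 3 reverse and
14 forward b = 0 volumes plus 3/6/64/64 directions at b = 200/500/1000/2000
s/mm² (151 forward volumes) — with per-shell Fibonacci-spiral directions
under a seeded random rotation; the published gradient vectors themselves
are not printed anywhere, so only the shell sizes are matched. Everything is
reproducible from `(phantom_config, seed)`.

What the phantom does **not** emulate: anatomically realistic geometry,
B0/B1 field inhomogeneity, motion, eddy-current or susceptibility
distortion, partial-volume mixtures at tissue boundaries, multi-compartment
T2 decay, or deviations of real signals from the rational MT approximation.
Passing tests therefore demonstrate correctness of the implementations and
robustness to thermal noise at realistic SNR — not performance on clinical
data, where those unmodelled effects dominate error budgets.

# Numerical choices and degenerate inputs

- Invalidity is encoded as `NaN` plus a validity mask; every summariser
  excludes `NaN` and reports counts. Exclusion beats clamping because
  clamped values silently bias ROI means.
- The T2 formula uses natural logarithms (decay physics).
- Eigenvalue computation clamps the `acos` argument to $[-1, 1]$ and treats
  the isotropic case ($p \to 0$) exactly; accuracy is ~$10^{-9}$ relative,
  sufficient against the $10^{-3}$ FA oracle tolerance.
- Erosion treats voxels outside the grid as background; an erosion that
  empties a mask warns rather than erring.
- Zero-variance FLAIR images yield empty candidate maps with a warning;
  empty candidate maps flow through refinement to a valid empty result.
- Worked example sizes: tests run mostly on 32³ phantoms, with the
  end-to-end identity checks at the default 64³; these sizes give exact
  identities and stable Monte-Carlo medians (10 seeds) while keeping the
  suite quick on a single CPU.

# Known limitations

- The MT forward/inverse pair shares one approximation; quantifying the
  bias of that approximation against the full spoiled-gradient-echo signal
  equation is possible but not wired in as a default test.
- NODDI maps, skeletons, tract maps and tissue masks are consumed, not
  estimated; garbage in, garbage out.
- The lesion segmentation is a reimplementation of a thresholding pipeline
  whose manual-editing step (and its inter-rater variability) cannot be
  reproduced in code; `carry_forward_mask()` accepts externally supplied
  edit masks instead.
- Volumes are reported in native space only; no atlas-space statistics.

# A worked example

```{r example, eval = FALSE}
library(msqmap)

cfg <- phantom_config(seed = 1)        # 64^3, SNR 40, five lesions
ph  <- build_phantom(cfg)

# T2 relaxometry
t2 <- t2map_from_dual_echo(ph$dual_echo$pd_echo, ph$dual_echo$t2w_echo)

# MT maps
mt <- compute_mt_maps(ph$mt)

# tensor scalars
sc <- tensor_scalars(fit_tensor(ph$dwi$series, ph$dwi$scheme,
                                mask = ph$masks$brain))

# g-ratio with self-calibration
cal <- calibrate_k(mt$mtsat_map, ph$gt$vic_map, ph$gt$viso_map,
                   ph$masks$splenium)
g <- compute_gratio_map(compute_mvf_avf(mt$mtsat_map, ph$gt$vic_map,
                                        ph$gt$viso_map, cal))

# lesion segmentation and summaries
seg <- segment_wml(ph$flair, ph$masks$brain, ph$gt$template,
                   gt_lesions = ph$gt$lesion_mask)
roi_summary(t2$t2_map, prepare_mask(ph$masks$nawm), roi = "nawm",
            metric = "T2")
```

Or, file-based: write the phantom as a BIDS-like dataset and run the full
stage graph.

```{r pipeline, eval = FALSE}
write_phantom_dataset(ph, "dataset")
res <- run_pipeline(study_config(seed = 1), "dataset")
head(res)
```
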