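Package: msqmap
Title: Quantitative Brain MRI Mapping for Longitudinal Multiple Sclerosis Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing stages for quantitative brain MRI in longitudinal
    multiple sclerosis cohorts: dual-echo T2 relaxometry, magnetisation
    transfer ratio (MTR) and saturation (MTsat) mapping with apparent R1 and
    amplitude estimation from spoiled gradient echo triplets, diffusion tensor
    fitting with FA/MD/axial/radial scalar maps, splenium-calibrated aggregate
    g-ratio maps from MTsat and NODDI volume fractions, FLAIR white matter
    lesion segmentation by relative intensity thresholding with probabilistic
    template exclusion, peak-width-of-skeletonized diffusion metrics (PSMD and
    analogues), ROI summary statistics and tissue volumetrics, and a synthetic
    multi-modal phantom generator with known ground truth that exercises every
    stage end to end. All volumes are exchanged as NIfTI-1 with FSL-style
    bvals/bvecs for diffusion schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
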