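Package: dtiretest
Title: Test-Retest Reliability Analysis for Diffusion Tensor Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying scan-rescan (test-retest) reliability of
    diffusion tensor imaging (DTI) metrics in repeated-measures cohort
    designs. Simulates paired diffusion-weighted acquisitions with known
    between-subject and within-subject variance structure and Rician noise,
    fits the diffusion tensor per voxel by log-linear and nonlinear least
    squares, derives fractional anisotropy and mean/axial/radial
    diffusivity, extracts region-of-interest means with template-FA
    thresholding, and estimates reliability via one-way random-effects
    variance components, intraclass correlation coefficients with
    delta-method confidence intervals, Bland-Altman agreement statistics,
    and voxelwise ICC maps. A two-stream study pipeline orchestrates the
    full analysis with seeded reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
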