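Package: seedpls
Title: Seed Partial Least Squares Analysis of Structural Covariance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Seed partial least squares (PLS) analysis of whole-brain
    structural covariance for longitudinal voxel-based morphometry
    studies. Stacks cell-wise seed-voxel Pearson correlations across
    group-by-timepoint design cells, decomposes them by singular value
    decomposition into latent variables, and assesses them with
    permutation tests of the singular values and a stratified subject
    bootstrap with Procrustes alignment yielding bootstrap salience
    ratio (BSR) maps and seed-correlation confidence intervals.
    Includes total-intracranial-volume scaling, anterior/posterior
    hippocampus segmentation along the MNI y-axis, ROI volumetry,
    cluster reports from thresholded BSR maps, mixed-design ANCOVA and
    baseline group statistics, and a synthetic-data generator with
    planted latent covariance structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    car,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
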