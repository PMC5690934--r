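Package: dirqa
Title: Ground-Truth Benchmarking of Deformable Image Registration for
    Adaptive Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for commissioning and quality assurance of deformable
    image registration (DIR) in adaptive radiotherapy. Synthesizes
    head-and-neck virtual phantoms consisting of paired start-of-treatment
    and end-of-treatment CT-like volumes linked by a known, invertible
    deformation vector field (DVF), together with organ-at-risk masks and a
    single-fraction dose distribution with controllable gradient placement.
    Test DVFs are produced by a built-in multi-resolution demons
    registration or by parametric error-injection models, and scored with
    voxel-wise target registration error (TRE) maps, per-ROI TRE statistics,
    the TG-132 goal check (95% of voxels within 2 mm), DICE similarity,
    dose propagation error, cumulative dose-volume histograms, the mean DVH
    difference, registration failure flagging, and Pearson correlation of
    spatial error with dosimetric error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
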