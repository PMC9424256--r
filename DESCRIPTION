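Package: probatlas
Title: Probabilistic Functional Atlases and Individual Neural Markers
    from fMRI Localizer Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds voxelwise probabilistic functional atlases from
    individual-subject first-level fMRI statistical maps (top-fraction or
    fixed-threshold binarization followed by overlap aggregation), with
    split-half activation-stability quality control for session selection,
    parcel-constrained functional ROI analysis (leave-one-run-out
    cross-validated effect size, significant-voxel counts, split-half
    spatial-correlation stability, hemispheric lateralization), atlas
    comparison utilities, sample-size stability curves, and a synthetic
    multi-run cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
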