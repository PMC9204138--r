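Package: dwicell
Title: Region-Specific Prediction of Cell Counts from Diffusion MRI Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for relating voxel-wise diffusion MRI microstructure
    metrics (DTI and NODDI scalars) to cell counts of different cell classes
    in the brain, and for predicting those counts from the metrics alone in a
    region-specific manner. Provides a synthetic phantom-cohort generator
    with configurable region-specific metric/count relationships, a weighted
    least squares diffusion tensor fit with iterated reweighting, mask
    erosion and cubic block regridding with an inter-subject variance
    criterion for block-size selection, per-subject Pearson correlation
    matrices aggregated across subjects by Fisher Z one-sample t-tests with
    Holm-Sidak correction, and an extremely-randomized-trees prediction
    pipeline with autoencoder feature compression, leave-one-subject-out
    cross-validation, bootstrap performance distributions, and
    hemisphere/region transfer validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ranger,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
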