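Package: tissuedeform
Title: Quasi-Dense Stereo Reconstruction, Soft-Tissue Deformation Recovery
    and Vision-Based Force Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Recovers quasi-dense 3D structure of soft-tissue surfaces from
    calibrated stereo microscope images, tracks localized tissue deformation
    over time, and converts tool-induced surface displacement into an estimate
    of the force exerted at the tool tip.  Stereo correspondences are
    established from affine-covariant elliptical regions scored by region
    overlap, saliency agreement and normalized cross-correlation, densified
    locally and propagated under a surface-normal gate, then triangulated to a
    point cloud.  Deformation is measured per point against a reference
    reconstruction; points without a reliable temporal track are mapped with
    3D thin-plate splines anchored on stable features.  Tool-tip displacement
    hidden by the instrument is inferred by fitting a Gaussian indentation
    model to the surrounding displacement field and converted to force through
    a calibrated quadratic force-displacement model.  A synthetic-scene
    generator renders fully ground-truthed stereo sequences for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
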