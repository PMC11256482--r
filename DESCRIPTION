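Package: morphorad
Title: Deformation-Based Morphometry of Radiation-Induced Brain Injury in Rodent MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable deformation-based morphometry (DBM) pipeline
    for longitudinal rodent brain MRI studies of radiation injury. Takes
    anatomical T2-weighted, diffusion-weighted and pre/post-contrast T2*
    volumes in NIfTI-1 format through brain masking, bias correction,
    mean-control template construction, affine and diffeomorphic nonlinear
    registration, log-Jacobian-determinant mapping, voxel-wise permutation
    statistics with family-wise error control, atlas-resolved cluster
    naming, quantitative CBV/MD/AD/RD maps, two-way ANOVA with Fisher LSD
    post-hoc tests and Pearson correlation matrices. Ships a synthetic
    phantom cohort generator with analytic ground truth (deformations,
    diffusion tensors, blood volume) so every stage is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
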