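Package: radagree
Title: Radiomics-Based Agreement Analysis of Tumor Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates how much a set of tumor segmentations of the same
    image volumes agree, using the intraclass correlation coefficient (ICC)
    of a standardized radiomics feature panel, and compares that sensitivity
    against the conventional geometric overlap metrics: the Dice similarity
    coefficient, the surface Dice coefficient at a distance tolerance, and
    the Hausdorff distance. Provides readers for NRRD and NIfTI-1 volumes
    and masks, an image filter bank (isotropic resampling,
    Laplacian-of-Gaussian, single-level stationary 3-D wavelet
    decomposition), a 944-feature intensity/shape/texture panel with
    fixed-bin-width discretization, a two-way ANOVA ICC engine with 95%
    confidence bounds, an end-to-end screening and class-discovery pipeline,
    and a seeded synthetic tumor-phantom cohort generator for testing the
    whole workflow without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
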