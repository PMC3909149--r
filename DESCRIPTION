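Package: massdx
Title: Multiparametric MR Phantom Simulation and Diagnosis of Breast Masses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates dynamic contrast-enhanced and diffusion-weighted MR
    phantoms of benign and malignant breast masses, segments lesions with a
    two-step fuzzy c-means / gradient-vector-flow snake scheme, extracts 28
    kinetic, morphological, texture (GLCM/Haralick) and diffusion (ADC)
    features per lesion, selects a compact diagnostic subset with a hybrid
    t-test filter / genetic-algorithm SVM wrapper / ablation scheme, and
    evaluates single features, feature groups and the combined subset with
    nested stratified cross-validation across several classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    class,
    EBImage,
    jsonlite,
    yaml,
    RNifti,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
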