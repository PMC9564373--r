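Package: idlss
Title: Incremental-Dose-Interval Lung Subregion Radiomics and Dosiomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Partitions the lung into incremental-dose-interval subregions
    (IDLSS) from a planning dose distribution, extracts CT radiomics
    (first-order, shape, and five texture-matrix families over
    Laplacian-of-Gaussian and coiflet-1 wavelet image types) and dose
    features (scale-invariant 3D dose moments, dose-volume-histogram
    parameters, dose-map dosiomics) per subregion, and compares
    subregion-based against whole-lung models of acute radiation
    pneumonitis with stability feature selection and repeated
    stratified-split ridge classification. Includes a synthetic
    CT/dose/lung phantom and cohort generator so the entire pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    optparse,
    yaml,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
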