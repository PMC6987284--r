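Package: FocusRadiomics
Title: Radiomic Classification of Small Enhancing Foci on Dynamic Breast MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for characterising small enhancing foci
    on dynamic contrast-enhanced breast MRI: slice-wise 2D affine
    co-registration of the dynamic series, 3D radiomic feature extraction
    (intensity, shape, grey-level co-occurrence and run-length texture
    statistics; 43 features per time-point over five time-points),
    evolutionary feature selection with simultaneous train/test splitting,
    a 3-nearest-neighbour classifier with a discrete positive-class
    probability rule, and diagnostic-accuracy reporting with exact binomial
    confidence intervals and ROC analysis. Includes a synthetic DCE-MRI
    cohort generator with class-dependent contrast kinetics so the whole
    pipeline can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, RNifti, jsonlite
Suggests: testthat (>= 3.0.0), withr, yaml, pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
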