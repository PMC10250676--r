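Package: stromatex
Title: Texture-Based Evaluation of Corneal Stroma Decellularization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies morphological changes in brightfield micrographs of
    corneal stroma caused by decellularization. Computes gray-level
    co-occurrence matrix (GLCM) texture features (angular second moment,
    inverse difference moment, contrast, correlation, sum variance) and
    level-1 Haar wavelet detail-subband energies per region of interest,
    runs the Kruskal-Wallis / Dunn / Bonferroni group-comparison workflow,
    and trains random-forest and support-vector-machine classifiers that
    separate intact from decellularized tissue. Includes a seeded synthetic
    micrograph generator emulating lamellar stromal texture with sparse
    keratocyte nuclei at graded decellularization severity, so the whole
    pipeline can be exercised end to end without access to the original
    micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    png,
    pROC,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
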