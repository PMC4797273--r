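Package: cooccupy
Title: Classification and Chromatin-Feature Modeling of Transcription
    Factor Co-Occupancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies ChIP-seq peaks of two transcription factors into
    solo and co-occupied binding events by reciprocal interval overlap,
    quantifies chromatin features (accessibility, histone marks, GC
    content, CpG methylation, chromatin state) in windows around binding
    sites, contrasts event classes statistically, and trains and
    evaluates classifiers (RBF-kernel SVM, random forest, Gaussian naive
    Bayes, linear discriminant) that predict co-occupancy within and
    across cell types. Ships a synthetic-data generator emulating the
    full set of inputs so the whole pipeline can be exercised and
    calibrated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.3)
Imports:
    Biostrings,
    data.table,
    e1071,
    GenomicRanges,
    IRanges,
    jsonlite,
    randomForest,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
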