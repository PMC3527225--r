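Package: cereblayers
Title: Localizing Gene Expression to Cerebellar Layers from ISH Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Registration-free classification of in-situ hybridization (ISH)
    expression images into cerebellar layers (Purkinje, granular, molecular,
    white matter). Images are represented by multi-scale histograms of local
    binary patterns LBP(8,2) plus mean intensity, scored by an RBF-kernel
    support vector machine, and per-gene image scores are pooled with order
    and moment statistics into a second-level linear classifier. Includes a
    synthetic layered-image generator for benchmarking, gene-grouped nested
    cross-validation, ROC/AUC evaluation, one-vs-one confusion matrices and
    a resolution-ablation experiment.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    kernlab,
    methods,
    png,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
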