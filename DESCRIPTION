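Package: foxtune
Title: Fox-Inspired Metaheuristic Optimization with an MRI Preprocessing
    and Hyperparameter-Tuning Harness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the fox-hunting population metaheuristic (FOX) and its
    contracted variant (CFOA) that adds Levy-flight exploration steps and a
    periodic elimination phase, together with the desk-scale scaffolding needed
    to exercise it end to end on a brain-tumor MRI classification workflow:
    contrast-limited adaptive histogram equalization (CLAHE) built from its
    histogram primitives, min-max normalization, affine augmentation with
    clinically motivated parameter ranges, class-imbalance loss functions
    (weighted and focal cross entropy with error-rate-driven class weights),
    classification metrics, depthwise-separable convolution cost formulas, a
    stratified dataset splitter, a synthetic three-class tumor-image generator
    with a MAT-file container dialect, and a CFOA-driven hyperparameter tuner
    over a toy classifier objective.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    EBImage,
    png,
    jsonlite,
    yaml,
    tibble,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
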