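Package: neuromastCoding
Title: Population Coding Analysis for Optogenetic Lateral-Line Stimulation
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for whole-brain calcium imaging experiments in
    which individual lateral-line neuromasts (or combinations of them) are
    stimulated optogenetically. Provides a synthetic-experiment generator with
    planted ground truth, stimulus-regressor construction and permutation-null
    responsiveness testing, single- versus mixed-selectivity classification
    with conditional-probability and topography statistics, linear support
    vector machine population decoding with Hoyer weight-sparseness and
    Jaccard overlap analyses, a bounded vector decomposition quantifying
    nonlinear summation of paired stimuli, trial-averaged principal-component
    trajectories, and region-wise pattern-decorrelation measures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    glmnet,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
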