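Package: PoseEthogram
Title: Rule-Based Behavioral Ethograms from Pose-Estimation Keypoint Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns DeepLabCut-style keypoint tables from bottom-view
    open-field recordings of rats into five-state behavioral ethograms
    (head-weaving stereotypy, quiet-awake, locomotion, grooming, rearing),
    run-level Markov transition matrices and weighted behavioral networks,
    and clustered per-animal motor profiles (PCA, t-SNE, hierarchical
    clustering with elbow-based cluster-count selection). Includes a
    synthetic kinematics generator that renders ground-truth-labelled
    keypoint sessions for validation, and closed-form summary statistics
    (coefficient of variation of weight change, high-fat-diet preference
    index, stereotypy-locomotion correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    igraph,
    Rtsne,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'kinematics.R'
    'detectors.R'
    'ethogram.R'
    'methods.R'
    'profiles.R'
    'transitions.R'
    'pipeline.R'
    'pose-io.R'
    'summaries.R'
    'synthkin.R'
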