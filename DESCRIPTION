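Package: richclubnet
Title: Rich-Club Organization and Group Inference for Structural Brain
    Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@richclubnet.org",
           role = c("aut", "cre"))
Description: Builds binary brain networks from weighted structural
    connectivity matrices by streamline-count filtering and sparsity
    thresholding; computes global and nodal graph-theory metrics with
    degree-preserving random-network normalization; quantifies rich-club
    organization and decomposes edges into rich, feeder and local classes;
    performs covariate-adjusted permutation inference, network-based
    statistic (NBS) subnetwork comparison and mapping of differential
    edges onto depression-related circuits; and discriminates groups from
    network features with a t-filtered, min-max scaled RBF support vector
    machine under leave-one-out cross-validation.  A synthetic cohort
    generator with planted rich-club topology provides ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'io.R'
    'threshold.R'
    'metrics.R'
    'richclub.R'
    'inference.R'
    'circuits.R'
    'classifier.R'
    'synthetic.R'
    'pipeline.R'
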