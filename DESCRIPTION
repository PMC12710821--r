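Package: hemiconn
Title: Hemisphere Chirality Classification from Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies brain hemispheres as left or right from
    within-hemisphere functional connectivity (hemiconnectomes), and probes
    whether handedness can be recovered the same way. Provides a synthetic
    cohort generator with block-structured covariances and planted
    hemispheric asymmetries, Fisher-Z connectome construction with canonical
    hemiconnectome/transconnectome/full-connectome feature extraction,
    handedness-stratified cross-validated classification (LDA, linear SVM,
    neural net) scored with the Matthews correlation coefficient and
    bootstrap confidence intervals, a two-stage permutation enrichment test
    that locates discriminative connections by resting-state network pair,
    and "hemisphere space" analyses: LD1 discriminant scores, the
    inter-hemisphere distance statistic |LD1_LH| + |LD1_RH|, and
    linear/segmented/quadratic models of distance against continuous
    handedness scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    e1071,
    nnet,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'atlas.R'
    'connectome.R'
    'classify.R'
    'enrichment.R'
    'hemiconn-package.R'
    'hemispace.R'
    'synthetic.R'
    'io.R'
    'pipeline.R'
    'utils.R'
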