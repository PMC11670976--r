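Package: neurodrain
Title: Drain Detection, Coverage Quantification and Malposition
    Classification for Intracerebral Hemorrhage CT Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-operative evaluation of hemorrhage drains from
    segmentation probability maps. Given co-registered 3D probability
    volumes for intracerebral hemorrhage (ICH) and drains, the package
    detects drains as discrete 26-connected objects, quantifies each
    drain's coverage by the hemorrhage as a 1-D profile along the drain's
    principal axis using a distance-transform "volume of touch", and
    classifies drain position (correct / not correct) with an L2-penalized
    logistic regression on the distal-15-mm profile. Agreement statistics
    (ICC(2,1), Bland-Altman limits of agreement, Fleiss' kappa, exact
    binomial confidence intervals, ROC-AUC) and a synthetic phantom
    generator with analytic truth profiles make the whole pipeline
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    RNifti,
    pROC,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'neurodrain-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'volumes-io.R'
    'detection.R'
    'coverage.R'
    'classifier.R'
    'metrics.R'
    'phantom.R'
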