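Package: facetraits
Title: Prediction of Facial Trait Judgments from Structural and Holistic Face Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study whether social trait judgments of faces
    (attractive, competent, trustworthy, dominant, mean, frightening,
    extroverted, threatening, likable) can be predicted from facial
    information.  Implements a structural descriptor built from polar and
    Euclidean relations among 21 fiducial landmarks, two holistic appearance
    descriptors (an eigen-decomposition of shape-normalized images and a
    dense-grid histogram of oriented gradients), a five-classifier bank
    (GentleBoost with stumps, RBF support vector machine, pruned decision
    tree, k-nearest neighbours, Parzen windows with random subspaces)
    evaluated under stratified N-fold cross-validation with Student-t
    confidence intervals, and second-level analyses: predicted-label
    correlation between descriptor pairs, feature-trait correlation with
    landmark importance maps, and trait-space principal components.  A
    synthetic face generator with planted trait signals makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    png,
    yaml,
    e1071,
    rpart
Suggests:
    testthat (>= 3.0.0),
    class,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
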