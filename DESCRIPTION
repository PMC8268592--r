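Package: scour
Title: Stepwise Classification of Unknown Metabolic Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts which metabolite concentrations control each reaction
    flux in a metabolic network from dynamic metabolomics and fluxomics time
    courses. Implements a stepwise machine-learning framework: candidate
    one-, two- and three-controller interactions are enumerated per flux,
    scored with rank-correlation and functional-uniqueness features, and
    classified by a two-level stacked ensemble (random forest, k-nearest
    neighbours, shallow neural network and linear discriminant analysis
    feeding a discriminant metamodel). Training data are autogenerated from
    damped-sine concentration profiles driving power-law (Biochemical
    Systems Theory) fluxes, so no real labelled data are required. Includes
    power-law network simulation, a measurement-noise model with triplicate
    replicates, median and Gaussian-filter preprocessing, and an evaluation
    harness with accuracy, sensitivity, specificity, PPV, F1 and a
    random-classifier baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    randomForest,
    nnet,
    MASS,
    class,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
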