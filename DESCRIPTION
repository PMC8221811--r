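Package: dacuity
Title: Decision Acuity: Latent Decision-Making Ability and Its
    Connectivity Signature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives a common factor ("decision acuity") from a battery of
    32 decision-making measures via an exploratory-confirmatory factor
    analysis pipeline (gaussianizing transforms, low-rank imputation,
    parallel analysis, minres extraction with oblique rotation,
    threshold-based confirmatory testing, split-half stability), computes
    investor-trustee exchange strategy metrics, partitions functional
    connectomes into modules by consensus Louvain clustering with
    NMI-tuned resolution, and predicts phenotypes from resting-state
    functional-connectivity edges with a bagged sparse partial
    least-squares nested cross-validation procedure, including
    permutation inference, virtual-lesion module scans, phenotype
    specificity via partial correlation, and cross-wave transfer. A
    synthetic cohort generator with known ground truth emulates the data
    structure of an accelerated longitudinal adolescent study for
    validation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
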