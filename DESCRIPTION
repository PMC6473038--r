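Package: focimeta
Title: Coordinate-Based Meta-Analysis of Neuroimaging Activation Foci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for coordinate-based meta-analysis of PET/fMRI activation
    peaks: ingestion of foci tables with Talairach-to-MNI normalisation,
    agglomerative Ward clustering of three-dimensional peak coordinates with a
    spatial-resolution stopping rule, exact binomial cluster-composition tests
    against dataset-level class priors, activation likelihood estimation (ALE)
    with non-additive modelled-activation maps, Monte-Carlo null distributions,
    FDR and cluster-extent thresholding, minimum-statistic conjunctions, and a
    seed-to-voxel resting-state functional-connectivity stage with sign-flip
    permutation inference. Includes seeded synthetic-data generators for foci
    datasets and preprocessed BOLD runs with planted ground truth for recovery
    and calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
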