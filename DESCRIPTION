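Package: dmnimpact
Title: Mechanistic and Machine-Learning Prediction of Default-Mode-Network
    Damage After Head Impact
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking head-impact biomechanics to resting-state
    functional damage of the default mode network (DMN). Implements a
    hyperelastic anisotropic brain-tissue constitutive model (Gent matrix
    plus fiber reinforcement) with a shear-energy-rate damage criterion and
    skull-fracture exclusion; a seeded synthetic surrogate for a finite
    element head-impact simulation library; a five-member bagging ensemble
    classifier with greedy forward feature selection and leave-one-out
    validation for predicting the probability of exceeding a DMN damage
    threshold; inverse impact-velocity estimation from probability-velocity
    curves via a 95%-of-plateau rule; single-case resting-state fMRI
    inference (dual regression, sign-flipping permutations,
    threshold-free cluster enhancement) yielding a DMN damage-load
    percentage; and forensic fall-kinematics reconstruction arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
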