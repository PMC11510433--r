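Package: dessol
Title: Solubility Modeling of Pharmaceuticals in Deep Eutectic Solvents
Version: 0.1.0
Authors@R:
    person("dessol", "maintainers", email = "dessol@example.org", role = c("aut", "cre"))
Description: Tools for modeling the solubility of active pharmaceutical
    ingredients in choline chloride- and betaine-based deep eutectic
    solvents. Implements COSMO-RS style sigma-potential descriptors
    (relative solute-minus-solvent potentials, step-function
    coarse-graining, hydrogen-bond region decomposition), ideal solubility
    from fusion thermodynamics with a heat-capacity approximation, a
    solubility dataset model with subset classification and coverage
    accounting, six descriptor-set definitions, evaluation metrics with a
    custom anti-overfitting loss based on learning-curve analysis, a
    regressor registry (including an authored nu-support-vector regressor)
    with seeded tree-structured Parzen estimator tuning, shake-flask assay
    arithmetic (calibration curves, limits of detection and quantification,
    mole-fraction conversion), and a synthetic-data generator with known
    ground truth for end-to-end parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    FNN,
    glmnet,
    jsonlite,
    quadprog,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
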