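Package: qsarvs
Title: Ensemble QSAR Virtual Screening with Consensus Scoring and
    Dose-Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A ligand-based virtual-screening pipeline for kinase
    inhibitor discovery. Curates IC50 bioactivity tables into binary
    active/inactive datasets, computes a fixed molecular-descriptor panel
    behind a provider contract, prunes descriptors in three auditable
    stages (zero variance, zero mutual information with the label,
    pairwise correlation above 0.8), trains random-forest, support-vector
    and neural-network classifiers with Bayesian hyperparameter
    optimization under stratified 10-fold cross-validation, fuses them by
    soft voting and stacking, and screens annotated compound libraries
    with a dual-confidence activity filter, rule-based drug-likeness
    (Lipinski, solubility, absorption, MCE-18, blood-brain barrier,
    toxicity flags) and a consensus score combining ensemble confidence
    with docking binding free energy. Includes principal-component
    chemical-space and applicability-domain analysis, Tanimoto similarity
    clustering, plate-based percent-inhibition and four-parameter
    logistic IC50 fitting, and synthetic-data generators with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    e1071,
    kernlab,
    lhs,
    minpack.lm,
    nnet,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
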