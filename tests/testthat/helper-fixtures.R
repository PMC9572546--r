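# Shared fixtures, all generated in code.

# A small but well-separated QSAR dataset: strong effects so the MI gate has
# full power at this sample size.
tiny_qsar <- function(seed = 5, effect_size = 1.5) {
  synth_qsar_dataset(n_active = 160, n_inactive = 80, n_features = 30,
                     n_constant = 2, n_duplicated = 3, n_independent = 5,
                     effect_size = effect_size, label_noise = 0.05,
                     seed = seed)
}

# Cheap base-model settings for fast fits in tests.
small_hp <- function(maxit = 150) {
  list(rf = list(n_estimators = 100L, max_depth = 10L, max_features = 0.3),
       svm = list(C = 1, gamma = 0.05),
       ann = list(hidden_layer_sizes = 8L, alpha = 0.1, maxit = maxit))
}

# The five top-ranked screening hits with their published per-compound
# inputs: fused-model confidences and docking binding free energies
# (kcal/mol). These printed values are pipeline *inputs* for the consensus
# stage.
top5_hits <- function() {
  data.frame(
    compound_id = c("Lariciresinol", "Nigracin", "Tricin",
                    "4'-Demethylepipodophyllotoxin", "Ophiopogonanone E"),
    conf_voting = c(0.855, 0.829, 0.830, 0.826, 0.844),
    conf_stacking = c(0.861, 0.838, 0.836, 0.859, 0.846),
    docking_energy_kcal = c(-9.282, -9.229, -9.007, -8.856, -8.802),
    s_ml_printed = c(0.858, 0.834, 0.833, 0.842, 0.845),
    s_total_printed = c(0.866, 0.851, 0.840, 0.838, 0.837),
    stringsAsFactors = FALSE
  )
}

# Published five-point inhibition series (percent at 50 ... 3.125 uM).
assay_series <- function() {
  list(
    conc = c(50, 25, 12.5, 6.25, 3.125),
    tricin = c(75.4, 61.8, 47.2, 34.8, 25.9),
    lariciresinol = c(15.1, 11.6, 9.0, 7.2, 5.6),
    demethylepipodophyllotoxin = c(10.2, 7.9, 5.7, 3.3, 1.9)
  )
}

# An ADMET annotation row passing every drug-likeness rule.
passing_admet_record <- function(id = "cmpd1") {
  data.frame(compound_id = id, smiles = "c1ccccc1CC",
             conf_voting = 0.9, conf_stacking = 0.9,
             mw = 350, logp = 2.5, hbd = 2, hba = 5, logs = -2,
             hia_percent = 80, mce18 = 60, bbb_permeant = TRUE,
             tox_mutagenicity = FALSE, tox_carcinogenicity = FALSE,
             tox_hepatotoxicity = FALSE, tox_oral_acute_toxicity = FALSE,
             docking_energy_kcal = -8, stringsAsFactors = FALSE)
}

# Fast small-scale pipeline configuration writing into `outdir`.
small_pipeline_config <- function(outdir, seed = 1) {
  cfg <- default_pipeline_config()
  cfg$seed <- seed
  cfg$outdir <- outdir
  cfg$synthetic$qsar <- list(n_active = 160L, n_inactive = 60L,
                             n_features = 40L, n_constant = 4L,
                             n_duplicated = 6L, n_independent = 8L,
                             effect_size = 1.5, label_noise = 0.05)
  cfg$synthetic$library <- list(n = 300L, fraction_dual_high = 0.1,
                                admet_pass_fraction = 0.3)
  cfg$training$hyperparameters <- small_hp()
  cfg$evaluation$folds <- 5L
  cfg
}
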