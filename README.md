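# qsarvs

Ensemble QSAR virtual screening for kinase inhibitor discovery, with
consensus scoring against docking affinities and dose–response IC50
analysis.

## The problem

Structure-based virtual screening alone suffers from high false-positive
rates and is slow on large libraries. A practical alternative is a
multi-stage funnel: a ligand-based machine-learning stage first narrows a
natural-product library down to high-confidence actives, rule-based
ADMET/drug-likeness filters remove undevelopable chemistry, and only the
survivors are docked; the two orthogonal signals are then fused into a
single consensus ranking, and the top candidates go to a kinase assay.
`qsarvs` implements that entire funnel as a tested, reusable R pipeline
for anyone building ligand-based screens against a kinase target (the
motivating application is JNK1, a type-2-diabetes target).

## What it computes

**Curation.** An IC50 bioactivity table is deduplicated by canonical
structure (duplicate potencies collapse to their geometric mean), records
without measured activity are dropped, and labels are assigned by the
strict rule IC50 < 1 µM ⇒ active. The curated set is split 4:1 into
training and test sets, stratified by label.

**Descriptors and pruning.** A fixed 208-descriptor panel is computed per
molecule behind a provider contract (an Open Babel-backed provider and a
file-backed provider for precomputed matrices are included). Training
descriptors are standardized (z-scores) and pruned in three fixed stages:

1. drop zero-variance descriptors;
2. drop descriptors with zero mutual information with the label
   (operationalized as "not statistically distinguishable from
   independence", see the methods vignette);
3. for every pair with |Pearson r| > 0.8, keep only one.

**Models.** Three base classifiers — random forest, RBF-kernel SVM, and a
single-hidden-layer neural network — are tuned by Bayesian optimization
(Gaussian-process surrogate, expected improvement) of the mean stratified
10-fold cross-validated AUC, then fused two ways: soft **voting**
(weighted mean of class probabilities) and **stacking** (logistic
meta-learner on out-of-fold base confidences).

**Screening.** A library compound survives the activity stage only if
*both* fused models give confidence ≥ 0.8. Drug-likeness then requires
Lipinski's Rule of Five with zero violations, −4 ≤ LogS ≤ 0.5,
HIA > 30 %, MCE-18 > 45, blood–brain-barrier permeation, and no toxicity
flag. Survivors are scored by consensus:

    S_ML    = (conf_voting + conf_stacking) / 2
    S_dock  = min(1, E_compound / E_reference)        (E_reference = −10.6 kcal/mol)
    S_total = (S_ML + S_dock) / 2

and ranked by `S_total`, selecting candidates with `S_total > 0.8`.

**Assay analysis.** Plate signal ratios convert to percent inhibition via

    inhibition = 100 · (R_noCompound − R_sample) / (R_noCompound − R_noKinase)

and dose–response series are fitted with a four-parameter logistic on
log10 concentration, reporting relative and absolute IC50 with
right-censoring ("> 50 µM") when the curve never reaches 50 %.

Every stage has a synthetic-data generator with known ground truth
(`synth_qsar_dataset()`, `synth_screening_library()`,
`synth_dose_response()`), so the full pipeline runs and is tested without
any external downloads.

## Worked example

Scoring the five top-ranked hits of a JNK1 natural-product screen from
their per-compound inputs (fused-model confidences and docking energies):

```r
library(qsarvs)
hits <- data.frame(
  compound_id = c("Lariciresinol", "Nigracin", "Tricin",
                  "4'-Demethylepipodophyllotoxin", "Ophiopogonanone E"),
  conf_voting = c(0.855, 0.829, 0.830, 0.826, 0.844),
  conf_stacking = c(0.861, 0.838, 0.836, 0.859, 0.846),
  docking_energy_kcal = c(-9.282, -9.229, -9.007, -8.856, -8.802))
ranked <- rank_candidates(score_library(hits, reference_energy_kcal = -10.6))
ranked[, c("compound_id", "s_ml", "s_dock", "s_total", "rank", "selected")]
#>                     compound_id   s_ml    s_dock   s_total rank selected
#> 1                 Lariciresinol 0.8580 0.8756604 0.8668302    1     TRUE
#> 2                      Nigracin 0.8335 0.8706604 0.8520755    2     TRUE
#> 3                        Tricin 0.8330 0.8497170 0.8413585    3     TRUE
#> 4 4'-Demethylepipodophyllotoxin 0.8425 0.8354717 0.8389858    4     TRUE
#> 5             Ophiopogonanone E 0.8450 0.8303774 0.8376887    5     TRUE
```

`s_ml` is each compound's mean ensemble confidence, `s_dock` its docking
energy relative to the co-crystallized ligand (−10.6 kcal/mol), and
`s_total` the consensus score used for ranking; all five exceed the 0.8
selection cut. Fitting Tricin's five-point inhibition series:

```r
fit <- fit_ic50(c(50, 25, 12.5, 6.25, 3.125), c(75.4, 61.8, 47.2, 34.8, 25.9))
fit
#> Dose-response fit: IC50 20.41 uM (relative), 14.31 uM (absolute 50% crossing)
#>   hill 0.975, top 101%, bottom 13.9%, RSS 0.0034
```

An end-to-end synthetic run (`run_pipeline(default_pipeline_config())`)
writes the full artifact chain — curated set, selection report, trained
ensemble, predictions, screening funnel, `ranked.csv`, IC50 table — into
an output directory, with a thin CLI in `inst/scripts/qsarvs`.

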