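---
title: "Methods: ensemble QSAR screening, consensus scoring, and dose-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble QSAR screening, consensus scoring, and dose-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and numerical choices behind `qsarvs`:
what each stage assumes, which parameters matter, what the synthetic-data
generators do and do not emulate, and where the design was genuinely open.

## 1. Curation and splitting

The bioactivity table is reduced to one record per canonical structure
(Open Babel canonical SMILES is the structure key; a single toolkit is the
point of truth for identity). Where duplicates carry several IC50
measurements we aggregate by the **geometric mean** rather than deleting
all duplicates outright: potencies are log-normally distributed across
assays, the geometric mean is the natural location estimate on that scale,
and it is order-independent. Records without a measured IC50 are removed
and every removal is counted by reason in the curation report, so the
funnel is auditable.

Labels use the strict rule IC50 < 1 µM ⇒ active; a compound exactly at
the threshold is inactive. The 4:1 train/test split is stratified by label
by default: with a ~4:1 active:inactive imbalance an unstratified test set
of a few hundred compounds is unstable in its class balance, and a flag
(`stratify = FALSE`) restores the plain random split.

## 2. Descriptor panel

`ob_descriptor_provider()` computes a fixed, ordered panel of 208 named
descriptors per molecule: 8 global physicochemical properties from Open
Babel (two H-bond-acceptor definitions, donor count, logP, molar
refractivity, molecular weight, fluorine count, TPSA), 10 heavy-element
counts, and 190 hashed structural-fragment counts obtained by folding the
1024-bit FP2 path fingerprint modulo 190. This panel is the package's own:
panels of this width are conventional for 2D QSAR, but any panel is
toolkit-release-dependent, which is why the provider records its name list
in the output metadata and why a file-backed provider
(`file_descriptor_provider()`) lets the entire numerical pipeline run from
precomputed matrices. Descriptor computation is deterministic:
repeated calls give bit-identical rows.

Standardization is fitted on training rows only and applied, never
refitted, to test and library matrices. Constant columns get scale 1 so
they map to exactly 0 instead of dividing by zero; the zero-variance
pruning stage removes them anyway.

## 3. Three-stage descriptor pruning

The stages run in a fixed order — variance, mutual information,
correlation — and the selection report records every drop with its reason
(variance value, MI value, or retained partner and correlation), so the
surviving panel can be reconstructed exactly and re-applied to new
matrices.

**Mutual information.** "Zero MI with the label" is only exact for an
idealized estimator: any nearly unbiased estimator returns a small
positive value for roughly half of all truly independent features, so
thresholding a raw estimate near zero cannot identify them. `mutual_info()`
therefore uses a plug-in estimate on an equal-frequency binning (at most 8
bins) gated by a G-test of independence: when the observed association is
not significant the estimate is returned as exactly 0, otherwise the
bias-corrected value (G − df)/2n in nats. The gate controls the
family-wise error across the panel (Bonferroni, family α = 0.01 by
default), so a truly independent descriptor survives the whole stage with
probability at most α regardless of panel width. The flip side is finite
power: a weakly informative descriptor whose G statistic falls below the
Bonferroni-corrected critical value is dropped. At the default study
scale (~1400 compounds) this affects only features near the detection
margin. The estimator is fully deterministic; the `seed` argument exists
for interface stability.

**Correlation.** Columns are visited in input order and a column is
dropped if it correlates above 0.8 (strictly) with an already-kept column,
recording the kept partner. This is deterministic and documented; for
transitive correlation structures (cliques, e.g. exact duplicates) the
kept *count* is order-invariant even though the kept *member* is not. The
0.8 threshold is a strict inequality: a pair at exactly the threshold
survives.

## 4. Base models, tuning, and fusion

The three base classifiers are random forest (`ranger`; `max_features`
maps to `mtry = floor(fraction × p)`, `min.node.size = 1` as is standard
for classification forests), RBF-kernel SVM (`e1071`, probability output
enabled), and a single-hidden-layer neural network (`nnet`, maximum 2000
iterations, fixed seed; a single hidden layer keeps the weight count
proportionate to the few-hundred-compound training sets this pipeline
targets).

Hyperparameters are tuned by Bayesian optimization of the mean stratified
10-fold cross-validated AUC — AUC because it is threshold-free and the
most informative single number for an imbalanced screen. The tuner uses a
maximin Latin-hypercube initial design, a Gaussian-process surrogate
(`kernlab::gausspr` with an RBF kernel on the unit cube and a
predictive-variance model) and expected improvement over a random
candidate set; integer parameters round, log-scaled parameters
exponentiate. No installed package provides the optimization loop itself,
so it is authored here (~60 lines) and is deterministic given its seed.
The default bounds (trees 50–500, depth 3–30, feature fraction 0.05–1;
C 1e−2–1e2 and gamma 1e−4–1 on log scales; hidden units 16–256, weight
decay 1e−4–10 log) bracket published optima for kinase-activity panels of
this size, which `default_hyperparameters()` exposes directly.

**Fusion.** Voting is soft with equal weights by default (weights are
configurable; nothing in our experiments justified tuned weights over
equal ones). Stacking fits a logistic regression on 5-fold out-of-fold
base confidences: each compound's meta-features come from base models that
never saw it, which is the property that keeps the meta-learner from
simply memorizing over-confident in-fold predictions; the fold bookkeeping
is retained on the model object so tests can assert it. Class imbalance is
left unweighted by default (a class-weight flag exists) — with a 4:1
ratio and AUC-based tuning, reweighting changed nothing in calibration
runs.

## 5. Evaluation

Accuracy, precision, recall, and F1 are computed from confusion counts at
a 0.5 threshold (the 0.8 screening threshold is a *screening* decision,
not an evaluation one). Precision is reported as missing, not zero, when
no compound is predicted positive, so fold averages are not silently
deflated. AUC is computed from ranks, which equals the Mann–Whitney
pairwise probability with half-credit ties at any sample size; tests
verify the equality against a brute-force pairwise oracle.

## 6. Chemical space and applicability domain

PCA runs on standardized descriptors (correlation-scale PCA): descriptor
units are wildly heterogeneous and unscaled PCA would be dominated by
whichever descriptor has the largest numeric range. The applicability
domain is an axis-aligned bounding box over the first two components of
the training scores, optionally widened by a fractional margin; a library
compound is in-domain iff both coordinates fall inside. A box is the
simplest formalization of the usual visual "does the library overlap the
training cloud" check and yields a single overlap fraction, which is
monotone in the margin by construction.

## 7. Screening filters and consensus score

The activity filter is a conjunction: both fused-model confidences must
reach 0.8 (≥, per "setting the threshold to 0.8"), whereas the final
candidate selection uses a strict `S_total > 0.8`. Drug-likeness is
operationalized as zero Lipinski violations (a violations-allowed knob
exists for sensitivity analysis) plus the solubility, absorption, MCE-18,
BBB and toxicity rules listed in the README; annotations are upstream
predictions consumed as inputs — this package never predicts ADMET
properties itself.

The docking sub-score is the energy ratio `E/E_ref`, capped at 1 when a
compound out-docks the reference so the score stays in [0, 1]; a positive
(unfavourable) energy scores 0 with a warning rather than going negative.
The default reference affinity is −10.6 kcal/mol and is configurable:
back-calculating from published score tables implies a slightly different
internal value (≈ −10.632, i.e. the printed reference was rounded), which
is why consensus totals are only reproducible to ~0.2% relative with the
printed reference — the package documents both rather than silently
adopting the implied value.

Similarity clustering of the final hit list uses 1024-bit FP2 path
fingerprints, Tanimoto similarity and average-linkage hierarchical
clustering — standard choices for a diversity heatmap; the fingerprint
provider is injectable for testing and for users who prefer circular
fingerprints.

## 8. Dose-response analysis

Percent inhibition normalizes each sample ratio between the plate's
compound-free (0%) and kinase-free (100%) controls; replicated controls
are averaged and the computation is invariant under any common rescaling
of the ratios. Equal control means abort with an "assay window collapsed"
error.

IC50 fitting uses a four-parameter logistic on log10 concentration with
all four parameters free but box-constrained (asymptotes in [−10, 110]%,
Hill slope in [0.1, 10], log-IC50 within the tested range ± 3 decades).
Initialization takes the asymptotes from the data extremes, the IC50 from
linear interpolation of the 50% crossing and Hill slope 1; because steep
curves and top-censored windows create shallow local minima around
hill = 1, the fit multi-starts over Hill slopes {1, 0.5, 2, 4} and keeps
the lowest-RSS solution. An interpolating solution (residual sum of
squares below 1e−6) counts as converged even if the optimizer stopped on
its iteration cap. Both the *relative* IC50 (fitted midpoint) and the
*absolute* IC50 (fitted 50% crossing) are reported because conventions
differ between curve-fitting tools; when the observed maximum inhibition
never reaches 50% the result is right-censored and reported as
"> top concentration", matching assay-report convention. The serial
dilution helper takes its point count and factor explicitly (the common
"two-fold from 50 µM" protocol is described sometimes as 10 points and
sometimes by its 195 nM endpoint, which implies 9 — the generator resolves
nothing and takes both parameters).

## 9. Synthetic data: what it emulates, and what it does not

`synth_qsar_dataset()` emulates a curated kinase set at its study
composition (defaults 1138 active / 285 inactive, 208 descriptors):
class-conditional Gaussian informative features with a per-feature
standardized mean shift (default effect size 0.6), exactly-constant
columns (12), exact duplicates of informative columns (20), and
label-independent noise columns (40), all named in a manifest. The effect
size was chosen once so that an informative feature's G statistic sits far
above the MI gate's critical value at the default sample size; 5% label
flips emulate assay/label noise and keep the attainable AUC near 0.95, so
a well-built ensemble lands in the calibrated cross-validated AUC band
[0.85, 1.0] rather than saturating at 1. Synthetic SMILES come from ten
scaffolds with an index-encoded C/N side chain — valid, parseable and
mutually distinct so structure-dependent code paths (parsing, canonical
keys, fingerprints) genuinely run. What the generator does **not**
emulate: real descriptor marginals and their heavy correlation blocks,
activity cliffs, scaffold-dependent labels, or natural-product
chemistry-space statistics. Passing tests therefore demonstrate that the
pipeline's machinery is correct and calibrated on data of known structure,
not that any particular real-world AUC will be achieved.

`synth_screening_library()` plants the screening funnel explicitly (which
compounds are dual-confidence-high, which pass every drug-likeness rule,
and which single rule each failure breaks) and samples docking energies
uniformly in a plausible range; ADMET annotations are sampled, not
predicted. `synth_dose_response()` back-computes plate ratios from the
logistic curve so the analysis chain inverts it exactly at zero noise, and
applies multiplicative Gaussian ratio noise otherwise.

## 10. Problem sizes and determinism

Test problem sizes are deliberately modest — a 240-compound fixture for
most model-level tests, one study-scale (1423 × 208) fixture for the
selection funnel and the cross-validated band check, a 4112-compound
synthetic library for the screening funnel, and 100 seeded replicates for
the IC50 noise study — enough for each statistical claim at its stated
tolerance while keeping the whole suite to a couple of minutes. Every
source of randomness (generators, splits, folds, tuner, forest growth,
network initialization) flows from an explicit integer seed, and the test
suite asserts bit-level reproducibility stage by stage and for the full
pipeline.

## Known limitations

- Descriptor panel membership differs from other toolkits' 208-descriptor
  panels; models and selection reports are therefore panel-specific.
- The MI gate trades power for a guaranteed false-keep rate; very weak
  signals near the detection margin are discarded.
- The applicability-domain box ignores density inside the box (a compound
  in a sparse corner counts as in-domain).
- The stacking meta-learner is intentionally simple (logistic regression);
  heterogeneous base-model quality might reward a richer meta-learner.
- Docking energies are consumed as annotations; nothing here validates
  them.
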