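---
title: "PET radiomics cross-combination modelling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PET radiomics cross-combination modelling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

petrad implements a baseline-PET radiomics pipeline for predicting interim
treatment response (complete metabolic response, Deauville 1–3, vs non-CR,
Deauville 4–5) and survival in high-risk diffuse large B-cell lymphoma.
The pipeline has five stages: lesion segmentation and metabolic metrics,
radiomic feature extraction, selector-by-classifier model election with
RadScore construction, logistic prediction modelling, and survival
analysis. Each stage is a small set of exported functions; `runPipeline()`
chains them behind a configuration object, and synthetic generators stand
in for patient data everywhere.

## Segmentation and metabolic metrics

Lesions are segmented semi-automatically: the user supplies a seed voxel or
bounding box, SUVmax is located inside that search region, and the lesion is
the 26-connected component of voxels with SUV at or above
`fraction × SUVmax` containing that maximum. The threshold fraction defaults
to 0.41 — the EANM-recommended boundary for lymphoma lesions — and is
configurable; a `global = TRUE` mode thresholds against the global volume
maximum instead (useful for rejecting cold regions, and the only mode in
which an empty mask is possible). 26-connectivity is the common PET VOI
convention; 6-connectivity is available via `connectivity = 6`.

Lesions with MTV < 10 cm³ are excluded before feature extraction; the
comparison is `>=` on the retained side, so a lesion of exactly 10 cm³
survives. The patient-level VOI is the union of retained lesions; patient
SUVmax is the maximum over lesions while MTV and TLG are summed. Whether
features should come from the merged VOI, the largest lesion, or per-lesion
aggregation is genuinely open in this field; the merged VOI is this
package's documented default because it preserves the single-score-per-
patient contract while using all retained tumor burden.

## Feature catalogue

`extractFeatures()` computes a fixed 110-feature catalogue keyed by IBSI
codes: 12 shape, 43 first-order (20 on continuous SUVs, 23 on the
discretized intensity histogram), 23 GLCM, 11 GLRLM, 5 NGTDM and 16 GLSZM
features. Two catalogue quirks are intentional: "Maximum 3D Diameter" is a
single feature (its printed source splits the name across a separator), and
the first-order family lists both the median and the 50th percentile —
numerically identical — as separate entries; both are kept so the catalogue
count stays at the printed 110.

Key numerical choices, each configurable:

* **Discretization** (`discretizeVOI()`): fixed bin *number*, default
  Ng = 64 equal-width bins between the in-mask minimum and maximum. A
  constant VOI maps to level 1 with a warning (texture features are then
  degenerate but defined).
* **GLCM/GLRLM aggregation**: features are computed per direction over the
  13 unique 3D directions at Chebyshev distance 1 and averaged ("averaged"
  aggregation); GLCMs are symmetrized and normalized per direction before
  feature evaluation.
* **GLSZM/NGTDM** use 26-connected zones / neighbourhoods over the whole
  VOI, with no direction averaging.
* **Degenerate-statistic conventions**: skewness, excess kurtosis,
  coefficient of variation and GLCM correlation of a constant VOI are 0;
  NGTDM coarseness is capped at 1e6; busyness/complexity/strength fall back
  to 0 when their denominators vanish. These keep every catalogue entry
  finite for any VOI with at least one voxel, which `extractFeatures()`
  enforces by raising an error naming any non-finite feature.
* **Percentiles** use the linear-interpolation (type-7) definition, written
  out explicitly and tested against `stats::quantile`.
* **Global intensity peak**: mean SUV inside the ~1 cm³ sphere (radius
  6.2 mm) centred at each in-mask voxel, maximized over centres; voxels
  outside the mask contribute to the sphere mean.

### Shape meshing

Shape features are mesh-based. Marching cubes needs large case tables, so
the mesher uses marching tetrahedra on the zero-padded binary mask (Kuhn
6-tetrahedron decomposition, iso-level 0.5), whose case logic is fully
derivable and therefore safely implementable from first principles. Raw
binary iso-surfaces carry the well-known staircase bias — their area
overestimates a smooth surface by ~25% regardless of resolution — so the
mesh is smoothed with Taubin's shrink-free λ/µ filter (λ = 0.5, µ = −0.53,
100 iterations). Flat mask faces are fixed points of the neighbour
averaging, so boxes keep their geometry, while staircase diagonals flatten
towards the smooth surface. Measured on digital solids: a radius-12-voxel
sphere scores sphericity 0.986, and a 10³-voxel cube recovers its analytic
surface within 5% and volume within 2%. Surface area, mesh volume and all
derived ratios (compactness, sphericity, asphericity, spherical
disproportion) come from this mesh; maximum 3D diameter is the largest
pairwise distance between mesh vertices. Voxelization itself contributes an
alignment-dependent volume error (worst when the lesion centre sits on a
voxel corner), which is visible in the ground-truth masks, not the mesher.

## Preprocessed images

`logFilter()` applies separable Gaussian smoothing at a physical scale
(default σ = 2 mm) followed by the spacing-scaled discrete Laplacian, with
replicate padding so constants map to zero exactly. `waveletDecompose()` is
a single-level separable periodized orthogonal 3D DWT (coiflet-1 default;
haar and db2 available) with hard-coded orthonormal filter banks; the
transform is exactly energy-conserving and invertible
(`waveletReconstruct()`), which the tests assert to numerical precision.
Because the catalogue's printed count of 110 corresponds to
original-image features, filtered-image features are **off by default**;
passing `filtered = list(...)` to `extractFeatures()` recomputes the
intensity and texture families per filtered image with the provenance tag
prefixed to each feature name.

## Cross-combination engine

Seven methods serve both as feature selectors and classifiers: GBDT
(xgboost), extremely randomized trees and random forest (ranger), AdaBoost
(own two-class SAMME over exhaustive decision stumps — no maintained R
AdaBoost implementation is available), LASSO (glmnet, λ chosen by internal
CV at `lambda.min`), SVM (e1071; linear kernel when coefficients are needed
for selection, RBF with decision-value ranking as a classifier) and
logistic regression. Ranking weights are impurity/gain importances for tree
ensembles, accumulated stump weights for AdaBoost, and absolute
coefficients for the linear methods; features are standardized (training
statistics only) before any fit.

`selectFeatures()` is recursive elimination: record the method's k-fold CV
AUC (k = 3 by default) on the current subset, drop the lowest-weight
feature (weights re-estimated on each subset; `dropPerStep` accelerates
large catalogues), repeat to a single feature, return the subset with
maximal CV AUC with ties going to the smaller subset.

`evaluatePair()` cross-validates the full selection+classification pipeline
with stratified k-fold CV (k = 5): by default the selection is **re-run
inside each training fold**, standardization statistics come from the
training fold only, and the AUC is measured on the held-out fold. The
literal protocol this reproduces runs selection once on the whole training
cohort *before* cross-validating the classifier; that order leaks
selection information into the folds, so it is available behind
`paperProtocol = TRUE` but is not the default. The label-shuffle tests
(CV AUC ≈ 0.5 on permuted outcomes) guard the default against any such
leakage.

`runGrid()` evaluates all 49 pairs under one fold assignment and elects the
argmax of mean CV AUC, breaking ties lexicographically in the canonical
method order (GBDT, ET, RF, AdaBoost, LASSO, SVM, LR). `fitRadScore()`
reruns the elected selector on the full training cohort, refits the elected
classifier on the selected features, and takes that refit's weights
(signed coefficients for linear classifiers; importances for tree
ensembles, which are magnitude-only) as the RadScore weights. Whether the
score weights should come from the selector's or the classifier's refit is
not fixed by the protocol; the classifier refit is the default and
`weightSource = "selector"` the alternative. An RBF-SVM classifier exposes
no coefficients, and LASSO can zero out every weight at `lambda.min`; in
both cases the selector's ranking weights are used so the score never
degenerates to all-zero. The elimination path length, not a forced feature
count, decides how many features enter the score: the reference analysis
itself reports both 10 and 11 key features in different places, so no
attempt is made to force either count.

Hyperparameters are fixed, recorded in the run manifest, and deliberately
modest: 150 ranger trees (100 in the pipeline default), 60 xgboost rounds
at η = 0.3 and depth 3 (50 in the pipeline default), 30 AdaBoost stumps
(25 in the pipeline default), 3-fold internal glmnet CV. They can be
overridden per call via `params`.

## Clinical models

Cutoffs for dichotomizing continuous predictors maximize the Youden index
over all midpoints between consecutive distinct scores (ties resolved to
the lower threshold); an exhaustive-search oracle test asserts equality.
AUC confidence intervals use DeLong variance (pROC). Univariate screening
at p < 0.05 gates entry into the multivariate logistic model; perfect
separation raises an explicit error rather than a silently divergent fit.
The five prediction models are fixed predictor sets: combined (sex, B
symptoms, SUVmax group, RadScore group), clinical (sex, B symptoms), PET
(SUVmax group), NCCN-IPI and IPI. Calibration uses decile binning with
bootstrap-refit curves (default 1000 replicates; 200 in the pipeline stage)
and logistic recalibration slope/intercept. Decision curves use
NB(p_t) = TP/n − FP/n·p_t/(1−p_t) on a 0.01–0.99 grid (step 0.01).
Nomogram points are |coefficient| × range scaled so the largest effect
spans 100 points, with an exact inverse-logit point-to-risk map (tested to
1e-6 against direct model predictions). Two-cohort demographic comparisons
use Pearson's χ² **without** continuity correction — verified to reproduce
the printed reference p-values (sex 0.110, LDH 0.173, B symptoms 0.250,
bulky disease 0.851, RadScore group 0.947) from their printed contingency
tables; the printed age-row p-value (0.132) is not reproducible by this
test (uncorrected Pearson gives 0.160) and is therefore not used as a
reference anywhere. Yates correction is available behind `correct = TRUE`.

## Survival

Kaplan–Meier curves use the product-limit estimator with the median defined
as the first time S(t) ≤ 0.5 (NA = not reached) and landmark rates at
12/36/60 months. The log-rank test and the Cox model (Efron tie handling,
the common default) compare RadScore groups; monotone partial likelihood
(non-overlapping groups) raises an explicit error. A numerical test
confirms the Cox score test agrees with the log-rank statistic on the same
data.

# The synthetic generators

`makePhantom()` emulates whole-body PET geometry: 4 × 4 × 4 mm voxels, a
low-uptake background (SUV 1) with Gaussian noise, and ellipsoidal lesions
with four texture generators (uniform, Gaussian-noise, checkerboard,
radial-gradient) chosen to make texture features discriminative between
lesions. It does *not* model scanner physics — no point-spread function,
attenuation, reconstruction artifacts or physiologic uptake — so passing
phantom tests demonstrates the correctness of the computational pipeline,
not clinical segmentation performance on real scans.

`simulateCohort()` emulates the statistical structure of a 177-patient
high-risk cohort: twelve binary covariates at the pooled reference margins
(e.g. 72.9% male, 32.8% B symptoms), lognormal SUVmax/MTV/TLG dichotomized
at the reference cutoffs (19.2 / 25.6 cm³ / 222), independent
standard-normal radiomic feature columns, a Bernoulli non-CR outcome whose
log-odds combine the planted coefficients (defaults: sex ln 2.76, B
symptoms ln 4.065, SUVmax-high ln 2.619, and a radiomic block over three of
the eleven key features) with an intercept calibrated to the requested
prevalence (default 0.40 — the reference cohort does not print its non-CR
rate, so this is the package's fixed choice of a plausible high-risk
interim non-CR fraction), and exponential PFS/OS times whose hazard is
multiplied by planted hazard ratios (2.1737 / 2.1356) in the high
latent-score group (top 27.7%, matching the reference 49/128 grouping).
Baseline hazards (median PFS 50 months, median OS 85 months in the low
group) and an administrative censoring window of 6–54 months (median ≈ 30,
mimicking the reference median follow-up) plus 10% random early dropout
complete the model. Radiomic features are independent in the generator —
real radiomic features are strongly correlated — so feature-selection tests
demonstrate recovery of planted signal, not robustness to collinearity.

The 7:3 split uses the ceiling convention for the held-out size:
ceil(0.3 × 177) = 54 validation / 123 training, which plain rounding would
not produce.

All randomness flows from a single seed per run; stage and fold sub-seeds
are derived deterministically from it, and identical spec + seed gives
bit-identical phantoms, cohorts and grids.

# Problem sizes

The test suite and the acceptance script run everything at reduced but
honest scales chosen as the package's own defaults: texture oracles sweep
VOIs up to 6³ voxels and 4 grey levels; shape checks use a 10³-voxel cube
and radius-12-voxel sphere; grid determinism/election tests run the full
49-cell grid at n = 60 with 3 features and lean hyperparameters;
feature-recovery runs 10 seeds at n = 600 with 2 informative + 18 noise
features; logistic/Cox recovery uses n = 2000–5000. The full test suite
runs in about two minutes on one CPU; the acceptance script in about 90
seconds.

# Known limitations

* The mesher's surface area carries a small negative bias on sharp-edged
  solids (−4% on a 10-voxel cube) and the staircase-smoothing trade-off is
  tuned for lesion-like blobs; it is not an IBSI-certified mesher.
* Filtered-image features require same-grid filtered volumes (LoG);
  wavelet sub-bands live on the decimated grid and are extracted separately
  rather than appended to the catalogue.
* The cohort generator plants independent features and exponential
  survival; it supports parameter-recovery tests, not benchmarking against
  real-data effect sizes, and patient-level reference AUCs/ORs/HRs from the
  original two-centre cohort are out of reach without that data.
* `glm`-based logistic fits assume no separation; quasi-complete separation
  in small strata is raised as an error by design rather than penalized.
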