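---
title: "Radiomic classification of small enhancing breast-MRI foci: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic classification of small enhancing breast-MRI foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FocusRadiomics)
```

## The problem

Enhancing foci are contrast-enhancing breast-MRI findings smaller than 5 mm.
They are too small for reliable morphological assessment and often too small
for targeted biopsy, yet a minority of them are early malignancies. Their
contrast kinetics carry diagnostic information: benign foci tend to enhance
slowly and persistently, while malignant ones show fast wash-in followed by
wash-out. This package implements a complete quantitative pipeline for that
classification problem on a five-time-point dynamic series (one unenhanced
volume T0 and four post-contrast volumes T1--T4, 1 mm isotropic in-plane,
60 s temporal resolution):

1. slice-wise 2D affine co-registration of T1--T4 to T0,
2. extraction of 43 radiomic features per time-point (215 per case),
3. evolutionary selection of a feature subset together with a split of the
   cohort into two homogeneous groups A and B ("TWIST"-style),
4. a 3-nearest-neighbour classifier with a discrete positive-class
   probability,
5. crossed A/B evaluation with exact binomial confidence intervals and ROC
   analysis.

Because patient images cannot be shipped, the package includes a synthetic
DCE-MRI generator that produces cohorts with known class, kinetics, texture
and (optionally) inter-time-point motion; every stage is validated against
it.

## Synthetic cohorts

Each case is an ellipsoidal lesion placed in a smoothed-noise parenchyma
background. Lesion voxels follow

$$ I(t) = B\,\bigl(1 + e(t)\bigr)\bigl(1 + h\,\tau(\mathbf{x})\bigr), \qquad
   e(t) = A\,\bigl(1 - e^{-r_\text{in} t}\bigr)\,e^{-r_\text{out} t}, $$

where $B$ is the baseline intensity, $A$ the wash-in amplitude,
$r_\text{in}$ and $r_\text{out}$ the uptake and decay rates (1/min), $h$ a
per-class heterogeneity scalar and $\tau$ a smoothed unit-variance random
field. With $r_\text{out} = 0$ the curve is monotone (persistent,
benign-type); with $r_\text{out} > 0$ it peaks and washes out
(malignant-type). This three-parameter form was chosen because it is the
simplest closed form that produces both archetypes with interpretable
parameters; no pharmacokinetic realism (e.g. Tofts modelling) is claimed.

Defaults (all configurable through `cohortConfig()`):

* geometry: 1 x 1 x 1 mm voxels, times 0--4 min, lesion diameters 3--5 mm
  (the focus regime);
* kinetics: benign $A = 0.6$, $r_\text{in} = 0.7$, $r_\text{out} = 0$;
  malignant $A = 1.2$, $r_\text{in} = 3$, $r_\text{out} = 0.4$, each
  jittered per case by up to 10%;
* texture heterogeneity 0.05 (benign) vs 0.15 (malignant);
* additive Gaussian noise, SD 5 against a background level of 60 and
  background texture SD 8. Gaussian rather than Rician noise: at this
  signal-to-noise ratio the difference is immaterial and Gaussian keeps the
  moments analytic.

All randomness flows from the configured seed; each case derives its own
stream from a stable hash of the case identifier, so cohorts are
reproducible and order-independent. What the generator does **not** emulate:
anatomy (the background is smoothed white noise), coil or bias-field
artefacts, fat-suppression behaviour, multi-lesion cases. Tests passing on
these phantoms therefore validate the *computational* pipeline, not clinical
performance.

## Registration

Motion between time-points is simulated and corrected slice-wise with a 2D
affine transform (6 parameters, centre-anchored). The metric is the mean
square difference of *z-scored* intensities: standardising both slices
decouples the global brightness change caused by contrast enhancement from
geometry. Optimisation is coarse-to-fine over a 3-level image pyramid with
Nelder-Mead, bilinear interpolation throughout, and one restart at the
finest level (simplex collapse is the common Nelder-Mead failure mode).
Two numerical details matter:

* both images are Gaussian-smoothed (sigma 1 px) before the metric is
  evaluated at every level. Without this, bilinear resampling attenuates
  the *noise* of the floating image more at half-pixel offsets than at
  integer ones, biasing the MSE optimum by a few tenths of a pixel;
* the metric is evaluated on an interior band (3 px margin), so replicated
  border pixels cannot bias the fit;
* if the optimised transform does not improve on the identity MSE, the
  identity is returned; constant slices return identity with a warning
  flag. The achieved objective therefore never exceeds the identity
  objective.

T0 is the fixed target (the choice is a package convention; either
convention is defensible). The lesion mask is never resampled -- it is
defined on the registered series. Registration is off by default in the
pipeline because the synthetic default is motion-free.

## Feature extraction

Per time-point, 43 features (215 per case):

* **6 intensity**: Max, Min, Mean, Sigma, Variance (population),
  IntegratedIntensity (sum x voxel volume).
* **5 shape**, computed once from the single mask and replicated across the
  five time-points (one mask per series): Volume, and equivalent-ellipsoid
  descriptors from the eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$
  of the covariance of masked voxel physical coordinates -- axis lengths
  $4\sqrt{\lambda}$, Elongation $\sqrt{\lambda_1/\lambda_2}$ ($\ge 1$),
  Eccentricity $\sqrt{1 - \lambda_3/\lambda_1}$. These conventions are
  stated because the feature *names* alone do not pin them down.
* **12 co-occurrence**: Energy, Entropy (base 2), inverse difference
  moment, Inertia, Cluster shade, Cluster prominence -- mean and sample SD
  (n - 1) over the 13 unique directions of the 3D 26-neighbourhood,
  offset distance 1, symmetric matrices normalised after summing both
  orientations.
* **20 run-length**: the ten classical run statistics (SRE, LRE, GLN, RLN,
  LGLRE, HGLRE, SRLGLE, SRHGLE, LRLGLE, LRHGLE), aggregated the same way.
  Runs are maximal same-level segments restricted to the mask; a run
  breaks at mask boundaries.

Grey levels: 32 equal-width bins between the masked minimum and maximum,
per ROI per time-point (a common radiomics default that keeps 5 mm ROIs
from producing overly sparse matrices; configurable). A constant ROI maps
to a single level rather than erroring, so unenhanced early time-points
remain processable. Volumes are cropped to the mask bounding box (plus a
margin) first; masked statistics are provably unaffected by the crop. The
implementation is validated feature-by-feature against brute-force pair and
run enumeration oracles, and the direction-averaged statistics are checked
to be invariant under 90-degree rotations of the ROI.

## Evolutionary selection and splitting

The selection stage optimises a chromosome with one bit per feature
(selected or not) and one bit per case (group A or B). Fitness is the mean
of the two crossed accuracies -- train on A / test on B and vice versa --
of the 3-NN classifier restricted to the selected features. Chromosomes
whose groups would leave fewer than $k+1$ cases of either class receive
fitness 0 (penalty, not repair: simpler and deterministic). The genetic
algorithm is standard: tournament selection (size 2), uniform crossover
(probability 0.9) applied independently to the feature and split segments,
per-bit mutation (default 1/genome length), elitism 1 (making the best
fitness non-decreasing), sparse initialisation (feature bits on with
probability 0.2, split bits fair coins). Defaults are population 100 and
200 generations; the behavioural tests use smaller, documented budgets
(population 30--40, 15--40 generations) that already recover planted
informative features reliably. No parsimony penalty is applied by default;
the original algorithm's internals are not public, so the implementation
targets the *behaviour* (planted-feature recovery, homogeneous splits), not
replication of a proprietary code path. `splitBalanceReport()` documents
split homogeneity with per-feature Mann-Whitney tests and
Benjamini-Hochberg q-values.

## Classifier

3-nearest neighbours with Euclidean distance on z-scored features
(z-scoring is learned from the training group; features are on wildly
different scales, so some normalisation is mandatory -- this also makes
predictions invariant to positive rescaling of any raw feature). The
positive-class probability is discrete: $P(+) \in \{1, 0.66, 0.33, 0\}$ for
3, 2, 1 or 0 positive neighbours; a case is called positive iff
$P(+) > 0.5$, which is exactly the unweighted majority vote. $P(+)$ is
stored as the printed two-decimal values rather than thirds: downstream
behaviour (threshold, ROC ordering) is identical and worked examples are
exact. Exact distance ties are broken by the lowest training-case index --
the single documented source of order sensitivity. Constant training
features are dropped with a warning.

## Diagnostics

Confidence intervals are exact Clopper-Pearson from beta quantiles: this
is the "binomial distribution" interval that reproduces the degenerate
bounds $\left(\alpha/2\right)^{1/n}$ when all cases are correct (87% lower
bound for 27/27, 91% for 37/37), which Wald intervals cannot. Point
estimates are displayed as integer percentages, rounded half-up (90.5
becomes 91); likelihood ratios are displayed as integers; full precision is
always retained alongside. Metrics with zero denominators are reported as
undefined (`NA`), never as 0. The ROC curve sweeps the four discrete score
values and the AUC is the trapezoidal area, which equals the tie-corrected
rank statistic (verified exhaustively in tests). The crossed evaluation
reports each arm, the element-wise pooled confusion matrix, and the *mean*
of the two arm AUCs (not an AUC of pooled scores), mirroring the two-column
+ total reporting convention of the crossed design.

## Problem sizes and runtime choices

The test suite exercises the pipeline at deliberately small scale --
volumes around $24^3$--$32^3$ voxels, cohorts of 16--20 cases, GA budgets
of a few hundred to a few thousand evaluations -- chosen so the whole suite
runs in minutes while every behavioural claim (oracle equivalence,
motion recovery below 0.3 px, planted-feature recovery, separable cohorts
classified perfectly) is still exercised at full fidelity. All thresholds
in the tests were set from the statistical properties of the procedures,
not tuned to the observed outcomes.

## Known limitations

* **Split-optimisation optimism.** The evolutionary stage *maximises* the
  crossed test accuracy over feature subsets and splits. Re-reporting that
  same quantity for the winning chromosome is therefore optimistically
  biased: on cohorts where the two classes are generated from the *same*
  distribution, the pipeline still reports pooled accuracies far above
  chance (around 0.85--0.9 at 20 cases with the default search budgets; the
  bias grows with search effort and shrinks only slowly with cohort size).
  This is a property of the evaluation design itself, and it is the main
  caveat attached to headline numbers produced by this kind of pipeline at
  small sample sizes. A fixed chromosome evaluated on permuted labels
  scores 0.5, as it should -- the optimism comes from the search, not from
  the classifier.
* The synthetic phantoms are statistically, not anatomically, realistic;
  absolute performance numbers on them do not transfer to patients.
* Registration is 2D slice-wise by construction; through-plane motion is
  neither simulated nor corrected.
* The 4-value discrete probability yields a coarse, 4-point ROC; AUCs are
  correspondingly coarse.

## A worked run

```{r, eval = FALSE}
cfg <- pipelineConfig(
  cohort = cohortConfig(nBenign = 20, nMalignant = 20),
  twist = twistConfig(populationSize = 40, generations = 40),
  outDir = "run1", seed = 1)
report <- runPipeline(cfg)
report       # Table-style grid: per-arm and pooled metrics, CIs, AUCs
```
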