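# FocusRadiomics

Radiomic classification of small enhancing foci on dynamic contrast-enhanced
(DCE) breast MRI.

Enhancing foci are sub-5 mm dots of contrast enhancement that are hard to
characterise visually and often too small to biopsy, yet some are early
cancers. Their contrast kinetics differ by nature: benign foci enhance
slowly and persistently, malignant ones show fast wash-in followed by
wash-out. `FocusRadiomics` implements, as reusable R functions, the full
quantitative pipeline for this problem:

* **Registration** — slice-wise 2D affine co-registration of the four
  post-contrast volumes (T1–T4) to the unenhanced one (T0), minimising the
  mean square difference of z-scored intensities over a coarse-to-fine
  pyramid (`registerSeries()`).
* **Feature extraction** — 43 features per time-point, 215 per case
  (`extractFeatures()`): 6 first-order intensity statistics, 5 shape
  descriptors from the lesion mask, 12 grey-level co-occurrence (GLCM)
  statistics and 20 grey-level run-length (GLRLM) statistics, each texture
  statistic aggregated as mean and SD over the 13 unique 3D directions.
* **Feature selection + cohort splitting** — an evolutionary "training with
  input selection and testing" stage (`twist()`): a genetic algorithm over
  chromosomes that simultaneously pick a feature subset and split the
  cohort into two homogeneous groups A and B, scored by crossed k-NN
  accuracy.
* **Classification** — 3-nearest neighbours on z-scored features
  (`knnFit()`, `knnPredict()`) with the discrete positive-class
  probability P(+) ∈ {1, 0.66, 0.33, 0} for 3/2/1/0 positive neighbours
  and the 0.5 decision threshold (= majority vote).
* **Diagnostics** — crossed A→B / B→A evaluation (`crossedEvaluation()`):
  confusion matrices, sensitivity/specificity/accuracy/PPV/NPV with exact
  Clopper–Pearson 95% CIs, likelihood ratios, 4-point ROC curves and
  trapezoidal AUC per arm plus their mean.
* **Synthetic cohorts** — a DCE-MRI phantom generator
  (`generateCohort()`) with class-dependent kinetics
  `e(t) = A (1 − exp(−r_in t)) exp(−r_out t)`, texture, noise and optional
  per-slice affine motion with recorded ground truth, so the whole pipeline
  is testable without patient data.

Feature tables are `SummarizedExperiment` objects; cases read/write as
NIfTI volumes plus a JSON sidecar (`writeCase()`, `readCase()`,
`validateInputs()`).

## Worked example

End-to-end run on a synthetic cohort of 20 benign and 20 malignant foci
(default, well-separated class kinetics):

```r
library(FocusRadiomics)
cfg <- pipelineConfig(
  cohort = cohortConfig(nBenign = 20, nMalignant = 20,
                        volumeShape = c(24, 24, 10)),
  twist = twistConfig(populationSize = 40, generations = 40),
  seed = 1)
report <- runPipeline(cfg)
report
```

```
# Crossed A/B diagnostic performance

| Metric | A/B | B/A | Total | 95% CI (%) |
|---|---|---|---|---|
| Sensitivity | 100% | 100% | 100% | 83-100 |
| Specificity | 100% | 100% | 100% | 83-100 |
| Accuracy | 100% | 100% | 100% | 91-100 |
| ...
| Area under the curve | 1.00 | 1.00 | 1.00 | |
```

With the default class archetypes the cohort is separable and the crossed
evaluation is perfect; the confidence intervals reflect the cohort size
(Clopper–Pearson lower bound 91% for 40/40 correct). The per-metric layout
(arm A/B, arm B/A, pooled total, 95% CI) mirrors the standard reporting of
a crossed train/test design.

The component functions work standalone. For example, the diagnostics of a
pooled confusion matrix with 27 true positives, 37 true negatives, 4 false
positives and no false negatives:

```r
diagnosticMetrics(confusionMatrix(27, 37, 4, 0))[, c("metric", "display", "ci_display")]
#>        metric display ci_display
#> 1 sensitivity     100     87-100
#> 2 specificity      90      77-97
#> 3    accuracy      94      86-98
#> 4         ppv      87      70-96
#> 5         npv     100     91-100
#> 6 lr_positive      10       <NA>
#> 7 lr_negative       0       <NA>
```

i.e. sensitivity 27/27 = 100% (95% CI 87–100%), specificity 37/41 = 90%
(77–97%), accuracy 64/68 = 94% (86–98%).

A thin command-line wrapper around `runPipeline()` is provided in
`inst/scripts/run_pipeline.R` (YAML config in, artefact directory out).

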