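#' @import methods
#' @importFrom stats sd optim qbeta rnorm runif setNames p.adjust wilcox.test
#'   predict dnorm cov
NULL

#' DynamicSeries: a five-time-point dynamic contrast-enhanced volume
#'
#' Holds one unenhanced (T0) and four contrast-enhanced (T1--T4) 3D volumes
#' as a single 4D array, together with voxel spacing (mm) and acquisition
#' times (minutes).
#'
#' @slot data 4D numeric array, dimensions `x, y, z, 5`.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @slot times Numeric length-5 acquisition times in minutes, strictly
#'   increasing with `times[1] == 0`.
#' @export
setClass("DynamicSeries",
  representation(data = "array", spacing = "numeric", times = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 4L || d[4] != 5L)
      return("data must be a 4D array with 5 time-points")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values (mm)")
    if (length(object@times) != 5L || object@times[1] != 0 ||
        any(diff(object@times) <= 0))
      return("times must be 5 strictly increasing values starting at 0")
    TRUE
  }
)

#' LesionMask: a binary 3D lesion segmentation
#'
#' @slot mask Logical 3D array, `TRUE` inside the lesion.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @export
setClass("LesionMask",
  representation(mask = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
      return("mask must be a logical 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values (mm)")
    if (!any(object@mask)) return("mask must contain at least one voxel")
    TRUE
  }
)

#' SyntheticCase: one simulated DCE-MRI case with ground truth
#'
#' @slot series A [DynamicSeries-class].
#' @slot mask A [LesionMask-class] aligned to the series.
#' @slot label `"benign"` or `"malignant"`.
#' @slot truth List with the realised kinetic parameters, lesion geometry
#'   and any injected per-slice motion transforms.
#' @slot caseId Character case identifier.
#' @export
setClass("SyntheticCase",
  representation(series = "DynamicSeries", mask = "LesionMask",
                 label = "character", truth = "list", caseId = "character"),
  validity = function(object) {
    if (!object@label %in% c("benign", "malignant"))
      return("label must be 'benign' or 'malignant'")
    if (!identical(dim(object@mask@mask), dim(object@series@data)[1:3]))
      return("mask and series shapes differ")
    TRUE
  }
)

#' Affine2D: a centre-anchored 2D affine transform
#'
#' Maps output pixel coordinates to input sampling coordinates as
#' `q = M (p - c) + c + t`, where `c` is the image centre, `M` the 2x2
#' `matrix` slot and `t` the `translation` slot (pixels).
#'
#' @slot matrix 2x2 numeric matrix; must be invertible.
#' @slot translation Numeric length-2 translation in pixels.
#' @export
setClass("Affine2D",
  representation(matrix = "matrix", translation = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@matrix), c(2L, 2L)))
      return("matrix must be 2x2")
    if (abs(det(object@matrix)) <= 1e-8)
      return("matrix must be invertible (|det| > 1e-8)")
    if (length(object@translation) != 2L)
      return("translation must have length 2")
    TRUE
  }
)

#' QuantizedROI: grey-level quantized masked region
#'
#' @slot levels Integer 3D array; levels in `1..nLevels` inside the mask,
#'   `NA` outside.
#' @slot nLevels Integer number of grey levels.
#' @slot mask Logical 3D array.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @export
setClass("QuantizedROI",
  representation(levels = "array", nLevels = "integer", mask = "array",
                 spacing = "numeric"),
  validity = function(object) {
    lv <- object@levels[object@mask]
    if (anyNA(lv) || any(lv < 1L) || any(lv > object@nLevels))
      return("all masked voxels must have a level in [1, nLevels]")
    if (!all(is.na(object@levels[!object@mask])))
      return("unmasked voxels must be NA")
    TRUE
  }
)

#' FeatureTable: radiomic features by case
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] with one assay
#' `"features"` (features x cases) and a `label` column in `colData`
#' (`benign`, `malignant` or `unknown`).
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment",
  validity = function(object) {
    if (!"features" %in% SummarizedExperiment::assayNames(object))
      return("assay 'features' is required")
    if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
      return("colData must contain a 'label' column")
    lab <- SummarizedExperiment::colData(object)$label
    if (!all(lab %in% c("benign", "malignant", "unknown")))
      return("labels must be benign/malignant/unknown")
    if (any(!is.finite(SummarizedExperiment::assay(object, "features"))))
      return("all feature values must be finite")
    TRUE
  }
)

#' TwistResult: outcome of evolutionary feature selection + splitting
#'
#' @slot selectedFeatures Character vector of selected feature names.
#' @slot groupA,groupB Character case ids of the two groups (disjoint,
#'   jointly exhaustive).
#' @slot bestFitness Best crossed-classification fitness in `[0, 1]`.
#' @slot fitnessHistory data.frame with columns `generation`, `best`, `mean`.
#' @slot config List of the evolutionary settings used.
#' @export
setClass("TwistResult",
  representation(selectedFeatures = "character", groupA = "character",
                 groupB = "character", bestFitness = "numeric",
                 fitnessHistory = "data.frame", config = "list"),
  validity = function(object) {
    if (length(intersect(object@groupA, object@groupB)) > 0)
      return("groups A and B must be disjoint")
    if (length(object@selectedFeatures) < 1L)
      return("at least one feature must be selected")
    if (object@bestFitness < 0 || object@bestFitness > 1)
      return("bestFitness must lie in [0, 1]")
    TRUE
  }
)

#' KnnModel: k-nearest-neighbour classifier on z-scored features
#'
#' @slot train Numeric matrix (cases x features) of z-scored training
#'   features.
#' @slot labels Character training labels.
#' @slot k Integer neighbour count.
#' @slot center,scale Numeric per-feature normalisation learned from the
#'   training set.
#' @slot positiveClass Character label treated as positive.
#' @export
setClass("KnnModel",
  representation(train = "matrix", labels = "character", k = "integer",
                 center = "numeric", scale = "numeric",
                 positiveClass = "character"),
  validity = function(object) {
    if (object@k < 1L || object@k > nrow(object@train))
      return("k must satisfy 1 <= k <= number of training cases")
    if (any(object@scale <= 0)) return("all feature scales must be positive")
    if (!object@positiveClass %in% object@labels)
      return("positive class absent from training labels")
    if (length(unique(object@labels)) < 2L)
      return("training set must contain both classes")
    TRUE
  }
)

#' ConfusionMatrix: binary classification counts
#'
#' @slot tp,tn,fp,fn Non-negative integer counts.
#' @export
setClass("ConfusionMatrix",
  representation(tp = "integer", tn = "integer", fp = "integer",
                 fn = "integer"),
  validity = function(object) {
    v <- c(object@tp, object@tn, object@fp, object@fn)
    if (any(v < 0)) return("counts must be non-negative")
    if (sum(v) == 0) return("total count must be positive")
    TRUE
  }
)

#' DiagnosticReport: crossed A/B evaluation summary
#'
#' Per-arm (train A predict B; train B predict A) and pooled confusion
#' matrices, diagnostic metrics with exact binomial confidence intervals,
#' per-arm ROC curves and AUCs, and the mean AUC.
#'
#' @slot arms List with elements `AtoB` and `BtoA`, each holding `cm`,
#'   `metrics`, `roc` and `predictions`.
#' @slot pooled List with `cm` and `metrics` for the element-wise summed
#'   confusion matrix.
#' @slot aucMean Mean of the two per-arm AUCs.
#' @slot k Neighbour count used.
#' @export
setClass("DiagnosticReport",
  representation(arms = "list", pooled = "list", aucMean = "numeric",
                 k = "integer"),
  validity = function(object) {
    if (!all(c("AtoB", "BtoA") %in% names(object@arms)))
      return("arms must contain AtoB and BtoA")
    TRUE
  }
)
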