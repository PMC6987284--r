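setMethod("show", "DynamicSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("DynamicSeries: %d x %d x %d voxels, 5 time-points\n",
              d[1], d[2], d[3]))
  cat(sprintf("  spacing: %s mm; times: %s min\n",
              paste(object@spacing, collapse = " x "),
              paste(object@times, collapse = ", ")))
})

setMethod("show", "LesionMask", function(object) {
  cat(sprintf("LesionMask: %d voxels (%.1f mm^3)\n", sum(object@mask),
              sum(object@mask) * prod(object@spacing)))
})

setMethod("show", "SyntheticCase", function(object) {
  cat(sprintf("SyntheticCase '%s' (%s)\n", object@caseId, object@label))
  show(object@series)
  show(object@mask)
})

setMethod("show", "Affine2D", function(object) {
  cat("Affine2D: matrix\n")
  print(round(object@matrix, 4))
  cat("  translation:", round(object@translation, 4), "px\n")
})

setMethod("show", "TwistResult", function(object) {
  cat(sprintf(
    "TwistResult: %d features selected; |A| = %d, |B| = %d\n",
    length(object@selectedFeatures), length(object@groupA),
    length(object@groupB)))
  cat(sprintf("  best crossed fitness: %.3f over %d generation(s)\n",
              object@bestFitness, max(object@fitnessHistory$generation)))
})

setMethod("show", "KnnModel", function(object) {
  cat(sprintf(
    "KnnModel: k = %d, %d training cases, %d features (positive: %s)\n",
    object@k, nrow(object@train), ncol(object@train),
    object@positiveClass))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: TP %d, TN %d, FP %d, FN %d\n",
              object@tp, object@tn, object@fp, object@fn))
})

setMethod("show", "DiagnosticReport", function(object) {
  cat(formatReport(object), sep = "\n")
})
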