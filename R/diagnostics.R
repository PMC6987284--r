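#' Construct a confusion matrix
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return A [ConfusionMatrix-class].
#' @export
confusionMatrix <- function(tp, tn, fp, fn) {
  new("ConfusionMatrix", tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn))
}

#' @describeIn confusionMatrix Element-wise sum (pooling of evaluation
#'   arms).
#' @param e1,e2 `ConfusionMatrix` objects.
#' @export
setMethod("+", signature("ConfusionMatrix", "ConfusionMatrix"),
  function(e1, e2) {
    confusionMatrix(e1@tp + e2@tp, e1@tn + e2@tn, e1@fp + e2@fp,
                    e1@fn + e2@fn)
  })

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Exact interval from beta quantiles, in percent. The degenerate cases have
#' closed forms: for `x = n` the lower bound is `(alpha/2)^(1/n)` and the
#' upper bound 100%; `x = 0` is the mirror image.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param confidence Confidence level (default 0.95).
#' @return Named numeric `c(lower, upper)` in percent (full precision).
#' @export
clopperPearson <- function(successes, n, confidence = 0.95) {
  stopifnot(.isCount(n, 1L), .isCount(successes, 0L), successes <= n)
  a <- 1 - confidence
  lower <- if (successes == 0) 0 else qbeta(a / 2, successes,
                                            n - successes + 1)
  upper <- if (successes == n) 1 else qbeta(1 - a / 2, successes + 1,
                                            n - successes)
  c(lower = 100 * lower, upper = 100 * upper)
}

# internal: one proportion row with CI
.propRow <- function(metric, x, d, confidence = 0.95) {
  if (d == 0) {
    return(data.frame(metric = metric, numerator = x, denominator = d,
                      percent = NA_real_, display = NA_integer_,
                      ci_lower = NA_real_, ci_upper = NA_real_,
                      ci_display = NA_character_))
  }
  ci <- clopperPearson(x, d, confidence)
  pct <- 100 * x / d
  data.frame(metric = metric, numerator = x, denominator = d,
             percent = pct, display = as.integer(roundHalfUp(pct)),
             ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
             ci_display = sprintf("%d-%d", roundHalfUp(ci[["lower"]]),
                                  roundHalfUp(ci[["upper"]])))
}

#' Diagnostic accuracy metrics with exact binomial confidence intervals
#'
#' Sensitivity, specificity, accuracy, PPV and NPV as percentages with
#' Clopper-Pearson 95% CIs, plus positive and negative likelihood ratios.
#' Display values are rounded half-up to integer percent; full precision is
#' kept in the `percent` column. Metrics with a zero denominator are
#' reported as `NA` (undefined), never as 0.
#'
#' @param cm A [confusionMatrix()].
#' @param confidence Confidence level for the intervals.
#' @return data.frame, one row per metric; likelihood ratios carry no CI.
#' @export
diagnosticMetrics <- function(cm, confidence = 0.95) {
  stopifnot(is(cm, "ConfusionMatrix"))
  tp <- cm@tp; tn <- cm@tn; fp <- cm@fp; fn <- cm@fn
  out <- rbind(
    .propRow("sensitivity", tp, tp + fn, confidence),
    .propRow("specificity", tn, tn + fp, confidence),
    .propRow("accuracy", tp + tn, tp + tn + fp + fn, confidence),
    .propRow("ppv", tp, tp + fp, confidence),
    .propRow("npv", tn, tn + fn, confidence))
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  lrp <- if (!is.na(sens) && !is.na(spec) && spec < 1) {
    sens / (1 - spec)
  } else NA_real_
  lrn <- if (!is.na(sens) && !is.na(spec) && spec > 0) {
    (1 - sens) / spec
  } else NA_real_
  lr <- data.frame(
    metric = c("lr_positive", "lr_negative"),
    numerator = NA_integer_, denominator = NA_integer_,
    percent = c(lrp, lrn),
    display = as.integer(roundHalfUp(c(lrp, lrn))),
    ci_lower = NA_real_, ci_upper = NA_real_, ci_display = NA_character_)
  rbind(out, lr)
}

#' ROC curve and AUC from discrete classifier scores
#'
#' Sweeps the decision threshold over the distinct score values (for the
#' 3-NN rule: 0, 0.33, 0.66, 1), computes sensitivity and 1 - specificity
#' at each, and integrates by the trapezoidal rule from (0, 0) to (1, 1).
#' Ties are handled exactly: the trapezoidal AUC equals the rank statistic
#' (concordant pairs + half ties) / (n+ n-).
#'
#' @param scores Numeric per-case scores (higher = more positive).
#' @param labels Character case labels.
#' @param positiveClass Positive label (default `"malignant"`).
#' @return List with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
rocCurve <- function(scores, labels, positiveClass = "malignant") {
  pos <- labels == positiveClass
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0) stop("both classes must be present")
  th <- sort(unique(scores), decreasing = TRUE)
  pts <- data.frame(threshold = c(Inf, th),
                    fpr = c(0, vapply(th, function(t)
                      sum(scores[!pos] >= t) / nN, numeric(1))),
                    tpr = c(0, vapply(th, function(t)
                      sum(scores[pos] >= t) / nP, numeric(1))))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

# internal: confusion matrix from predictions
.cmFromPred <- function(pred, truth, positiveClass) {
  p <- pred == positiveClass
  t <- truth == positiveClass
  confusionMatrix(sum(p & t), sum(!p & !t), sum(p & !t), sum(!p & t))
}

#' Crossed A/B evaluation of the selected radiomic signature
#'
#' Fits the k-NN classifier on group A and predicts group B, then vice
#' versa, using only the selected features; reports per-arm and pooled
#' (element-wise summed) confusion matrices with metrics and exact binomial
#' CIs, per-arm ROC/AUC from the discrete `P(+)` scores, and the mean of the
#' two arm AUCs.
#'
#' @param table A [FeatureTable-class].
#' @param twistResult A [TwistResult-class] over the same cases.
#' @param k Neighbour count (default 3).
#' @param positiveClass Positive label (default `"malignant"`).
#' @param threshold Decision threshold on `P(+)`.
#' @return A [DiagnosticReport-class].
#' @export
crossedEvaluation <- function(table, twistResult, k = 3L,
                              positiveClass = "malignant",
                              threshold = 0.5) {
  stopifnot(is(table, "FeatureTable"), is(twistResult, "TwistResult"))
  X <- featureMatrix(table)[, twistResult@selectedFeatures, drop = FALSE]
  y <- setNames(caseLabels(table), caseIds(table))
  ids <- caseIds(table)
  stopifnot(all(c(twistResult@groupA, twistResult@groupB) %in% ids))
  arm <- function(trainIds, testIds, name) {
    ytr <- y[trainIds]; yte <- y[testIds]
    if (length(unique(ytr)) < 2L || length(unique(yte)) < 2L)
      stop("a group lacks one of the classes")
    model <- suppressWarnings(
      knnFit(X[trainIds, , drop = FALSE], ytr, k, positiveClass))
    pred <- knnPredict(model, X[testIds, , drop = FALSE], threshold)
    cm <- .cmFromPred(pred$predicted_class, yte, positiveClass)
    roc <- rocCurve(pred$p_positive, yte, positiveClass)
    list(name = name, cm = cm, metrics = diagnosticMetrics(cm), roc = roc,
         predictions = data.frame(case_id = testIds,
                                  label = as.character(yte),
                                  p_positive = pred$p_positive,
                                  predicted_class = pred$predicted_class))
  }
  ab <- arm(twistResult@groupA, twistResult@groupB, "AtoB")
  ba <- arm(twistResult@groupB, twistResult@groupA, "BtoA")
  pooledCm <- ab$cm + ba$cm
  new("DiagnosticReport",
      arms = list(AtoB = ab, BtoA = ba),
      pooled = list(cm = pooledCm, metrics = diagnosticMetrics(pooledCm)),
      aucMean = (ab$roc$auc + ba$roc$auc) / 2,
      k = as.integer(k))
}
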