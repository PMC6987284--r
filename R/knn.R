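#' Fit a k-nearest-neighbour classifier
#'
#' Learns per-feature z-score normalisation from the training set (constant
#' features are dropped with a warning) and stores the normalised training
#' matrix. Distances are Euclidean on the z-scored features.
#'
#' @param features Numeric matrix, cases x features, or a
#'   [FeatureTable-class].
#' @param labels Character training labels (ignored for a `FeatureTable`,
#'   which carries its own).
#' @param k Neighbour count (default 3, the model used throughout).
#' @param positiveClass Label treated as positive (default `"malignant"`).
#' @return A [KnnModel-class].
#' @export
knnFit <- function(features, labels = NULL, k = 3L,
                   positiveClass = "malignant") {
  if (is(features, "FeatureTable")) {
    labels <- caseLabels(features)
    features <- featureMatrix(features)
  }
  features <- as.matrix(features)
  stopifnot(length(labels) == nrow(features))
  if (k > nrow(features)) stop("k exceeds the number of training cases")
  ctr <- colMeans(features)
  scl <- apply(features, 2, sd)
  keep <- scl > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant feature(s) dropped")
    if (!any(keep)) stop("no non-constant features remain")
  }
  z <- sweep(sweep(features[, keep, drop = FALSE], 2, ctr[keep]), 2,
             scl[keep], "/")
  new("KnnModel", train = z, labels = as.character(labels),
      k = as.integer(k), center = ctr[keep], scale = scl[keep],
      positiveClass = positiveClass)
}

# internal: indices of the k nearest training cases for each query row;
# exact distance ties are broken by the lowest training-case index
.knnNeighbours <- function(model, z) {
  tr <- model@train
  d2 <- outer(rowSums(z^2), rowSums(tr^2), "+") - 2 * z %*% t(tr)
  nb <- lapply(seq_len(nrow(d2)), function(i)
    order(d2[i, ], seq_len(ncol(d2)))[seq_len(model@k)])
  matrix(unlist(nb), ncol = model@k, byrow = TRUE)
}

# internal: normalise query features with the training parameters
.knnNormalise <- function(model, features) {
  features <- as.matrix(features)
  nm <- names(model@center)
  if (!is.null(colnames(features))) {
    if (!all(nm %in% colnames(features)))
      stop("query features do not match the training feature names")
    features <- features[, nm, drop = FALSE]
  } else if (ncol(features) != length(nm)) {
    stop("query feature count does not match the training set")
  }
  sweep(sweep(features, 2, model@center), 2, model@scale, "/")
}

#' Discrete positive-class probability of the 3-NN rule
#'
#' For `k = 3`, `P(+)` is determined by the classes of the three nearest
#' training neighbours: 1 when all three are positive, 0.66 when two are,
#' 0.33 when one is, and 0 when none is. (For other `k` the vote fraction
#' `n+ / k` is returned.)
#'
#' @param model A fitted [knnFit()] model.
#' @param features Query feature matrix (cases x features) or a
#'   [FeatureTable-class].
#' @return Numeric vector of `P(+)`, with the neighbour index matrix as
#'   attribute `"neighbours"`.
#' @export
knnPredictProba <- function(model, features) {
  if (is(features, "FeatureTable")) features <- featureMatrix(features)
  z <- .knnNormalise(model, features)
  nb <- .knnNeighbours(model, z)
  npos <- apply(nb, 1, function(ix)
    sum(model@labels[ix] == model@positiveClass))
  p <- if (model@k == 3L) c(0, 0.33, 0.66, 1)[npos + 1L] else npos / model@k
  attr(p, "neighbours") <- nb
  p
}

#' Classify with the 0.5 probability threshold
#'
#' A case is assigned to the positive class iff `P(+) > threshold`; at the
#' default 0.5 this is the unweighted 3-NN majority vote.
#'
#' @inheritParams knnPredictProba
#' @param threshold Decision threshold on `P(+)` (default 0.5).
#' @return data.frame with `p_positive`, `predicted_class` and the
#'   neighbour indices as attribute `"neighbours"`.
#' @export
knnPredict <- function(model, features, threshold = 0.5) {
  p <- knnPredictProba(model, features)
  negClass <- setdiff(unique(model@labels), model@positiveClass)[1]
  out <- data.frame(
    p_positive = as.numeric(p),
    predicted_class = ifelse(p > threshold, model@positiveClass, negClass),
    stringsAsFactors = FALSE)
  attr(out, "neighbours") <- attr(p, "neighbours")
  out
}
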