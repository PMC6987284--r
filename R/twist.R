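#' Evolutionary selection settings
#'
#' Defaults follow standard genetic-algorithm practice: generational GA with
#' tournament selection, uniform crossover applied independently to the
#' feature-selection and group-split segments of the chromosome, per-bit
#' mutation and elitism.
#'
#' @param populationSize Chromosomes per generation (>= 2).
#' @param generations Number of generations (0 evaluates only the random
#'   initial population).
#' @param tournamentSize Tournament size for parent selection.
#' @param crossoverProb Probability of crossover per offspring.
#' @param mutationProb Per-bit mutation probability; `NULL` means
#'   `1 / genome length`.
#' @param elitism Number of best chromosomes copied unchanged (>= 1 keeps
#'   the best fitness non-decreasing).
#' @param k Neighbour count of the fitness classifier (default 3).
#' @param balanced Use balanced accuracy in the fitness (for unbalanced
#'   cohorts).
#' @param featureInitProb Probability that a feature bit starts on (sparse
#'   start).
#' @param seed Integer seed; the whole run is reproducible from it.
#' @return A validated `TwistConfig` list.
#' @export
twistConfig <- function(populationSize = 100, generations = 200,
                        tournamentSize = 2, crossoverProb = 0.9,
                        mutationProb = NULL, elitism = 1, k = 3,
                        balanced = FALSE, featureInitProb = 0.2,
                        seed = 1L) {
  stopifnot(.isCount(populationSize, 2L), .isCount(generations, 0L),
            .isCount(tournamentSize, 1L), .isCount(elitism, 0L),
            crossoverProb >= 0, crossoverProb <= 1,
            is.null(mutationProb) ||
              (mutationProb >= 0 && mutationProb <= 1),
            .isCount(k, 1L), featureInitProb > 0, featureInitProb <= 1)
  structure(list(populationSize = as.integer(populationSize),
                 generations = as.integer(generations),
                 tournamentSize = as.integer(tournamentSize),
                 crossoverProb = crossoverProb, mutationProb = mutationProb,
                 elitism = as.integer(elitism), k = as.integer(k),
                 balanced = balanced, featureInitProb = featureInitProb,
                 seed = as.integer(seed)),
            class = "TwistConfig")
}

# internal: crossed kNN accuracy of one chromosome on raw matrices.
# Invalid chromosomes (no feature selected, or a group with fewer than
# k + 1 cases of either class) score 0 rather than being repaired.
.chromosomeFitness <- function(X, y, feat, split, k, positive,
                               balanced = FALSE) {
  if (!any(feat)) return(0)
  for (grp in list(split, !split)) {
    if (sum(grp & y == positive) < k + 1 ||
        sum(grp & y != positive) < k + 1) return(0)
  }
  Xs <- X[, feat, drop = FALSE]
  arm <- function(tr, te) {
    ctr <- colMeans(Xs[tr, , drop = FALSE])
    scl <- apply(Xs[tr, , drop = FALSE], 2, sd)
    keep <- scl > 0
    if (!any(keep)) return(0)
    ztr <- sweep(sweep(Xs[tr, keep, drop = FALSE], 2, ctr[keep]), 2,
                 scl[keep], "/")
    zte <- sweep(sweep(Xs[te, keep, drop = FALSE], 2, ctr[keep]), 2,
                 scl[keep], "/")
    d2 <- outer(rowSums(zte^2), rowSums(ztr^2), "+") - 2 * zte %*% t(ztr)
    ytr <- y[tr]
    pred <- apply(d2, 1, function(di) {
      nb <- order(di, seq_along(di))[seq_len(k)]
      sum(ytr[nb] == positive) * 2L > k
    })
    truth <- y[te] == positive
    if (balanced) {
      (mean(pred[truth]) + mean(!pred[!truth])) / 2
    } else {
      mean(pred == truth)
    }
  }
  (arm(which(split), which(!split)) + arm(which(!split), which(split))) / 2
}

#' Fitness of one feature-subset / split chromosome
#'
#' Mean of the two crossed classification accuracies (train on group A,
#' test on B, and vice versa) of a k-nearest-neighbour classifier restricted
#' to the selected features. Chromosomes violating the validity constraints
#' (no feature selected, or a group with fewer than `k + 1` cases of either
#' class) receive fitness 0.
#'
#' @param featureMask Logical vector over the table's features, or a
#'   character vector of feature names.
#' @param split Logical vector over cases; `TRUE` = group A.
#' @param table A [FeatureTable-class].
#' @param k Neighbour count (default 3).
#' @param positiveClass Positive label (default `"malignant"`).
#' @param balanced Use balanced accuracy.
#' @return Fitness in `[0, 1]`.
#' @export
twistFitness <- function(featureMask, split, table, k = 3L,
                         positiveClass = "malignant", balanced = FALSE) {
  X <- featureMatrix(table)
  if (is.character(featureMask)) featureMask <- colnames(X) %in% featureMask
  stopifnot(length(featureMask) == ncol(X), length(split) == nrow(X))
  .chromosomeFitness(X, caseLabels(table), featureMask, split, k,
                     positiveClass, balanced)
}

#' Evolve a feature subset and train/test split simultaneously
#'
#' Generational genetic algorithm over chromosomes holding one bit per
#' feature (selected or not) and one bit per case (group A or B), scored by
#' the crossed k-nearest-neighbour accuracy of [twistFitness()]. Returns the
#' best chromosome decoded as a [TwistResult-class].
#'
#' @param table A [FeatureTable-class] with both classes present and at
#'   least `2 (k + 1)` cases per class.
#' @param cfg A [twistConfig()].
#' @param positiveClass Positive label (default `"malignant"`).
#' @return A [TwistResult-class].
#' @export
twist <- function(table, cfg = twistConfig(), positiveClass = "malignant") {
  stopifnot(is(table, "FeatureTable"), inherits(cfg, "TwistConfig"))
  X <- featureMatrix(table)
  y <- caseLabels(table)
  ids <- caseIds(table)
  n <- nrow(X); f <- ncol(X); k <- cfg$k
  for (cl in unique(y)) {
    if (sum(y == cl) < 2 * (k + 1))
      stop("class '", cl, "' has fewer than 2(k+1) cases; no valid split")
  }
  if (length(unique(y)) < 2L || !positiveClass %in% y)
    stop("both classes must be present")
  set.seed(cfg$seed)
  pop <- cfg$populationSize
  mut <- if (is.null(cfg$mutationProb)) 1 / (f + n) else cfg$mutationProb

  feats <- matrix(runif(pop * f) < cfg$featureInitProb, pop, f)
  none <- rowSums(feats) == 0
  if (any(none))
    feats[cbind(which(none), sample.int(f, sum(none), replace = TRUE))] <- TRUE
  splits <- matrix(runif(pop * n) < 0.5, pop, n)

  evalAll <- function(feats, splits, fit = rep(NA_real_, nrow(feats))) {
    for (i in which(is.na(fit)))
      fit[i] <- .chromosomeFitness(X, y, feats[i, ], splits[i, ], k,
                                   positiveClass, cfg$balanced)
    fit
  }
  fit <- evalAll(feats, splits)
  history <- data.frame(generation = 0L, best = max(fit), mean = mean(fit))

  for (g in seq_len(cfg$generations)) {
    ord <- order(fit, decreasing = TRUE)
    nf <- matrix(FALSE, pop, f); ns <- matrix(FALSE, pop, n)
    newFit <- rep(NA_real_, pop)
    nElite <- min(cfg$elitism, pop)
    if (nElite > 0) {
      el <- ord[seq_len(nElite)]
      nf[seq_len(nElite), ] <- feats[el, , drop = FALSE]
      ns[seq_len(nElite), ] <- splits[el, , drop = FALSE]
      newFit[seq_len(nElite)] <- fit[el]
    }
    pick <- function() {
      cand <- sample.int(pop, cfg$tournamentSize, replace = TRUE)
      cand[which.max(fit[cand])]
    }
    for (i in if (nElite < pop) seq(nElite + 1L, pop) else integer(0)) {
      p1 <- pick(); p2 <- pick()
      cf <- feats[p1, ]; cs <- splits[p1, ]
      if (runif(1) < cfg$crossoverProb) {
        mf <- runif(f) < 0.5
        cf[mf] <- feats[p2, mf]
        ms <- runif(n) < 0.5
        cs[ms] <- splits[p2, ms]
      }
      flipF <- runif(f) < mut
      cf[flipF] <- !cf[flipF]
      flipS <- runif(n) < mut
      cs[flipS] <- !cs[flipS]
      if (!any(cf)) cf[sample.int(f, 1L)] <- TRUE
      nf[i, ] <- cf; ns[i, ] <- cs
    }
    feats <- nf; splits <- ns
    fit <- evalAll(feats, splits, newFit)
    history <- rbind(history, data.frame(generation = g, best = max(fit),
                                         mean = mean(fit)))
  }

  best <- which.max(fit)
  new("TwistResult",
      selectedFeatures = colnames(X)[feats[best, ]],
      groupA = ids[splits[best, ]], groupB = ids[!splits[best, ]],
      bestFitness = fit[best], fitnessHistory = history,
      config = unclass(cfg))
}

#' Per-feature homogeneity of the A/B split
#'
#' Mann-Whitney comparison of every selected feature between groups A and B
#' with Benjamini-Hochberg adjusted q-values, documenting how statistically
#' homogeneous the evolved split is.
#'
#' @param result A [TwistResult-class].
#' @param table The [FeatureTable-class] it was computed on.
#' @param features Features to test (default the selected set).
#' @return data.frame with `feature`, `median_A`, `median_B`, `p`, `q`.
#' @export
splitBalanceReport <- function(result, table,
                               features = result@selectedFeatures) {
  X <- featureMatrix(table)
  stopifnot(all(features %in% colnames(X)))
  ia <- rownames(X) %in% result@groupA
  ib <- rownames(X) %in% result@groupB
  rows <- lapply(features, function(fn) {
    a <- X[ia, fn]; b <- X[ib, fn]
    p <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value)
    if (is.nan(p)) p <- 1  # all values tied across both groups
    data.frame(feature = fn, median_A = stats::median(a),
               median_B = stats::median(b), p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out
}
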