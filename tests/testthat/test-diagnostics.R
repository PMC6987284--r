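test_that("metrics reproduce the crossed-evaluation worked example", {
  m <- diagnosticMetrics(confusionMatrix(27, 37, 4, 0))
  g <- function(nm, col = "display") m[m$metric == nm, col]
  expect_identical(g("sensitivity"), 100L)
  expect_identical(g("specificity"), 90L)
  expect_identical(g("accuracy"), 94L)
  expect_identical(g("ppv"), 87L)
  expect_identical(g("npv"), 100L)
  expect_identical(g("lr_positive"), 10L)
  expect_identical(g("lr_negative"), 0L)
  expect_equal(g("specificity", "percent"), 100 * 37 / 41,
               tolerance = 1e-12)
  # degenerate and undefined cases
  all100 <- diagnosticMetrics(confusionMatrix(1, 1, 0, 0))
  expect_true(all(all100$display[1:5] == 100L))
  noNeg <- diagnosticMetrics(confusionMatrix(3, 0, 0, 2))
  expect_true(is.na(noNeg[noNeg$metric == "specificity", "percent"]))
})

test_that("confusion matrices pool by element-wise addition", {
  pooled <- confusionMatrix(11, 18, 2, 0) + confusionMatrix(16, 19, 2, 0)
  expect_identical(c(pooled@tp, pooled@tn, pooled@fp, pooled@fn),
                   c(27L, 37L, 4L, 0L))
  expect_error(confusionMatrix(0, 0, 0, 0), "positive")
  expect_error(confusionMatrix(-1, 2, 0, 0))
})

test_that("exact binomial intervals match closed forms and symmetry", {
  ci <- clopperPearson(27, 27)
  expect_equal(ci[["lower"]], 100 * 0.025^(1 / 27), tolerance = 1e-10)
  expect_identical(ci[["upper"]], 100)
  expect_identical(roundHalfUp(ci[["lower"]]), 87)
  expect_identical(roundHalfUp(clopperPearson(37, 37)[["lower"]]), 91)
  # x <-> n - x mirror symmetry
  a <- clopperPearson(0, 27)
  expect_equal(a[["upper"]], 100 - ci[["lower"]], tolerance = 1e-10)
  expect_identical(a[["lower"]], 0)
  expect_error(clopperPearson(5, 0))
  expect_error(clopperPearson(9, 5))
})

test_that("exact intervals keep at least nominal coverage", {
  # deterministic coverage computation: sum binomial probabilities of the
  # outcomes whose interval contains p
  n <- 41
  for (p in c(0.5, 0.9, 0.97)) {
    contains <- vapply(0:n, function(x) {
      ci <- clopperPearson(x, n)
      ci[["lower"]] / 100 <= p && p <= ci[["upper"]] / 100
    }, logical(1))
    coverage <- sum(dbinom(0:n, n, p)[contains])
    expect_gte(coverage, 0.95)
  }
  # and empirically over simulated binomials
  set.seed(17)
  for (p in c(0.5, 0.9, 0.97)) {
    x <- rbinom(2000, n, p)
    hit <- vapply(x, function(xi) {
      ci <- clopperPearson(xi, n)
      ci[["lower"]] / 100 <= p && p <= ci[["upper"]] / 100
    }, logical(1))
    expect_gte(mean(hit), 0.95)
  }
})

test_that("ROC handles the degenerate score patterns", {
  labs <- rep(c("malignant", "benign"), each = 5)
  sep <- rocCurve(c(rep(1, 5), rep(0, 5)), labs)
  expect_identical(sep$auc, 1)
  flat <- rocCurve(rep(0.33, 10), labs)
  expect_identical(flat$auc, 0.5)
  expect_error(rocCurve(runif(5), rep("benign", 5)), "both classes")
})

test_that("trapezoidal AUC equals the rank statistic on discrete scores", {
  set.seed(18)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    labs <- c("malignant", "benign",
              sample(c("malignant", "benign"), n - 2, replace = TRUE))
    scores <- sample(c(0, 0.33, 0.66, 1), n, replace = TRUE)
    r <- rocCurve(scores, labs)
    expect_equal(r$auc, oracleAUC(scores, labs, "malignant"),
                 tolerance = 1e-12)
  }
})

test_that("our AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  labs <- sample(c("malignant", "benign"), 40, replace = TRUE,
                 prob = c(0.4, 0.6))
  if (length(unique(labs)) < 2) labs[1:2] <- c("malignant", "benign")
  scores <- sample(c(0, 0.33, 0.66, 1), 40, replace = TRUE)
  ours <- rocCurve(scores, labs)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labs, predictor = scores, levels = c("benign", "malignant"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("crossed evaluation is perfect on a separable cohort", {
  ft <- separableTable(nPerClass = 12, seed = 20)
  ids <- caseIds(ft)
  res <- new("TwistResult", selectedFeatures = paste0("f", 1:4),
             groupA = ids[seq(1, 24, 2)], groupB = ids[seq(2, 24, 2)],
             bestFitness = 1,
             fitnessHistory = data.frame(generation = 0L, best = 1,
                                         mean = 1),
             config = list())
  rep <- crossedEvaluation(ft, res)
  pm <- rep@pooled$metrics
  expect_identical(pm[pm$metric == "accuracy", "display"], 100L)
  expect_identical(rep@arms$AtoB$roc$auc, 1)
  expect_identical(rep@aucMean, 1)
  cm <- rep@pooled$cm
  expect_identical(cm@tp + cm@tn + cm@fp + cm@fn, 24L)
})

test_that("labels permuted after the split give chance-level accuracy", {
  base <- plantedTable(nPerClass = 20, nInformative = 2, nNoise = 8,
                       seed = 300)
  tw <- twist(base, twistConfig(populationSize = 20, generations = 5,
                                seed = 2))
  X <- featureMatrix(base)
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    ft <- FeatureTable(X, sample(caseLabels(base)))
    rep <- crossedEvaluation(ft, tw)
    cm <- rep@pooled$cm
    (cm@tp + cm@tn) / (cm@tp + cm@tn + cm@fp + cm@fn)
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 2 * se + 1e-12)
})

test_that("a group missing one class is rejected", {
  ft <- separableTable(nPerClass = 6, seed = 21)
  ids <- caseIds(ft)
  res <- new("TwistResult", selectedFeatures = paste0("f", 1:4),
             groupA = ids[1:6], groupB = ids[7:12],  # A all benign
             bestFitness = 0,
             fitnessHistory = data.frame(generation = 0L, best = 0,
                                         mean = 0),
             config = list())
  expect_error(crossedEvaluation(ft, res), "lacks")
})
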