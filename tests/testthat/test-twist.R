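test_that("fitness is 1 for separable clusters and 0 for invalid
           chromosomes", {
  ft <- separableTable(nPerClass = 10)
  n <- 20
  split <- rep(c(TRUE, FALSE), 10)  # balanced across classes
  feat <- rep(TRUE, 4)
  expect_identical(twistFitness(feat, split, ft), 1)
  expect_identical(twistFitness(rep(FALSE, 4), split, ft), 0)
  # a group with fewer than k+1 cases of one class is invalid
  badSplit <- c(rep(TRUE, 19), FALSE)
  expect_identical(twistFitness(feat, badSplit, ft), 0)
})

test_that("fitness under permuted labels is indistinguishable from 0.5", {
  set.seed(15)
  base <- plantedTable(nPerClass = 15, nInformative = 2, nNoise = 10,
                       seed = 100)
  X <- featureMatrix(base)
  split <- rep(c(TRUE, FALSE), 15)
  fits <- vapply(1:20, function(s) {
    set.seed(s)
    ft <- FeatureTable(X, sample(caseLabels(base)))
    twistFitness(rep(TRUE, ncol(X)), split, ft)
  }, numeric(1))
  se <- sd(fits) / sqrt(length(fits))
  expect_lt(abs(mean(fits) - 0.5), 2 * se + 1e-12)
})

test_that("evolution is reproducible, bounded, and monotone under elitism", {
  ft <- plantedTable(nPerClass = 10, nInformative = 2, nNoise = 10, seed = 3)
  cfg <- twistConfig(populationSize = 20, generations = 10, seed = 77)
  r1 <- twist(ft, cfg)
  r2 <- twist(ft, cfg)
  expect_identical(r1@selectedFeatures, r2@selectedFeatures)
  expect_identical(r1@groupA, r2@groupA)
  expect_identical(r1@bestFitness, r2@bestFitness)
  expect_true(all(diff(r1@fitnessHistory$best) >= 0))
  expect_true(all(r1@fitnessHistory$best >= 0 &
                    r1@fitnessHistory$best <= 1))
  expect_setequal(c(r1@groupA, r1@groupB), caseIds(ft))
  expect_length(intersect(r1@groupA, r1@groupB), 0L)
})

test_that("zero generations returns the best of the initial population", {
  ft <- plantedTable(nPerClass = 10, nInformative = 2, nNoise = 10, seed = 4)
  r <- twist(ft, twistConfig(populationSize = 15, generations = 0,
                             seed = 5))
  expect_identical(nrow(r@fitnessHistory), 1L)
  expect_identical(r@fitnessHistory$generation, 0L)
})

test_that("cohorts too small for a valid split are rejected up front", {
  ft <- separableTable(nPerClass = 7)  # 7 < 2 (k + 1) = 8
  expect_error(twist(ft, twistConfig(populationSize = 10, generations = 1)),
               "fewer than")
})

test_that("planted informative features are recovered", {
  ft <- plantedTable(nPerClass = 30, nInformative = 3, nNoise = 50,
                     effectSize = 2, seed = 200)
  r <- twist(ft, twistConfig(populationSize = 40, generations = 40,
                             seed = 1))
  expect_true(all(paste0("inf", 1:3) %in% r@selectedFeatures))
  expect_gte(r@bestFitness, 0.9)
})

test_that("the balance report is calibrated under the null", {
  set.seed(16)
  X <- matrix(rnorm(40 * 50), 40, 50,
              dimnames = list(paste0("c", 1:40), paste0("f", 1:50)))
  ft <- FeatureTable(X, rep(c("benign", "malignant"), 20))
  res <- new("TwistResult", selectedFeatures = colnames(X),
             groupA = paste0("c", 1:20), groupB = paste0("c", 21:40),
             bestFitness = 0.5,
             fitnessHistory = data.frame(generation = 0L, best = 0.5,
                                         mean = 0.5),
             config = list())
  rep <- splitBalanceReport(res, ft)
  expect_lte(mean(rep$q < 0.05), 0.05)
})

test_that("identical groups give p = 1 and a planted shift is flagged", {
  X <- matrix(rnorm(20 * 5), 20, 5,
              dimnames = list(paste0("c", 1:20), paste0("f", 1:5)))
  X[11:20, ] <- X[1:10, ]  # group B duplicates group A case for case
  ft <- FeatureTable(X, rep("benign", 20))
  res <- new("TwistResult", selectedFeatures = colnames(X),
             groupA = paste0("c", 1:10), groupB = paste0("c", 11:20),
             bestFitness = 0.5,
             fitnessHistory = data.frame(generation = 0L, best = 0.5,
                                         mean = 0.5),
             config = list())
  expect_true(all(splitBalanceReport(res, ft)$p == 1))
  # plant a location shift in one feature of group B
  X2 <- X; X2[11:20, 3] <- X2[11:20, 3] + 10
  ft2 <- FeatureTable(X2, rep("benign", 20))
  rep2 <- splitBalanceReport(res, ft2)
  expect_lt(rep2$q[rep2$feature == "f3"], 0.05)
  expect_true(all(rep2$p[rep2$feature != "f3"] == 1))
})
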