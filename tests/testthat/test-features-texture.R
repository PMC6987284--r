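test_that("a constant ROI gives the degenerate single-cell GLCM", {
  roi <- list(levels = array(1L, c(3, 3, 3)), mask = array(TRUE, c(3, 3, 3)),
              nLevels = 8L)
  s <- glcmStats(glcmMatrix(asQuantized(roi), c(1, 0, 0)))
  expect_equal(s[["Energy"]], 1)
  expect_equal(s[["Entropy"]], 0)
  expect_equal(s[["InverseDifferenceMoment"]], 1)
  expect_equal(s[["Inertia"]], 0)
})

test_that("the alternating 1x1x4 line matches exhaustive pair counting", {
  lv <- array(NA_integer_, c(1, 1, 4))
  lv[1, 1, ] <- c(1L, 2L, 1L, 2L)
  roi <- list(levels = lv, mask = array(TRUE, c(1, 1, 4)), nLevels = 2L)
  q <- asQuantized(roi)
  P <- glcmMatrix(q, c(0, 0, 1))
  # 3 pairs, each a (1,2) or (2,1) combination -> symmetric off-diagonal
  expect_equal(P, matrix(c(0, 0.5, 0.5, 0), 2))
  s <- glcmStats(P)
  expect_equal(s[["Energy"]], 0.5)
  expect_equal(s[["Entropy"]], 1)
  expect_equal(s[["InverseDifferenceMoment"]], 0.5)
  expect_equal(s[["Inertia"]], 1)
  expect_equal(s[["ClusterShade"]], 0)
  expect_equal(unname(s), unname(oracleGLCMStats(oracleGLCM(lv, 2L,
                                                            c(0, 0, 1)))),
               tolerance = 1e-12)
})

test_that("co-occurrence matrices satisfy the probability identities", {
  set.seed(7)
  dirs <- directionSet3D()
  for (i in 1:5) {
    roi <- randomROI(c(4, 5, 3), nLevels = 6)
    q <- asQuantized(roi)
    for (di in sample(nrow(dirs), 4)) {
      P <- glcmMatrix(q, dirs[di, ])
      if (is.null(P)) next
      expect_equal(sum(P), 1, tolerance = 1e-12)
      expect_equal(P, t(P), tolerance = 1e-15)
      s <- glcmStats(P)
      expect_gte(s[["Entropy"]], 0)
      expect_gt(s[["Energy"]], 0)
      expect_lte(s[["Energy"]], 1)
    }
  }
})

test_that("run-length closed forms hold on degenerate lines", {
  # strictly alternating levels: all runs have length 1
  lv <- array(NA_integer_, c(1, 1, 6)); lv[1, 1, ] <- rep(c(1L, 2L), 3)
  q <- asQuantized(list(levels = lv, mask = array(TRUE, c(1, 1, 6)),
                        nLevels = 2L))
  s <- glrlmStats(glrlmMatrix(q, c(0, 0, 1)))
  expect_equal(s[["SRE"]], 1)
  expect_equal(s[["LRE"]], 1)
  # constant line of length L: one run, LRE = L^2
  L <- 5L
  lv <- array(NA_integer_, c(1, 1, L)); lv[1, 1, ] <- 3L
  q <- asQuantized(list(levels = lv, mask = array(TRUE, c(1, 1, L)),
                        nLevels = 4L))
  R <- glrlmMatrix(q, c(0, 0, 1))
  expect_identical(sum(R), 1L)
  s <- glrlmStats(R)
  expect_equal(s[["LRE"]], L^2)
  expect_equal(s[["SRE"]], 1 / L^2)
})

test_that("runs cover every masked voxel exactly once per direction", {
  set.seed(8)
  dirs <- directionSet3D()
  for (i in 1:5) {
    roi <- randomROI(c(5, 4, 4), nLevels = 4, pMask = 0.6)
    q <- asQuantized(roi)
    for (di in seq_len(nrow(dirs))) {
      R <- glrlmMatrix(q, dirs[di, ])
      covered <- sum(R %*% seq_len(ncol(R)))
      expect_equal(covered, sum(roi$mask), ignore_attr = TRUE)
    }
  }
})

test_that("texture statistics match the brute-force oracles on small ROIs", {
  set.seed(9)
  dirs <- directionSet3D()
  for (i in 1:8) {
    roi <- randomROI(c(4, 4, 4), nLevels = 5, pMask = 0.75)
    q <- asQuantized(roi)
    for (di in seq_len(nrow(dirs))) {
      P <- glcmMatrix(q, dirs[di, ])
      Po <- oracleGLCM(roi$levels, roi$nLevels, dirs[di, ])
      if (is.null(P)) {
        expect_null(Po)
      } else {
        expect_equal(glcmStats(P), oracleGLCMStats(Po), tolerance = 1e-12)
      }
      R <- glrlmMatrix(q, dirs[di, ])
      Ro <- oracleGLRLM(roi$levels, roi$nLevels, dirs[di, ])
      expect_equal(glrlmStats(R), oracleGLRLMStats(Ro), tolerance = 1e-12)
    }
  }
})

test_that("direction-averaged texture features are rotation coherent", {
  set.seed(10)
  cs <- generateCase("malignant", smallCohortConfig(), caseSeed = 31)
  cr <- cropToBbox(cs@series, cs@mask, margin = 1)
  vol <- seriesVolume(cr$series, 2)
  m <- cr$mask@mask
  rot <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  feats <- function(vol, m) {
    q <- quantizeROI(vol, m, 16)
    dirs <- directionSet3D()
    g <- sapply(seq_len(nrow(dirs)), function(di)
      glcmStats(glcmMatrix(q, dirs[di, ])))
    r <- sapply(seq_len(nrow(dirs)), function(di)
      glrlmStats(glrlmMatrix(q, dirs[di, ])))
    c(rowMeans(g), rowMeans(r))
  }
  expect_equal(feats(rot(vol), rot(m)), feats(vol, m), tolerance = 1e-10)
})

test_that("adding a constant shifts first-order features and nothing else", {
  cs <- generateCase("benign", smallCohortConfig(), caseSeed = 17)
  f0 <- extractFeatures(cs@series, cs@mask)
  shifted <- cs
  shifted@series@data <- cs@series@data + 50
  f1 <- extractFeatures(shifted@series, shifted@mask)
  for (ti in 0:4) {
    for (nm in c("Max", "Min", "Mean"))
      expect_equal(f1[[paste0(nm, "_T", ti)]],
                   f0[[paste0(nm, "_T", ti)]] + 50, tolerance = 1e-9)
    for (nm in c("Sigma", "Variance"))
      expect_equal(f1[[paste0(nm, "_T", ti)]], f0[[paste0(nm, "_T", ti)]],
                   tolerance = 1e-9)
  }
  texture <- grep("_Mean_T|_SD_T", names(f0), value = TRUE)
  expect_equal(f1[texture], f0[texture], tolerance = 1e-9)
})

test_that("extraction yields 43 features per time-point, shape replicated", {
  cs <- generateCase("malignant", smallCohortConfig(noiseSigma = 0),
                     caseSeed = 21)
  fv <- extractFeatures(cs@series, cs@mask)
  expect_length(fv, 215L)
  expect_true(all(is.finite(fv)))
  for (ti in 0:4)
    expect_identical(sum(endsWith(names(fv), paste0("_T", ti))), 43L)
  for (nm in c("Volume", "Eccentricity", "Elongation"))
    expect_length(unique(fv[paste0(nm, "_T", 0:4)]), 1L)
  # enhancing lesion: mean intensity rises after contrast
  expect_lt(fv[["Mean_T0"]], fv[["Mean_T2"]])
  # determinism
  expect_identical(fv, extractFeatures(cs@series, cs@mask))
})
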