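test_that("noiseless homogeneous lesions follow the kinetic model exactly", {
  cfg <- smallCohortConfig(noiseSigma = 0,
                           textureHeterogeneity = c(benign = 0,
                                                    malignant = 0))
  for (label in c("benign", "malignant")) {
    cs <- generateCase(label, cfg, caseSeed = 42)
    kp <- cs@truth$kinetics
    e <- kineticCurve(kp)
    for (ti in 0:4) {
      mu <- mean(seriesVolume(cs@series, ti)[cs@mask@mask])
      expect_equal(mu, kp$baselineIntensity * (1 + e[ti + 1]),
                   tolerance = 1e-12)
    }
  }
})

test_that("case generation is deterministic for a fixed seed", {
  cfg <- smallCohortConfig()
  a <- generateCase("malignant", cfg, caseSeed = 7)
  b <- generateCase("malignant", cfg, caseSeed = 7)
  expect_identical(a@series@data, b@series@data)
  expect_identical(a@mask@mask, b@mask@mask)
  expect_identical(a@truth$kinetics, b@truth$kinetics)
})

test_that("cohorts have the configured class counts and reproduce", {
  cfg <- cohortConfig(nBenign = 6, nMalignant = 4, seed = 3)
  cohort <- generateCohort(cfg)
  expect_length(cohort, 10L)
  labels <- vapply(cohort, function(cs) cs@label, character(1))
  expect_identical(sum(labels == "benign"), 6L)
  expect_identical(sum(labels == "malignant"), 4L)
  cohort2 <- generateCohort(cfg)
  for (i in seq_along(cohort))
    expect_identical(cohort[[i]]@series@data, cohort2[[i]]@series@data)
})

test_that("zero motion amplitude records identity transforms only", {
  cs <- generateCase("benign", smallCohortConfig(motionAmplitude = 0),
                     caseSeed = 5)
  for (ti in 1:4) for (A in cs@truth$motion[[ti]]) {
    expect_identical(A@matrix, diag(2))
    expect_identical(A@translation, c(0, 0))
  }
})

test_that("mask volume matches an independent digitization of the truth
           ellipsoid and brackets the analytic volume", {
  cfg <- smallCohortConfig(volumeShape = c(20, 20, 14))
  for (seed in c(2, 9, 23)) {
    cs <- generateCase("malignant", cfg, caseSeed = seed)
    tr <- cs@truth
    dims <- dim(cs@mask@mask)
    sp <- cs@mask@spacing
    # independent voxel-centre digitization of the recorded ellipsoid
    cnt <- 0L
    for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
      for (z in seq_len(dims[3])) {
        u <- t(tr$rotation) %*% ((c(x, y, z) - 0.5) * sp - tr$center)
        if (sum((u / tr$axes)^2) <= 1) cnt <- cnt + 1L
      }
    expect_identical(sum(cs@mask@mask), cnt)
    # analytic volume of ellipsoids shrunk/expanded by the half voxel
    # diagonal brackets the digitized volume
    h <- sqrt(sum((sp / 2)^2))
    lower <- 4 / 3 * pi * prod(pmax(tr$axes - h, 0))
    upper <- 4 / 3 * pi * prod(tr$axes + h)
    vox <- sum(cs@mask@mask) * prod(sp)
    expect_gte(vox, lower)
    expect_lte(vox, upper)
  }
})

test_that("lesions are a single connected component", {
  cfg <- smallCohortConfig()
  for (seed in 11:14) {
    cs <- generateCase("benign", cfg, caseSeed = seed)
    expect_true(isSingleComponent(cs@mask@mask))
  }
})

test_that("a lesion that cannot fit raises an error", {
  expect_error(
    generateCase("benign",
                 smallCohortConfig(volumeShape = c(24, 24, 5)),
                 caseSeed = 1),
    "does not fit")
})

test_that("injected motion is reproducible and invertible", {
  cfg <- smallCohortConfig(noiseSigma = 0)
  base <- generateCase("malignant", cfg, caseSeed = 3)
  m1 <- injectMotion(base, amplitude = 2, seed = 99)
  m2 <- injectMotion(base, amplitude = 2, seed = 99)
  for (ti in 1:4) for (z in seq_along(m1@truth$motion[[ti]])) {
    expect_identical(m1@truth$motion[[ti]][[z]]@matrix,
                     m2@truth$motion[[ti]][[z]]@matrix)
    expect_identical(m1@truth$motion[[ti]][[z]]@translation,
                     m2@truth$motion[[ti]][[z]]@translation)
  }
  expect_identical(m1@series@data, m2@series@data)
  expect_identical(m1@series@data[, , , 1], base@series@data[, , , 1])
  # applying the recorded inverse restores the series up to interpolation
  # error: the residual must be far below the motion-induced change
  movedErr <- 0; restoredErr <- 0
  for (ti in 2:5) for (z in seq_len(dim(base@series@data)[3])) {
    orig <- base@series@data[, , z, ti]
    moved <- m1@series@data[, , z, ti]
    A <- m1@truth$motion[[ti - 1]][[z]]
    restored <- applyAffine2D(moved, invertAffine2D(A))
    interior <- 4:(nrow(orig) - 3)
    movedErr <- movedErr + mean(abs(moved - orig)[interior, interior])
    restoredErr <- restoredErr +
      mean(abs(restored - orig)[interior, interior])
  }
  expect_lt(restoredErr, 0.5 * movedErr)
})
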