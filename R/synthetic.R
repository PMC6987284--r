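#' Construct a DynamicSeries
#'
#' @param data 4D numeric array `x, y, z, 5` (T0 unenhanced, T1--T4
#'   enhanced).
#' @param spacing Voxel spacing in mm (length 3).
#' @param times Acquisition times in minutes (length 5, first 0).
#' @return A [DynamicSeries-class] object.
#' @export
DynamicSeries <- function(data, spacing = c(1, 1, 1), times = 0:4) {
  new("DynamicSeries", data = data, spacing = as.numeric(spacing),
      times = as.numeric(times))
}

#' Construct a LesionMask
#'
#' @param mask Logical 3D array.
#' @param spacing Voxel spacing in mm (length 3).
#' @return A [LesionMask-class] object.
#' @export
LesionMask <- function(mask, spacing = c(1, 1, 1)) {
  new("LesionMask", mask = mask, spacing = as.numeric(spacing))
}

#' @describeIn DynamicSeries-class Extract the 3D volume at time-point `t`
#'   (0-based, 0..4).
#' @param series A `DynamicSeries`.
#' @param t Time-point index in 0..4.
#' @export
seriesVolume <- function(series, t) {
  stopifnot(is(series, "DynamicSeries"), t %in% 0:4)
  series@data[, , , t + 1L, drop = TRUE]
}

#' Cohort simulation settings
#'
#' Defines the acquisition geometry and the two class archetypes for the
#' synthetic DCE-MRI generator: 1 mm slices, 1 x 1 mm in-plane resolution
#' and a 60 s dynamic interval; benign foci with slow persistent
#' enhancement and mild texture, malignant foci with fast wash-in/wash-out
#' and stronger texture heterogeneity.
#'
#' @param nBenign,nMalignant Cases per class (both >= 1).
#' @param volumeShape Volume dimensions in voxels (length 3).
#' @param voxelSpacing Voxel spacing in mm (length 3).
#' @param lesionDiameterRange List with `benign` and `malignant` length-2
#'   numeric diameter ranges in mm (focus regime: <= 5 mm).
#' @param noiseSigma SD of additive Gaussian noise, signal units.
#' @param textureHeterogeneity Named numeric, per-class scalar >= 0 scaling
#'   the multiplicative lesion texture field.
#' @param motionAmplitude Maximum per-slice translation (pixels); 0 disables
#'   motion injection.
#' @param kinetics List with `benign` and `malignant` [kineticParams()].
#' @param kineticJitter Per-case uniform relative jitter applied to
#'   baseline, amplitude and rates (fraction, >= 0).
#' @param background List: `level` (signal units), `textureSd` (signal
#'   units) and `smoothSigma` (voxels) of the smoothed-noise parenchyma.
#' @param seed Integer seed; all cohort randomness derives from it.
#' @return A validated `CohortConfig` list.
#' @export
cohortConfig <- function(nBenign = 20, nMalignant = 20,
                         volumeShape = c(32, 32, 14),
                         voxelSpacing = c(1, 1, 1),
                         lesionDiameterRange = list(benign = c(3, 5),
                                                    malignant = c(3, 5)),
                         noiseSigma = 5,
                         textureHeterogeneity = c(benign = 0.05,
                                                  malignant = 0.15),
                         motionAmplitude = 0,
                         kinetics = list(
                           benign = kineticParams(100, 0.6, 0.7, 0),
                           malignant = kineticParams(100, 1.2, 3, 0.4)),
                         kineticJitter = 0.1,
                         background = list(level = 60, textureSd = 8,
                                           smoothSigma = 2.5),
                         seed = 1L) {
  stopifnot(.isCount(nBenign, 1L), .isCount(nMalignant, 1L),
            nBenign + nMalignant >= 2)
  stopifnot(length(volumeShape) == 3L, all(volumeShape >= 4),
            length(voxelSpacing) == 3L, all(voxelSpacing > 0))
  for (cl in c("benign", "malignant")) {
    r <- lesionDiameterRange[[cl]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2] ||
        r[1] < 2 * max(voxelSpacing))
      stop("lesionDiameterRange$", cl,
           " must be an increasing range with lower bound >= 2 voxels")
  }
  stopifnot(noiseSigma >= 0, all(textureHeterogeneity >= 0),
            motionAmplitude >= 0, kineticJitter >= 0, kineticJitter < 1)
  stopifnot(inherits(kinetics$benign, "KineticParams"),
            inherits(kinetics$malignant, "KineticParams"))
  structure(list(nBenign = as.integer(nBenign),
                 nMalignant = as.integer(nMalignant),
                 volumeShape = as.integer(volumeShape),
                 voxelSpacing = as.numeric(voxelSpacing),
                 lesionDiameterRange = lesionDiameterRange,
                 noiseSigma = noiseSigma,
                 textureHeterogeneity = textureHeterogeneity,
                 motionAmplitude = motionAmplitude,
                 kinetics = kinetics, kineticJitter = kineticJitter,
                 background = background, seed = as.integer(seed)),
            class = "CohortConfig")
}

#' Generate one synthetic DCE-MRI case
#'
#' Places a randomly oriented ellipsoidal lesion of class-dependent diameter
#' inside a smoothed-noise parenchyma background. Lesion voxels follow
#' `baseline * (1 + e(t)) * (1 + h * texture)` where `e(t)` is the class
#' kinetic curve and `h` the class heterogeneity; independent Gaussian noise
#' is added per volume. The realised parameters are stored as ground truth.
#'
#' @param label `"benign"` or `"malignant"`.
#' @param cfg A [cohortConfig()].
#' @param caseSeed Integer seed for this case's RNG stream.
#' @param caseId Character identifier.
#' @return A [SyntheticCase-class].
#' @export
generateCase <- function(label, cfg, caseSeed = cfg$seed,
                         caseId = paste0(label, "_1")) {
  stopifnot(inherits(cfg, "CohortConfig"), label %in% c("benign", "malignant"))
  set.seed(caseSeed)
  dims <- cfg$volumeShape
  sp <- cfg$voxelSpacing
  size <- dims * sp

  # lesion geometry: random diameter in the class range, mildly anisotropic
  # semi-axes, random orientation
  dr <- cfg$lesionDiameterRange[[label]]
  diameter <- runif(1, dr[1], dr[2])
  axes <- (diameter / 2) * c(1, runif(2, 0.7, 1))
  rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  maxAx <- max(axes)
  lo <- maxAx + sp
  hi <- size - maxAx - sp
  if (any(lo >= hi)) stop("lesion does not fit in the volume")
  center <- runif(3, lo, hi)

  # voxel centres in physical coordinates
  g <- lapply(1:3, function(a) ((seq_len(dims[a]) - 0.5) * sp[a]))
  coords <- as.matrix(expand.grid(x = g[[1]], y = g[[2]], z = g[[3]]))
  u <- (coords - matrix(center, nrow(coords), 3, byrow = TRUE)) %*% rot
  inside <- rowSums(sweep(u, 2, axes, "/")^2) <= 1
  mask <- array(inside, dim = dims)
  if (!any(mask)) stop("lesion mask is empty; diameter too small for grid")

  # per-case kinetic jitter
  j <- cfg$kineticJitter
  k0 <- cfg$kinetics[[label]]
  jit <- function(x) if (j > 0) x * (1 + runif(1, -j, j)) else x
  kp <- kineticParams(jit(k0$baselineIntensity), jit(k0$washInAmplitude),
                      jit(k0$washInRate),
                      if (k0$washOutRate > 0) jit(k0$washOutRate) else 0,
                      k0$timePoints)
  enh <- kineticCurve(kp)

  bg <- cfg$background$level +
    cfg$background$textureSd * .smoothField(dims, cfg$background$smoothSigma)
  tex <- .smoothField(dims, 1.5)
  h <- cfg$textureHeterogeneity[[label]]

  data <- array(0, dim = c(dims, 5L))
  for (ti in 1:5) {
    vol <- bg
    vol[mask] <- kp$baselineIntensity * (1 + enh[ti]) *
      (if (h > 0) 1 + h * tex[mask] else 1)
    if (cfg$noiseSigma > 0)
      vol <- vol + rnorm(length(vol), sd = cfg$noiseSigma)
    data[, , , ti] <- vol
  }

  obj <- new("SyntheticCase",
             series = DynamicSeries(data, sp, k0$timePoints),
             mask = LesionMask(mask, sp), label = label,
             truth = list(kinetics = kp, enhancement = enh,
                          center = center, axes = axes, rotation = rot,
                          diameter = diameter, motion = list()),
             caseId = caseId)
  injectMotion(obj, cfg$motionAmplitude,
               seed = stageSeed(caseSeed, "motion"))
}

#' Generate a reproducible synthetic cohort
#'
#' Per-case RNG streams are derived from `cfg$seed` and the case identifier,
#' so cohorts are reproducible and individual cases do not depend on
#' generation order.
#'
#' @param cfg A [cohortConfig()].
#' @return List of [SyntheticCase-class] objects (benign first).
#' @export
generateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "CohortConfig"))
  labels <- c(rep("benign", cfg$nBenign), rep("malignant", cfg$nMalignant))
  ids <- paste0(labels, "_", unlist(lapply(
    c(cfg$nBenign, cfg$nMalignant), seq_len)))
  lapply(seq_along(labels), function(i) {
    generateCase(labels[i], cfg,
                 caseSeed = stageSeed(cfg$seed, paste0("case_", ids[i])),
                 caseId = ids[i])
  })
}

#' Inject per-slice affine motion into the enhanced volumes
#'
#' Resamples every slice of T1--T4 under an independent random 2D affine
#' (translation up to `amplitude` pixels, small rotation and shear); T0 is
#' left untouched. The true transforms are recorded in `truth$motion` (a
#' list indexed `[[time]][[slice]]`) so registration recovery can be scored.
#' With `amplitude = 0` the image data are unchanged and identity transforms
#' are recorded.
#'
#' @param case A [SyntheticCase-class].
#' @param amplitude Maximum absolute translation in pixels (>= 0).
#' @param seed Integer seed for the motion RNG stream.
#' @return The case with moved T1--T4 volumes and recorded truth.
#' @export
injectMotion <- function(case, amplitude, seed = 1L) {
  stopifnot(is(case, "SyntheticCase"), amplitude >= 0)
  set.seed(seed)
  dims <- dim(case@series@data)
  motion <- vector("list", 4L)
  data <- case@series@data
  for (ti in 2:5) {
    motion[[ti - 1L]] <- vector("list", dims[3])
    for (z in seq_len(dims[3])) {
      if (amplitude == 0) {
        A <- affine2d(diag(2), c(0, 0))
      } else {
        theta <- runif(1, -0.02, 0.02)
        shear <- runif(1, -0.01, 0.01)
        M <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)),
                    2, 2) %*% matrix(c(1, 0, shear, 1), 2, 2)
        A <- affine2d(M, runif(2, -amplitude, amplitude))
        data[, , z, ti] <- applyAffine2D(data[, , z, ti], A)
      }
      motion[[ti - 1L]][[z]] <- A
    }
  }
  case@series@data <- data
  case@truth$motion <- motion
  case
}
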