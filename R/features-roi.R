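#' Crop a series and mask to the lesion bounding box
#'
#' Restricts all five volumes and the mask to the tight bounding box of the
#' mask plus a margin, clipped to the volume bounds. Masked statistics are
#' unaffected by cropping; it only removes uninformative surroundings.
#'
#' @param series A [DynamicSeries-class].
#' @param mask A [LesionMask-class] (nonempty).
#' @param margin Margin in voxels (>= 0).
#' @return List with cropped `series` and `mask`.
#' @export
cropToBbox <- function(series, mask, margin = 2L) {
  stopifnot(is(series, "DynamicSeries"), is(mask, "LesionMask"), margin >= 0)
  m <- mask@mask
  if (!any(m)) stop("empty mask")
  idx <- which(m, arr.ind = TRUE)
  dims <- dim(m)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, dims)
  ranges <- lapply(1:3, function(a) lo[a]:hi[a])
  list(series = DynamicSeries(
         series@data[ranges[[1]], ranges[[2]], ranges[[3]], , drop = FALSE],
         series@spacing, series@times),
       mask = LesionMask(
         m[ranges[[1]], ranges[[2]], ranges[[3]], drop = FALSE],
         mask@spacing))
}

#' Quantize masked voxels onto a grey-level grid
#'
#' Equal-width bins between the masked minimum and maximum:
#' `level = min(floor((v - min) / (max - min) * nLevels) + 1, nLevels)`.
#' A constant ROI maps every voxel to level 1 (degenerate rule), so
#' unenhanced early time-points remain processable.
#'
#' @param volume Numeric 3D array.
#' @param mask Logical 3D array of the same shape.
#' @param nLevels Number of grey levels (default 32).
#' @param spacing Voxel spacing in mm.
#' @return A [QuantizedROI-class].
#' @export
quantizeROI <- function(volume, mask, nLevels = 32L, spacing = c(1, 1, 1)) {
  stopifnot(identical(dim(volume), dim(mask)), .isCount(nLevels, 1L))
  v <- volume[mask]
  if (length(v) == 0L) stop("empty mask")
  mn <- min(v); mx <- max(v)
  lv <- if (mx > mn) {
    pmin(floor((v - mn) / (mx - mn) * nLevels) + 1L, nLevels)
  } else {
    rep(1L, length(v))
  }
  levels <- array(NA_integer_, dim = dim(volume))
  levels[mask] <- as.integer(lv)
  new("QuantizedROI", levels = levels, nLevels = as.integer(nLevels),
      mask = mask, spacing = as.numeric(spacing))
}

#' First-order intensity statistics of the masked voxels
#'
#' @param volume Numeric 3D array.
#' @param mask Logical 3D array.
#' @param spacing Voxel spacing in mm (for IntegratedIntensity).
#' @return Named numeric: `Max`, `Min`, `Mean`, `Sigma`, `Variance`
#'   (population variance), `IntegratedIntensity` (sum x voxel volume,
#'   mm^3-weighted).
#' @export
intensityFeatures <- function(volume, mask, spacing = c(1, 1, 1)) {
  v <- volume[mask]
  if (length(v) == 0L) stop("empty mask")
  mu <- mean(v)
  va <- mean((v - mu)^2)
  c(Max = max(v), Min = min(v), Mean = mu, Sigma = sqrt(va), Variance = va,
    IntegratedIntensity = sum(v) * prod(spacing))
}

#' 3D shape descriptors of a binary mask
#'
#' Equivalent-ellipsoid conventions on the covariance of the masked voxel
#' physical coordinates (eigenvalues `l1 >= l2 >= l3`): axis lengths
#' `4 sqrt(l)`, `Elongation = sqrt(l1 / l2)` (>= 1) and
#' `Eccentricity = sqrt(1 - l3 / l1)`.
#'
#' @param mask Logical 3D array with at least one voxel.
#' @param spacing Voxel spacing in mm.
#' @return Named numeric: `Eccentricity`, `Elongation`, `MajorAxisLength`,
#'   `MinorAxisLength` (mm), `Volume` (mm^3). Masks with fewer than 2 voxels
#'   return zero axes with a warning.
#' @export
shapeFeatures <- function(mask, spacing = c(1, 1, 1)) {
  n <- sum(mask)
  if (n == 0L) stop("empty mask")
  vol <- n * prod(spacing)
  if (n < 2L) {
    warning("fewer than 2 voxels; axis lengths undefined, reported as 0")
    return(c(Eccentricity = 0, Elongation = 0, MajorAxisLength = 0,
             MinorAxisLength = 0, Volume = vol))
  }
  xyz <- which(mask, arr.ind = TRUE)
  phys <- sweep(xyz, 2, spacing, "*")
  ctr <- colMeans(phys)
  d <- sweep(phys, 2, ctr)
  covm <- crossprod(d) / n  # population covariance
  ev <- sort(pmax(eigen(covm, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  c(Eccentricity = if (ev[1] > 0) sqrt(1 - ev[3] / ev[1]) else 0,
    Elongation = if (ev[2] > 0) sqrt(ev[1] / ev[2]) else 0,
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[3]),
    Volume = vol)
}

#' The 13 unique 3D directions of the 26-neighbourhood
#'
#' Displacement vectors at Chebyshev distance 1, unique modulo sign
#' (co-occurrence pairs and runs are orientation-symmetric).
#'
#' @return A 13 x 3 integer matrix of offsets.
#' @export
directionSet3D <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  out <- g[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  rownames(out) <- apply(out, 1, paste, collapse = ",")
  out
}
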