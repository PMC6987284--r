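#' Grey-level co-occurrence matrix for one 3D direction
#'
#' Counts pairs of masked voxels separated by the offset `direction`
#' (both orientations, giving a symmetric matrix) and normalises to
#' probabilities. Unmasked voxels never participate in a pair.
#'
#' @param q A [QuantizedROI-class].
#' @param direction Integer length-3 offset (one row of [directionSet3D()]).
#' @return `nLevels x nLevels` probability matrix, or `NULL` when the mask
#'   admits no voxel pair in that direction.
#' @export
glcmMatrix <- function(q, direction) {
  stopifnot(is(q, "QuantizedROI"), length(direction) == 3L)
  dims <- dim(q@mask)
  idx <- which(q@mask)
  coord <- arrayInd(idx, dims)
  nb <- sweep(coord, 2, as.integer(direction), "+")
  ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
        nb[, 2] >= 1L & nb[, 2] <= dims[2] &
        nb[, 3] >= 1L & nb[, 3] <= dims[3]
  if (!any(ok)) return(NULL)
  nbLin <- (nb[ok, 3] - 1L) * dims[1] * dims[2] +
           (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
  paired <- q@mask[nbLin]
  if (!any(paired)) return(NULL)
  a <- q@levels[idx[ok][paired]]
  b <- q@levels[nbLin[paired]]
  n <- q@nLevels
  cnt <- tabulate((a - 1L) * n + b, nbins = n * n)
  M <- matrix(cnt, n, n, byrow = TRUE)
  M <- M + t(M)
  M / sum(M)
}

#' Second-order (co-occurrence) texture statistics
#'
#' With `p(i, j)` the symmetric normalised GLCM and
#' `mu = sum(i * p(i, .))`: Energy `sum(p^2)`; Entropy `-sum(p log2 p)`
#' (with `0 log 0 = 0`); InverseDifferenceMoment
#' `sum(p / (1 + (i - j)^2))`; Inertia (contrast) `sum((i - j)^2 p)`;
#' ClusterShade `sum((i + j - 2 mu)^3 p)`; ClusterProminence the 4th-power
#' analogue.
#'
#' @param P GLCM probability matrix from [glcmMatrix()].
#' @return Named numeric of the 6 statistics.
#' @export
glcmStats <- function(P) {
  n <- nrow(P)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  mux <- sum(i * P)
  muy <- sum(j * P)
  pos <- P > 0
  c(Energy = sum(P^2),
    Entropy = -sum(P[pos] * log2(P[pos])),
    InverseDifferenceMoment = sum(P / (1 + (i - j)^2)),
    Inertia = sum((i - j)^2 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterProminence = sum((i + j - mux - muy)^4 * P))
}

#' Grey-level run-length matrix for one 3D direction
#'
#' Runs are maximal segments of equal-level masked voxels along the
#' direction; a run breaks at mask boundaries. Entry `r[i, j]` counts runs
#' of level `i` and length `j`, so `sum_j j * r[i, j]` over all `i` equals
#' the number of masked voxels.
#'
#' @inheritParams glcmMatrix
#' @return `nLevels x maxRunLength` integer count matrix, or `NULL` when the
#'   mask is empty.
#' @export
glrlmMatrix <- function(q, direction) {
  stopifnot(is(q, "QuantizedROI"), length(direction) == 3L)
  d <- as.integer(direction)
  dims <- dim(q@mask)
  idx <- which(q@mask)
  if (length(idx) == 0L) return(NULL)
  coord <- arrayInd(idx, dims)
  ax <- which(d != 0L)[1]
  tt <- coord[, ax] * d[ax]  # position along the line (monotone in the walk)
  # line identifier: starting point of the line through the voxel
  base <- coord - tt %*% t(d)
  B <- 3L * max(dims) + 3L
  off <- max(dims) + 1L
  key <- ((base[, 1] + off) * B + (base[, 2] + off)) * B + (base[, 3] + off)
  ord <- order(key, tt)
  k <- key[ord]; to <- tt[ord]; lv <- q@levels[idx][ord]
  N <- length(k)
  newRun <- c(TRUE, k[-1] != k[-N] | to[-1] != to[-N] + 1L | lv[-1] != lv[-N])
  runId <- cumsum(newRun)
  lens <- tabulate(runId)
  levs <- lv[newRun]
  n <- q@nLevels
  J <- max(lens)
  cnt <- tabulate((lens - 1L) * n + levs, nbins = n * J)
  matrix(cnt, n, J)
}

#' Run-length texture statistics
#'
#' The ten classical run-length statistics: short/long run emphasis, grey
#' level and run-length non-uniformity, low/high grey level run emphasis and
#' the four joint short/long x low/high emphases.
#'
#' @param R Run count matrix from [glrlmMatrix()].
#' @return Named numeric of the 10 statistics (`SRE`, `LRE`, `GLN`, `RLN`,
#'   `LGLRE`, `HGLRE`, `SRLGLE`, `SRHGLE`, `LRLGLE`, `LRHGLE`).
#' @export
glrlmStats <- function(R) {
  Nr <- sum(R)
  if (Nr == 0) stop("no runs")
  n <- nrow(R); J <- ncol(R)
  i <- matrix(seq_len(n), n, J)
  j <- matrix(seq_len(J), n, J, byrow = TRUE)
  c(SRE = sum(R / j^2) / Nr,
    LRE = sum(R * j^2) / Nr,
    GLN = sum(rowSums(R)^2) / Nr,
    RLN = sum(colSums(R)^2) / Nr,
    LGLRE = sum(R / i^2) / Nr,
    HGLRE = sum(R * i^2) / Nr,
    SRLGLE = sum(R / (i^2 * j^2)) / Nr,
    SRHGLE = sum(R * i^2 / j^2) / Nr,
    LRLGLE = sum(R * j^2 / i^2) / Nr,
    LRHGLE = sum(R * i^2 * j^2) / Nr)
}
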