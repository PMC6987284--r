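#' Construct a 2D affine transform
#'
#' @param matrix 2x2 numeric matrix (dimensionless).
#' @param translation Length-2 translation in pixels.
#' @return An [Affine2D-class] object.
#' @export
affine2d <- function(matrix = diag(2), translation = c(0, 0)) {
  new("Affine2D", matrix = matrix, translation = as.numeric(translation))
}

#' @describeIn affine2d Compose two transforms: `(A %then% B)(x) = A(B(x))`
#'   under the shared image-centre convention.
#' @param A,B `Affine2D` objects.
#' @export
composeAffine2D <- function(A, B) {
  affine2d(A@matrix %*% B@matrix,
           as.numeric(A@matrix %*% B@translation) + A@translation)
}

#' @describeIn affine2d Exact inverse transform.
#' @export
invertAffine2D <- function(A) {
  Mi <- solve(A@matrix)
  affine2d(Mi, as.numeric(-Mi %*% A@translation))
}

#' Resample a 2D image under an affine transform
#'
#' Pull-back resampling with bilinear interpolation: output pixel `p` takes
#' the value of the input at `M (p - c) + c + t`, with `c` the image centre.
#' Coordinates outside the image are clamped to the border (replicate
#' padding).
#'
#' @param img Numeric matrix.
#' @param A An [Affine2D-class].
#' @return Resampled matrix of the same dimensions.
#' @export
applyAffine2D <- function(img, A) {
  nr <- nrow(img); nc <- ncol(img)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  p <- cbind(rep(seq_len(nr), nc) - ctr[1],
             rep(seq_len(nc), each = nr) - ctr[2])
  q <- p %*% t(A@matrix)
  r <- q[, 1] + ctr[1] + A@translation[1]
  cc <- q[, 2] + ctr[2] + A@translation[2]
  matrix(.bilinear(img, r, cc), nr, nc)
}

# internal: vectorised bilinear sampling with border clamping
.bilinear <- function(img, r, cc) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr)
  cc <- pmin(pmax(cc, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(cc), nc - 1L)
  if (nr == 1L) r0 <- rep(1, length(r))
  if (nc == 1L) c0 <- rep(1, length(cc))
  fr <- r - r0; fc <- cc - c0
  i00 <- (c0 - 1) * nr + r0
  v00 <- img[i00]; v10 <- img[i00 + (nr > 1L)]
  i01 <- i00 + (nc > 1L) * nr
  v01 <- img[i01]; v11 <- img[i01 + (nr > 1L)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

#' Registration settings
#'
#' @param pyramidLevels Number of multi-resolution levels (>= 1).
#' @param maxIterations Maximum optimiser iterations per level.
#' @param tolerance Relative convergence tolerance on the objective.
#' @param smoothingSigma Gaussian pre-smoothing (pixels) applied to both
#'   images at every level when evaluating the metric; counters the
#'   half-pixel bias that interpolated noise otherwise induces in an MSE
#'   optimum.
#' @param interpolation Only `"bilinear"` is supported.
#' @return A validated `RegistrationConfig` list.
#' @export
registrationConfig <- function(pyramidLevels = 3, maxIterations = 400,
                               tolerance = 1e-8, smoothingSigma = 1,
                               interpolation = "bilinear") {
  stopifnot(.isCount(pyramidLevels, 1L), .isCount(maxIterations, 1L),
            tolerance > 0, smoothingSigma >= 0, interpolation == "bilinear")
  structure(list(pyramidLevels = as.integer(pyramidLevels),
                 maxIterations = as.integer(maxIterations),
                 tolerance = tolerance,
                 smoothingSigma = smoothingSigma,
                 interpolation = interpolation),
            class = "RegistrationConfig")
}

# internal: separable 2D Gaussian blur with replicate padding; applied to
# both images at every pyramid level before computing the metric, so the
# offset-dependent smoothing of interpolated noise cannot bias the optimum
# toward half-pixel shifts
.blur2 <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  convRows <- function(m) {
    n <- nrow(m)
    idx <- pmin(pmax(seq_len(n + 2 * r) - r, 1L), n)
    pad <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (o in seq_along(k))
      out <- out + k[o] * pad[seq_len(n) + (o - 1L), , drop = FALSE]
    out
  }
  t(convRows(t(convRows(img))))
}

# internal: 2x downsampling by 2x2 block averaging
.downsample2 <- function(img) {
  nr <- 2L * (nrow(img) %/% 2L); nc <- 2L * (ncol(img) %/% 2L)
  x <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  x <- (x[seq(1, nr, 2), , drop = FALSE] + x[seq(2, nr, 2), , drop = FALSE]) / 2
  (x[, seq(1, nc, 2), drop = FALSE] + x[, seq(2, nc, 2), drop = FALSE]) / 2
}

# internal: z-scored mean square difference; both images standardised so the
# metric is insensitive to the global brightness change driven by contrast
# enhancement
.zmse <- function(a, b) {
  za <- (a - mean(a)) / sd(a)
  zb <- (b - mean(b)) / sd(b)
  mean((za - zb)^2)
}

.paramsToAffine <- function(p) {
  affine2d(matrix(c(1 + p[1], p[3], p[2], 1 + p[4]), 2, 2), p[5:6])
}

#' Register one slice by minimising the mean-square intensity difference
#'
#' Coarse-to-fine estimation of the 2D affine transform that minimises the
#' mean square difference between the (z-scored) target and the resampled
#' floating slice. If optimisation does not improve on the identity
#' transform, the identity is returned; a constant target or floating image
#' returns the identity with `attr(., "flat") = TRUE` and a warning.
#'
#' @param target,floating Numeric matrices of equal shape.
#' @param cfg A [registrationConfig()].
#' @return An [Affine2D-class] mapping target pixel coordinates to floating
#'   sampling coordinates, with attributes `mse` (achieved objective) and
#'   `mseIdentity`.
#' @export
registerSlice <- function(target, floating, cfg = registrationConfig()) {
  stopifnot(identical(dim(target), dim(floating)))
  if (sd(target) == 0 || sd(floating) == 0) {
    warning("constant image; returning identity transform")
    out <- affine2d()
    attr(out, "flat") <- TRUE
    return(out)
  }
  pyrT <- list(target); pyrF <- list(floating)
  for (l in seq_len(cfg$pyramidLevels - 1L)) {
    tl <- pyrT[[1]]
    if (min(dim(tl)) < 12L) break
    pyrT <- c(list(.downsample2(tl)), pyrT)
    pyrF <- c(list(.downsample2(pyrF[[1]])), pyrF)
  }
  p <- rep(0, 6)
  for (l in seq_along(pyrT)) {
    if (l > 1L) p[5:6] <- p[5:6] * 2
    tl <- .blur2(pyrT[[l]], cfg$smoothingSigma)
    fl <- .blur2(pyrF[[l]], cfg$smoothingSigma)
    nr <- nrow(tl); nc <- ncol(tl)
    ctr <- c((nr + 1) / 2, (nc + 1) / 2)
    # score only an interior band so border clamping cannot bias the fit
    m <- if (min(nr, nc) >= 16L) 3L else 1L
    rows <- (1L + m):(nr - m); cols <- (1L + m):(nc - m)
    pr <- rep(rows, length(cols)) - ctr[1]
    pc <- rep(cols, each = length(rows)) - ctr[2]
    ti <- as.vector(tl[rows, cols])
    zt <- (ti - mean(ti)) / sd(ti)
    obj <- function(q) {
      r <- (1 + q[1]) * pr + q[2] * pc + ctr[1] + q[5]
      cc <- q[3] * pr + (1 + q[4]) * pc + ctr[2] + q[6]
      v <- .bilinear(fl, r, cc)
      zv <- (v - mean(v)) / sd(v)
      mean((zt - zv)^2)
    }
    opt <- optim(p, obj, method = "Nelder-Mead",
                 control = list(maxit = cfg$maxIterations,
                                reltol = cfg$tolerance))
    if (l == length(pyrT)) {  # restart once: N-M simplices can collapse
      opt <- optim(opt$par, obj, method = "Nelder-Mead",
                   control = list(maxit = cfg$maxIterations,
                                  reltol = cfg$tolerance))
    }
    p <- opt$par
  }
  mseId <- .zmse(target, floating)
  mseOpt <- .zmse(target, applyAffine2D(floating, .paramsToAffine(p)))
  if (mseOpt > mseId) {
    out <- affine2d()
    attr(out, "mse") <- mseId
  } else {
    out <- .paramsToAffine(p)
    attr(out, "mse") <- mseOpt
  }
  attr(out, "mseIdentity") <- mseId
  out
}

#' Slice-wise co-registration of a dynamic series
#'
#' Registers every slice of the four enhanced volumes (T1--T4) to the
#' corresponding slice of the unenhanced volume (T0, the fixed target) and
#' returns the resampled series together with all estimated transforms. The
#' lesion mask is never resampled: it is defined on the registered series.
#'
#' @param series A [DynamicSeries-class].
#' @param cfg A [registrationConfig()].
#' @return List with `series` (registered [DynamicSeries-class]) and
#'   `transforms`, a list indexed `[[time]][[slice]]` of
#'   [Affine2D-class] objects for T1--T4.
#' @export
registerSeries <- function(series, cfg = registrationConfig()) {
  stopifnot(is(series, "DynamicSeries"))
  data <- series@data
  nz <- dim(data)[3]
  transforms <- vector("list", 4L)
  for (ti in 2:5) {
    transforms[[ti - 1L]] <- vector("list", nz)
    for (z in seq_len(nz)) {
      A <- registerSlice(data[, , z, 1L], series@data[, , z, ti], cfg)
      transforms[[ti - 1L]][[z]] <- A
      data[, , z, ti] <- applyAffine2D(series@data[, , z, ti], A)
    }
  }
  list(series = DynamicSeries(data, series@spacing, series@times),
       transforms = transforms)
}

#' Translation-equivalent residual of a recovered transform
#'
#' Composes the recovered registration transform with the true injected
#' motion and reports the displacement this composition leaves at the slice
#' centre, in pixels; 0 means exact recovery.
#'
#' @param recovered,truth [Affine2D-class] objects (both in the pull-back
#'   convention used by [applyAffine2D()]).
#' @return Non-negative residual displacement in pixels.
#' @export
registrationResidual <- function(recovered, truth) {
  comp <- composeAffine2D(truth, recovered)
  sqrt(sum(comp@translation^2))
}
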