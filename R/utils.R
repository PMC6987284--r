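#' Round half away from zero
#'
#' Display rounding used throughout the reporting layer: exact halves round
#' up (e.g. 90.5 -> 91), unlike [base::round()]'s round-half-even. Only
#' display values are rounded; all statistics are carried at full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a stage-specific RNG seed from a global seed
#'
#' Hashes a stage name together with the global seed into a 31-bit integer,
#' so each pipeline stage draws from its own reproducible stream and adding
#' a stage never perturbs the randomness of earlier ones. The hash is plain
#' integer arithmetic on the UTF-8 code points (exact in doubles), hence
#' platform-stable.
#'
#' @param seed Integer global seed.
#' @param stage Character scalar naming the stage (or case).
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  mod <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% mod
  as.integer((h * 48271 + abs(seed)) %% mod)
}

# internal: positive scalar check
.isCount <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == as.integer(x)
}

# internal: gaussian-smoothed white noise field, separable convolution with
# replicate padding; used for parenchyma background and lesion texture
.smoothField <- function(dims, sigma) {
  x <- array(stats::rnorm(prod(dims)), dim = dims)
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  convAxis <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    m <- aperm(a, perm)
    dm <- dim(m)
    m <- matrix(m, nrow = dm[1])
    idx <- pmin(pmax(seq_len(dm[1] + 2 * r) - r, 1L), dm[1])
    padded <- m[idx, , drop = FALSE]
    out <- matrix(0, nrow = dm[1], ncol = ncol(m))
    for (o in seq_along(k)) {
      out <- out + k[o] * padded[seq_len(dm[1]) + (o - 1L), , drop = FALSE]
    }
    dim(out) <- dm
    aperm(out, order(perm))
  }
  for (axis in 1:3) x <- convAxis(x, axis)
  # renormalise to unit marginal variance so `sigma` controls correlation
  # length, not amplitude
  s <- stats::sd(x)
  if (s > 0) x <- x / s
  x
}
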