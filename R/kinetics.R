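#' Contrast-enhancement kinetic parameters
#'
#' Parameters of a three-parameter enhancement model distinguishing the two
#' kinetic archetypes seen in small enhancing foci: slow persistent
#' enhancement (benign-type; `washOutRate = 0`) and fast wash-in followed by
#' wash-out (malignant-type).
#'
#' @param baselineIntensity Pre-contrast signal level (arbitrary units, > 0).
#' @param washInAmplitude Peak relative enhancement as a fraction of
#'   baseline (>= 0).
#' @param washInRate Uptake rate in 1/min (>= 0).
#' @param washOutRate Decay rate in 1/min (>= 0; 0 gives a persistent curve).
#' @param timePoints Acquisition times in minutes; length 5, strictly
#'   increasing, first element 0. Default `0:4` (60 s temporal resolution).
#' @return A validated `KineticParams` list.
#' @examples
#' p <- kineticParams(100, washInAmplitude = 1.2, washInRate = 3,
#'                    washOutRate = 0.4)
#' kineticCurve(p)
#' @export
kineticParams <- function(baselineIntensity, washInAmplitude, washInRate,
                          washOutRate = 0, timePoints = 0:4) {
  if (!is.numeric(baselineIntensity) || baselineIntensity <= 0)
    stop("baselineIntensity must be positive")
  if (washInAmplitude < 0 || washInRate < 0 || washOutRate < 0)
    stop("amplitude and rates must be non-negative")
  if (length(timePoints) != 5L || timePoints[1] != 0 ||
      any(diff(timePoints) <= 0))
    stop("timePoints must be 5 strictly increasing values starting at 0")
  structure(list(baselineIntensity = baselineIntensity,
                 washInAmplitude = washInAmplitude,
                 washInRate = washInRate,
                 washOutRate = washOutRate,
                 timePoints = as.numeric(timePoints)),
            class = "KineticParams")
}

#' Relative enhancement curve
#'
#' Evaluates `e(t) = A (1 - exp(-r_in t)) exp(-r_out t)` at the five
#' acquisition times. `e(0) = 0` always; with `washOutRate = 0` the curve is
#' monotonically non-decreasing (persistent enhancement), otherwise it peaks
#' and washes out.
#'
#' @param p A [kineticParams()] object.
#' @return Numeric vector of 5 relative enhancements.
#' @export
kineticCurve <- function(p) {
  if (!inherits(p, "KineticParams")) stop("p must be a KineticParams object")
  t <- p$timePoints
  p$washInAmplitude * (1 - exp(-p$washInRate * t)) * exp(-p$washOutRate * t)
}
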