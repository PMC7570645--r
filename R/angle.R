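#' Back angle from an acceleration vector
#'
#' The back angle is the angle between the measured acceleration vector and
#' the gravitational acceleration reference vector,
#' `alpha = arccos(a . g / (|a| |g|))`, in degrees. With the device worn on
#' the thoracic spine and the gravity reference pointing down, an upright
#' straight back reads close to 180 degrees and bending forward lowers the
#' angle; 160 degrees is the conventional crooked-posture cutoff. The result
#' is invariant to positive rescaling of either vector and the normalized dot
#' product is clamped to \[-1, 1\] before `acos`, so valid input never yields
#' `NaN`.
#'
#' @param a 3-vector measured acceleration (or n x 3 matrix).
#' @param g 3-vector gravity reference; default `c(0, 0, -9.81)` m/s^2
#'   (z axis up).
#' @return angle(s) in degrees in \[0, 180\].
#' @examples
#' back_angle(c(0, 0, 9.81))       # upright: 180
#' back_angle(c(0, 9.81, 0))       # horizontal: 90
#' @export
back_angle <- function(a, g = c(0, 0, -9.81)) {
  a <- as_samples(a, "acceleration")
  g <- as.numeric(g)
  if (length(g) != 3L || !all(is.finite(g))) {
    pw_error("pw_invalid_data", "gravity reference must be a finite 3-vector")
  }
  na <- sqrt(rowSums(a^2))
  ng <- vec_norm(g)
  if (ng == 0 || any(na == 0)) {
    pw_error("pw_invalid_data", "zero-norm vector has no direction")
  }
  cosang <- pmin(1, pmax(-1, as.numeric(a %*% g) / (na * ng)))
  acos(cosang) * 180 / pi
}

#' Back-angle trace from an accelerometer trace
#'
#' @param acc_trace data frame with columns `t`, `x`, `y`, `z`.
#' @param g gravity reference vector, see [back_angle()].
#' @return data frame with columns `t` and `angle` (degrees).
#' @export
angle_trace <- function(acc_trace, g = c(0, 0, -9.81)) {
  if (is.null(acc_trace) || nrow(acc_trace) == 0L) {
    pw_error("pw_invalid_data", "accelerometer trace is empty")
  }
  ang <- back_angle(as.matrix(acc_trace[, c("x", "y", "z")]), g)
  data.frame(t = acc_trace$t, angle = ang)
}

#' RMS difference between two angle traces
#'
#' Pairs the two traces by nearest timestamp (tolerance defaulting to half
#' the median sampling period of the first trace, as in [classify_stream()])
#' and returns the root-mean-square of the paired angle differences. This is
#' the statistic used to validate sensor-derived back angles against an
#' independent reference angle trace.
#'
#' @param trace_a,trace_b data frames with columns `t` and `angle` (degrees).
#' @param pairing_tol maximum timestamp mismatch (seconds) for a pair.
#' @return RMS difference in degrees (>= 0).
#' @export
rms_difference <- function(trace_a, trace_b, pairing_tol = NULL) {
  if (is.null(trace_a) || is.null(trace_b) || nrow(trace_a) == 0L || nrow(trace_b) == 0L) {
    pw_error("pw_invalid_data", "both angle traces must be non-empty")
  }
  trace_a <- trace_a[order(trace_a$t), , drop = FALSE]
  trace_b <- trace_b[order(trace_b$t), , drop = FALSE]
  if (is.null(pairing_tol)) pairing_tol <- default_pairing_tol(trace_a$t)
  idx <- nearest_index(trace_a$t, trace_b$t)
  ok <- abs(trace_b$t[idx] - trace_a$t) <= pairing_tol
  if (!any(ok)) {
    pw_error("pw_invalid_data", "angle traces share no timestamps within the pairing tolerance")
  }
  d <- trace_a$angle[ok] - trace_b$angle[idx][ok]
  sqrt(mean(d^2))
}

#' Angle-based ground-truth posture label
#'
#' Labels a back angle `"incorrect"` when it falls strictly below the
#' threshold (default 160 degrees) and `"correct"` otherwise; the threshold
#' itself counts as correct. Used to derive validation labels from a
#' reference angle trace.
#'
#' @param angle numeric angle(s) in degrees in \[0, 180\].
#' @param threshold crooked-posture cutoff in degrees, in (0, 180\].
#' @return character vector of `"correct"`/`"incorrect"`.
#' @export
label_by_angle <- function(angle, threshold = 160) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0 || threshold > 180) {
    pw_error("pw_invalid_parameter", "threshold must be a single angle in (0, 180]")
  }
  if (any(!is.finite(angle)) || any(angle < 0 | angle > 180)) {
    pw_error("pw_invalid_data", "angles must be finite and within [0, 180] degrees")
  }
  ifelse(angle < threshold, "incorrect", "correct")
}
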