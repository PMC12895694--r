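# Circular label arithmetic for orientation decoding. Orientations live in a
# 180-degree space; decoding maps them onto the full circle (radians in
# [-pi, pi)) so that sine/cosine projections provide linear regression targets.

#' Map orientation degrees to the decoding angle in radians
#'
#' Orientations in the 0-180 degree space are wrapped and mapped linearly onto
#' `[-pi, pi)`: `theta = deg * (2 * pi / 180) - pi`. This doubling makes the
#' 180-degree-periodic orientation space fully circular, so 0 deg and 180 deg
#' coincide.
#'
#' @param deg Numeric vector of orientations in degrees (any finite value;
#'   wrapped into `[0, 180)`).
#' @return Angles in radians in `[-pi, pi)`.
#' @export
#' @examples
#' degrees_to_theta(c(0, 45, 90))   # -pi, -pi/2, 0
degrees_to_theta <- function(deg) {
  stopifnot(is.numeric(deg), all(is.finite(deg)))
  (deg %% 180) * (2 * pi / 180) - pi
}

#' Inverse of [degrees_to_theta()]
#'
#' @param theta Angles in radians.
#' @return Orientations in degrees in `[0, 180)`.
#' @export
theta_to_degrees <- function(theta) {
  stopifnot(is.numeric(theta), all(is.finite(theta)))
  (((theta + pi) * (180 / (2 * pi))) %% 180)
}

#' Project decoding angles onto sine and cosine regression targets
#'
#' @param theta Angles in radians.
#' @return A data.frame with columns `theta`, `x` (cosine) and `y` (sine);
#'   training labels lie on the unit circle.
#' @export
theta_to_sincos <- function(theta) {
  stopifnot(is.numeric(theta), all(is.finite(theta)))
  data.frame(theta = theta, x = cos(theta), y = sin(theta))
}

#' Reconstruct an angle from predicted sine/cosine components
#'
#' Four-quadrant inverse tangent `atan2(yhat, xhat)`. The predicted components
#' are unconstrained, so they need not lie on the unit circle. The degenerate
#' input (0, 0) has no defined angle; it is mapped to 0 with a warning so that
#' trial counts stay balanced downstream.
#'
#' @param xhat Predicted cosine component(s).
#' @param yhat Predicted sine component(s).
#' @return Angles in radians in `(-pi, pi]`.
#' @export
reconstruct_angle <- function(xhat, yhat) {
  stopifnot(length(xhat) == length(yhat))
  zero <- xhat == 0 & yhat == 0
  if (any(zero)) {
    warning(sum(zero), " degenerate (0, 0) prediction(s) mapped to angle 0")
  }
  out <- atan2(yhat, xhat)
  out[zero] <- 0
  out
}

#' Circular absolute angular error
#'
#' @param theta True angle(s), radians.
#' @param theta_hat Predicted angle(s), radians.
#' @return Absolute circular differences in `[0, pi]`.
#' @export
#' @examples
#' angular_error(pi - 0.1, -pi + 0.1)  # 0.2, across the wrap
angular_error <- function(theta, theta_hat) {
  stopifnot(all(is.finite(theta)), all(is.finite(theta_hat)))
  abs(atan2(sin(theta - theta_hat), cos(theta - theta_hat)))
}

#' Feature-continuous accuracy above chance
#'
#' Converts circular angular errors into an accuracy percentage,
#' `mean(100 - error / pi * 100) - 50`, so that +50 marks perfect
#' reconstruction, 0 marks chance (a 45-degree orientation error), and -50 the
#' maximal error.
#'
#' @param errors Angular errors in radians, each in `[0, pi]`.
#' @return Scalar FCA above chance, in percent, in `[-50, 50]`.
#' @export
#' @examples
#' fca_above_chance(rep(0, 10))      # +50
#' fca_above_chance(rep(pi / 2, 10)) # 0
fca_above_chance <- function(errors) {
  if (!length(errors)) stop("fca_above_chance() needs at least one error value")
  stopifnot(is.numeric(errors), all(is.finite(errors)))
  if (any(errors < -1e-12 | errors > pi + 1e-12)) {
    stop("angular errors must lie in [0, pi]")
  }
  mean(100 - errors / pi * 100) - 50
}
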