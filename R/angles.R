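#' Axial-angle utilities
#'
#' Phosphene orientations and fiber tangents are axial quantities: an angle
#' theta and theta + 180 describe the same undirected axis. All orientation
#' arithmetic in the package therefore wraps to the half-circle
#' \eqn{[-90, 90)} degrees.
#'
#' @param theta Numeric vector of angles in degrees.
#' @return `wrap_axial()` returns angles wrapped to \eqn{[-90, 90)};
#'   `axial_mean()` returns the doubled-angle circular mean, a single angle in
#'   \eqn{[-90, 90)} (NA if all inputs are NA).
#' @examples
#' wrap_axial(c(95, -95, 180))
#' axial_mean(c(80, -80))   # mean axis is vertical, not 0
#' @export
wrap_axial <- function(theta) {
  ((theta + 90) %% 180) - 90
}

#' @rdname wrap_axial
#' @export
axial_mean <- function(theta) {
  theta <- theta[!is.na(theta)]
  if (length(theta) == 0L) return(NA_real_)
  s <- mean(sinpi(theta / 90))  # sin(2 theta), theta in deg
  c <- mean(cospi(theta / 90))
  wrap_axial(atan2(s, c) * 90 / pi)
}

#' Absolute angular error between two axial angles
#'
#' The smallest absolute difference between two undirected axes, i.e. the
#' minimum over 180-degree wraps of `|theta1 - theta2|`. Used to compare drawn
#' phosphene orientations with nerve-fiber-bundle tangents.
#'
#' @param theta1,theta2 Angles in degrees (recycled to a common length).
#' @return Numeric vector of errors in degrees, in \eqn{[0, 90]}. NA inputs
#'   propagate.
#' @examples
#' angular_error(85, -85)  # 10, via the 180-degree wrap
#' @export
angular_error <- function(theta1, theta2) {
  abs(wrap_axial(theta1 - theta2))
}

# standard error of the mean of axial angles, about their circular mean
axial_sem <- function(theta) {
  theta <- theta[!is.na(theta)]
  n <- length(theta)
  if (n < 2L) return(NA_real_)
  res <- wrap_axial(theta - axial_mean(theta))
  sd(res) / sqrt(n)
}
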