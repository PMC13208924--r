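# Skew-normal sampling parameterized by (mean, sd, skewness).
#
# The location-scale-shape family SN(xi, omega, alpha) has population moments
#   mean = xi + omega * mu_z,   var = omega^2 * (1 - mu_z^2),
#   skewness g = (4 - pi)/2 * mu_z^3 / (1 - mu_z^2)^(3/2),
# with mu_z = sqrt(2/pi) * delta and delta = alpha / sqrt(1 + alpha^2).
# Attainable skewness is bounded by |g| < 0.99527.

#' Maximum attainable skewness of the skew-normal family
#' @return A positive scalar, about 0.99527.
#' @keywords internal
sn_max_skewness <- function() {
  b <- sqrt(2 / pi)
  0.5 * (4 - pi) * b^3 / (1 - b^2)^1.5
}

#' Solve the skew-normal delta parameter from a target population skewness
#'
#' Inverts the skew-normal skewness formula in closed form: with
#' `k = (2|g| / (4 - pi))^(1/3)`, `mu_z^2 = k^2 / (1 + k^2)` and
#' `delta = sign(g) * mu_z / sqrt(2/pi)`.
#'
#' @param gamma Target population skewness; must satisfy
#'   `abs(gamma) < sn_max_skewness()`.
#' @return `delta` in (-1, 1); the shape is `alpha = delta / sqrt(1 - delta^2)`.
#' @export
sn_delta_from_skewness <- function(gamma) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (abs(gamma) >= sn_max_skewness()) {
    stop("target skewness ", gamma, " is outside the attainable skew-normal ",
         "range (|skewness| < ", format(sn_max_skewness(), digits = 6), ")")
  }
  if (gamma == 0) return(0)
  k <- (2 * abs(gamma) / (4 - pi))^(1 / 3)
  mu_z <- k / sqrt(1 + k^2)
  sign(gamma) * mu_z / sqrt(2 / pi)
}

#' Skew-normal parameters (xi, omega, alpha) for given mean, sd and skewness
#' @param mean,sd,gamma Target population mean, standard deviation (> 0) and
#'   skewness.
#' @return A list with elements `xi`, `omega`, `alpha`, `delta`.
#' @export
sn_params_from_moments <- function(mean, sd, gamma) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0)
  delta <- sn_delta_from_skewness(gamma)
  mu_z <- sqrt(2 / pi) * delta
  omega <- sd / sqrt(1 - mu_z^2)
  list(xi = mean - omega * mu_z,
       omega = omega,
       alpha = delta / sqrt(1 - delta^2),
       delta = delta)
}

#' Draw skew-normal variates with prescribed mean, sd and skewness
#'
#' Uses the convolution representation
#' `Z = delta * |U0| + sqrt(1 - delta^2) * U1` with independent standard
#' normals, then applies the location-scale map so the population mean, SD
#' and skewness equal the requested values.
#'
#' @param n Number of draws.
#' @inheritParams sn_params_from_moments
#' @return Numeric vector of length `n`; uses the current R RNG stream.
#' @examples
#' set.seed(1)
#' x <- rskewnorm(1e4, mean = 500, sd = 48, gamma = -0.11)
#' c(mean(x), sd(x))
#' @export
rskewnorm <- function(n, mean = 0, sd = 1, gamma = 0) {
  p <- sn_params_from_moments(mean, sd, gamma)
  u0 <- stats::rnorm(n)
  u1 <- stats::rnorm(n)
  z <- p$delta * abs(u0) + sqrt(1 - p$delta^2) * u1
  p$xi + p$omega * z
}

#' Population skewness implied by a skew-normal delta
#' @param delta Skew-normal delta in (-1, 1).
#' @return Population skewness.
#' @keywords internal
sn_skewness_from_delta <- function(delta) {
  mu_z <- sqrt(2 / pi) * delta
  0.5 * (4 - pi) * mu_z^3 / (1 - mu_z^2)^1.5
}
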