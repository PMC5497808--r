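#' Scaled frequency profile U
#'
#' Evaluates the dimensionless frequency profile
#' \deqn{U(\xi) = \sigma + (1-\sigma)\frac{1-e^{k(\xi-1)}}{1-e^{-k}}, \quad \xi \le 1,}
#' and \eqn{U(\xi) = 0} for \eqn{\xi > 1}. The profile is continuous and
#' strictly decreasing on \eqn{[0, 1]} with \eqn{U(0) = 1} and
#' \eqn{U(1) = \sigma}, and jumps from \eqn{\sigma} to zero across the
#' anterior end: oscillations arrest abruptly in formed segments. Positions
#' exactly at \eqn{\xi = 1} count as inside the PSM.
#'
#' @param xi dimensionless position \eqn{x/\bar{x}}, may be a vector.
#' @param p a [frequency_profile()].
#' @return Dimensionless frequency fraction, same length as `xi`.
#' @export
eval_U <- function(xi, p) {
  stopifnot(inherits(p, "frequency_profile"))
  if (!is.numeric(xi) || any(!is.finite(xi))) {
    stop("'xi' must be finite numeric", call. = FALSE)
  }
  u <- p$sigma + (1 - p$sigma) * (1 - exp(p$k * (xi - 1))) / (1 - exp(-p$k))
  u[xi > 1] <- 0
  u
}

#' Scaled velocity profile V
#'
#' Evaluates \eqn{V(\xi) = 1 - e^{-q\xi}}: zero at the posterior tip,
#' strictly increasing, saturating at 1 far anteriorly.
#'
#' @param xi dimensionless position \eqn{x/\bar{x}} (>= 0), may be a vector.
#' @param p a [velocity_profile()].
#' @return Dimensionless velocity fraction in `[0, 1)`.
#' @export
eval_V <- function(xi, p) {
  stopifnot(inherits(p, "velocity_profile"))
  if (!is.numeric(xi) || any(!is.finite(xi)) || any(xi < 0)) {
    stop("'xi' must be finite and >= 0", call. = FALSE)
  }
  1 - exp(-p$q * xi)
}

#' PSM length over time
#'
#' \eqn{\bar{x}(t) = x_0 + x_1 \tanh(\eta (t - \bar{t}))}: a smooth, monotone
#' (decreasing for \eqn{\eta < 0}) length trajectory bounded between
#' \eqn{x_0 - x_1} and \eqn{x_0 + x_1}.
#'
#' @param t time, min (vectorised).
#' @param p a [length_dynamics()].
#' @return PSM length, um.
#' @export
psm_length <- function(t, p) {
  stopifnot(inherits(p, "length_dynamics"))
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("'t' must be finite numeric", call. = FALSE)
  }
  p$x0 + p$x1 * tanh(p$eta * (t - p$tbar))
}

#' Rate of PSM length change
#'
#' Analytic derivative of [psm_length()]:
#' \eqn{d\bar{x}/dt = x_1 \eta \, \mathrm{sech}^2(\eta(t - \bar{t}))}, with
#' extremal magnitude \eqn{|x_1 \eta|} at \eqn{t = \bar{t}}. For the zebrafish
#' parameters this peak shortening rate is 1.03 um/min.
#'
#' @inheritParams psm_length
#' @return Signed rate, um/min (negative while shortening).
#' @export
psm_length_rate <- function(t, p) {
  stopifnot(inherits(p, "length_dynamics"))
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("'t' must be finite numeric", call. = FALSE)
  }
  p$x1 * p$eta / cosh(p$eta * (t - p$tbar))^2
}

#' Intrinsic frequency field
#'
#' The position- and time-dependent intrinsic angular frequency
#' \eqn{\omega(x, t) = \omega_0 U(x/\bar{x}(t))}: maximal \eqn{\omega_0} at
#' the posterior tip, \eqn{\sigma \omega_0} at the anterior end, zero beyond.
#' Invariant under joint rescaling of `x` and the PSM length.
#'
#' @param x position along the body axis, um (>= 0; vectorised).
#' @param t time, min (scalar or same length as `x`).
#' @param fp a [frequency_profile()].
#' @param lp a [length_dynamics()].
#' @return Angular frequency, rad/min.
#' @export
frequency_field <- function(x, t, fp, lp) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("'x' must be finite and >= 0", call. = FALSE)
  }
  fp$omega0 * eval_U(x / psm_length(t, lp), fp)
}

#' Cell velocity field
#'
#' \eqn{v(x, t) = v_0 V(x/\bar{x}(t))}; the boundary condition
#' \eqn{v(0) = 0} holds exactly (the posterior tip is the reference frame).
#'
#' @inheritParams frequency_field
#' @param vp a [velocity_profile()].
#' @return Speed, um/min.
#' @export
velocity_field <- function(x, t, vp, lp) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("'x' must be finite and >= 0", call. = FALSE)
  }
  vp$v0 * eval_V(x / psm_length(t, lp), vp)
}

#' Local growth-rate profile
#'
#' The velocity gradient \eqn{\partial v/\partial x =
#' (q v_0/\bar{x}) e^{-q x/\bar{x}}}, interpreted as the local tissue growth
#' rate: maximal at the posterior tip and decaying over the length scale
#' \eqn{\bar{x}/q}.
#'
#' @inheritParams velocity_field
#' @return Rate, 1/min.
#' @export
growth_rate_profile <- function(x, t, vp, lp) {
  xb <- psm_length(t, lp)
  (vp$q * vp$v0 / xb) * exp(-vp$q * x / xb)
}
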