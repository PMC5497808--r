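#' Frequency-profile parameters
#'
#' Parameters of the scaled intrinsic-frequency profile of the segmentation
#' clock, \eqn{\omega(x, t) = \omega_0 U(x/\bar{x}(t))}. The shape function
#' \eqn{U} equals 1 at the posterior tip (\eqn{\xi = 0}), decays to the
#' anterior fraction \eqn{\sigma} at the anterior end (\eqn{\xi = 1}) and is
#' zero beyond it (oscillations are arrested in formed segments).
#'
#' @param omega0 maximum angular frequency at the posterior tip, rad/min.
#' @param k dimensionless shape parameter; `1/k` is the characteristic decay
#'   scale of the profile in units of PSM length.
#' @param sigma anterior frequency fraction, \eqn{0 < \sigma \le 1};
#'   \eqn{U(1) = \sigma}.
#' @return An object of class `"frequency_profile"`.
#' @seealso [eval_U()], [frequency_field()], [zebrafish_parameters()]
#' @export
frequency_profile <- function(omega0 = 0.15, k = 2.07, sigma = 0.34) {
  check_scalar(omega0, "omega0", positive = TRUE)
  check_scalar(k, "k", positive = TRUE)
  check_scalar(sigma, "sigma")
  if (sigma <= 0 || sigma > 1) {
    stop("'sigma' must lie in (0, 1]", call. = FALSE)
  }
  structure(list(omega0 = omega0, k = k, sigma = sigma),
            class = "frequency_profile")
}

#' Velocity-profile parameters
#'
#' Parameters of the scaled cell-velocity profile
#' \eqn{v(x, t) = v_0 V(x/\bar{x}(t))} with \eqn{V(\xi) = 1 - e^{-q\xi}}.
#' The velocity vanishes at the posterior tip (the reference frame) and
#' saturates at \eqn{v_0} far anteriorly; its gradient is the local growth
#' rate, maximal at the tip.
#'
#' @param v0 saturation speed, um/min.
#' @param q dimensionless shape parameter; the growth-rate profile decays over
#'   \eqn{\bar{x}/q}.
#' @return An object of class `"velocity_profile"`.
#' @seealso [eval_V()], [velocity_field()], [growth_rate_profile()]
#' @export
velocity_profile <- function(v0 = 0.87, q = 1.80) {
  check_scalar(v0, "v0")
  if (v0 < 0) stop("'v0' must be >= 0", call. = FALSE)
  check_scalar(q, "q", positive = TRUE)
  structure(list(v0 = v0, q = q), class = "velocity_profile")
}

#' PSM length-dynamics parameters
#'
#' Parameters of the sigmoidal time course of the PSM length,
#' \eqn{\bar{x}(t) = x_0 + x_1 \tanh(\eta (t - \bar{t}))}. With \eqn{\eta < 0}
#' (the zebrafish case) the tissue shortens monotonically from
#' \eqn{x_0 + x_1} to \eqn{x_0 - x_1}.
#'
#' @param x0 midpoint length, um.
#' @param x1 half-amplitude of the length change, um; requires
#'   \eqn{x_0 > x_1 \ge 0} so the length stays positive.
#' @param eta rate constant, 1/min, stored signed (negative for shortening).
#' @param tbar midpoint time, min.
#' @return An object of class `"length_dynamics"`.
#' @seealso [psm_length()], [psm_length_rate()]
#' @export
length_dynamics <- function(x0 = 417, x1 = 202, eta = -5.09e-3, tbar = 192) {
  check_scalar(x0, "x0", positive = TRUE)
  check_scalar(x1, "x1")
  check_scalar(eta, "eta")
  check_scalar(tbar, "tbar")
  if (x1 < 0 || x1 >= x0) {
    stop("need x0 > x1 >= 0 so the PSM length stays positive", call. = FALSE)
  }
  structure(list(x0 = x0, x1 = x1, eta = eta, tbar = tbar),
            class = "length_dynamics")
}

#' Bundle of model parameters
#'
#' Collects the frequency profile, velocity profile, PSM length dynamics,
#' phase-coupling strength and initial time into a single parameter set for
#' the phase-field model. [zebrafish_parameters()] returns the published
#' zebrafish calibration.
#'
#' @param freq a [frequency_profile()].
#' @param vel a [velocity_profile()].
#' @param len a [length_dynamics()].
#' @param epsilon phase-coupling strength, um^2/min (diffusion-like; >= 0).
#' @param t0 initial time, min: the simulation starts from a spatially uniform
#'   phase at `t0`, so the transient is part of the model and `t0` anchors the
#'   staging of segment formation.
#' @return An object of class `"model_parameters"`.
#' @export
model_parameters <- function(freq = frequency_profile(),
                             vel = velocity_profile(),
                             len = length_dynamics(),
                             epsilon = 7,
                             t0 = -256) {
  stopifnot(inherits(freq, "frequency_profile"),
            inherits(vel, "velocity_profile"),
            inherits(len, "length_dynamics"))
  check_scalar(epsilon, "epsilon")
  if (epsilon < 0) stop("'epsilon' must be >= 0", call. = FALSE)
  check_scalar(t0, "t0")
  structure(list(freq = freq, vel = vel, len = len,
                 epsilon = epsilon, t0 = t0),
            class = "model_parameters")
}

#' Zebrafish parameter set
#'
#' The calibrated zebrafish parameter set (transgenic reporter line at
#' 23.5 degrees C): `omega0 = 0.15` rad/min, `v0 = 0.87` um/min,
#' `epsilon = 7` um^2/min, `k = 2.07`, `sigma = 0.34`, `q = 1.80`,
#' `t0 = -256` min, and PSM length dynamics `x0 = 417` um, `x1 = 202` um,
#' `eta = -5.09e-3` 1/min, `tbar = 192` min. With this set, `t = 0`
#' corresponds to the formation of the 7th segment.
#'
#' @return A [model_parameters()] object.
#' @export
zebrafish_parameters <- function() model_parameters()

#' @export
print.model_parameters <- function(x, ...) {
  cat("Phase-field model parameters\n")
  cat(sprintf("  frequency : omega0 = %g rad/min, k = %g, sigma = %g\n",
              x$freq$omega0, x$freq$k, x$freq$sigma))
  cat(sprintf("  velocity  : v0 = %g um/min, q = %g\n", x$vel$v0, x$vel$q))
  cat(sprintf("  length    : x0 = %g um, x1 = %g um, eta = %g 1/min, tbar = %g min\n",
              x$len$x0, x$len$x1, x$len$eta, x$len$tbar))
  cat(sprintf("  coupling  : epsilon = %g um^2/min\n", x$epsilon))
  cat(sprintf("  start     : t0 = %g min\n", x$t0))
  invisible(x)
}

# flat named-list view used by the YAML config reader/writer
params_to_list <- function(mp) {
  list(omega0 = mp$freq$omega0, k = mp$freq$k, sigma = mp$freq$sigma,
       v0 = mp$vel$v0, q = mp$vel$q,
       x0 = mp$len$x0, x1 = mp$len$x1, eta = mp$len$eta, tbar = mp$len$tbar,
       epsilon = mp$epsilon, t0 = mp$t0)
}

params_from_list <- function(x) {
  need <- c("omega0", "k", "sigma", "v0", "q", "x0", "x1", "eta", "tbar",
            "epsilon", "t0")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("parameter config is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  model_parameters(
    freq = frequency_profile(x$omega0, x$k, x$sigma),
    vel = velocity_profile(x$v0, x$q),
    len = length_dynamics(x$x0, x$x1, x$eta, x$tbar),
    epsilon = x$epsilon, t0 = x$t0
  )
}

check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
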