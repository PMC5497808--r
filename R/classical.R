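#' Classical-wave parameters
#'
#' Parameters for the closed-form classical-wave solutions that mirror the
#' Doppler and dynamic-wavelength effects of the segmentation clock: a
#' source at `x = 0` emitting `u0 sin(omega t)` into a medium with
#' propagation speed `c`, observed either by a moving observer (speed
#' `vbar`, Doppler case) or at rest in a medium whose refractive index grows
#' as \eqn{n(t) = r t^2} (dynamic-wavelength case). These solutions serve as
#' exact oracles for the frequency-decomposition operators.
#'
#' @param omega source angular frequency, rad per unit time (> 0).
#' @param c propagation speed, length per unit time (> 0).
#' @param u0 wave amplitude (arbitrary units).
#' @param vbar observer speed towards the source (>= 0).
#' @param r refractive-index rate, 1/time^2 (>= 0).
#' @return An object of class `"classical_wave_params"`.
#' @export
classical_wave_params <- function(omega = 1, c = 1, u0 = 1, vbar = 0, r = 0) {
  check_scalar(omega, "omega", positive = TRUE)
  check_scalar(c, "c", positive = TRUE)
  check_scalar(u0, "u0")
  check_scalar(vbar, "vbar")
  check_scalar(r, "r")
  if (vbar < 0 || r < 0) stop("'vbar' and 'r' must be >= 0", call. = FALSE)
  structure(list(omega = omega, c = c, u0 = u0, vbar = vbar, r = r),
            class = "classical_wave_params")
}

#' Plane wave from a harmonic source
#'
#' \eqn{u(x,t) = u_0 \sin(\omega t - 2\pi x/\lambda)} with
#' \eqn{\lambda = 2\pi c/\omega}: the solution of the one-dimensional wave
#' equation with boundary condition \eqn{u(0,t) = u_0 \sin\omega t} and zero
#' initial condition. [plane_wave_phase()] returns the phase
#' \eqn{\omega t - (\omega/c) x}.
#'
#' @param x position (vectorised).
#' @param t time (>= 0, vectorised).
#' @param p a [classical_wave_params()].
#' @return Wave amplitude (or phase, in rad).
#' @export
plane_wave <- function(x, t, p) {
  p$u0 * sin(plane_wave_phase(x, t, p))
}

#' @rdname plane_wave
#' @export
plane_wave_phase <- function(x, t, p) {
  p$omega * t - (p$omega / p$c) * x
}

#' Doppler-shifted frequency of a moving observer
#'
#' An observer moving towards the source at speed `vbar` through the plane
#' wave sees the frequency \eqn{\Omega = (1 + \bar{v}/c)\,\omega}, the
#' textbook moving-observer Doppler shift. The returned list also exposes
#' the decomposition \eqn{\Omega = \omega + \Omega_D} with
#' \eqn{\Omega_D = (d\bar{x}/dt)\,\partial_x\phi = \bar{v}\omega/c}, the
#' same Doppler operator used for the segmentation clock.
#'
#' @param p a [classical_wave_params()].
#' @return A list with `Omega`, `omega`, `Omega_D`.
#' @export
doppler_observed_frequency <- function(p) {
  stopifnot(inherits(p, "classical_wave_params"))
  list(Omega = (1 + p$vbar / p$c) * p$omega,
       omega = p$omega,
       Omega_D = p$vbar * p$omega / p$c)
}

#' Wave in a medium with time-dependent refractive index
#'
#' For \eqn{n(t) = r t^2} the wave equation
#' \eqn{\partial_t^2 u = (c/n(t))^2 \partial_x^2 u} with the harmonic source
#' at `x = 0` and zero initial condition admits the closed-form solution
#' \deqn{u(x,t) = u_0\left(1 + \frac{r}{c}xt\right)
#'   \sin\!\left(\frac{\omega t}{1 + \frac{r}{c}xt}\right),}
#' i.e. phase \eqn{\phi(x,t) = \omega t/(1 + rxt/c)} with a position- and
#' time-dependent amplitude prefactor. The phase fronts propagate at
#' \eqn{c/n(t)}.
#'
#' @param x position (>= 0, vectorised).
#' @param t time (>= 0, vectorised).
#' @param p a [classical_wave_params()] with `r > 0`.
#' @return Wave amplitude (or phase, in rad, for [refractive_phase()]).
#' @export
refractive_wave <- function(x, t, p) {
  p$u0 * (1 + (p$r / p$c) * x * t) * sin(refractive_phase(x, t, p))
}

#' @rdname refractive_wave
#' @export
refractive_phase <- function(x, t, p) {
  p$omega * t / (1 + (p$r / p$c) * x * t)
}

#' Local wavelength in the dynamic-index medium
#'
#' \eqn{\lambda(x,t) = \frac{2\pi}{r c \omega}(r x + c/t)^2}, equal to
#' \eqn{2\pi/|\partial_x \phi|} of the closed-form phase. At fixed position
#' the wavelength decreases over time although the source frequency is
#' constant, and approaches the time-independent limit
#' \eqn{2\pi r x^2/(c\omega)}. `t = 0` returns `Inf` (the pattern has not
#' yet reached any interior point).
#'
#' @inheritParams refractive_wave
#' @return Local wavelength (`Inf` at `t = 0`).
#' @export
refractive_local_wavelength <- function(x, t, p) {
  out <- (2 * pi / (p$r * p$c * p$omega)) * (p$r * x + p$c / t)^2
  out[t == 0] <- Inf
  out
}

#' Local frequency in the dynamic-index medium
#'
#' \eqn{\Omega(x,t) = \omega/(1 + rxt/c)^2 = \partial_t \phi}: an observer
#' at rest at `x > 0` sees a frequency below the source frequency
#' (\eqn{\Omega = \omega + \Omega_W} with \eqn{\Omega_W < 0}), the pure
#' dynamic-wavelength effect.
#'
#' @inheritParams refractive_wave
#' @return Local angular frequency.
#' @export
refractive_local_frequency <- function(x, t, p) {
  p$omega / (1 + (p$r / p$c) * x * t)^2
}
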