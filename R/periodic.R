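#' Find the time-periodic state at constant PSM length
#'
#' At frozen PSM length the phase dynamics relax to a time-periodic state
#' \eqn{\phi(x,t) = \Omega t + \psi(x)} with collective frequency
#' \eqn{\Omega} and a stationary profile \eqn{\psi} obeying
#' \eqn{\Omega + v \psi' = \omega + (\varepsilon/2)\psi''} with
#' \eqn{\psi'(0) = 0}. The state is obtained by relaxation: the PDE is
#' integrated in chunks until the profile change over one estimated period
#' falls below `tol` (sup-norm, relative to \eqn{2\pi}). \eqn{\Omega} is the
#' least-squares slope of the posterior phase over the final three periods.
#'
#' @param mp a [model_parameters()].
#' @param xbar0 fixed PSM length, um.
#' @param sc optional [simulation_config()]; by default a grid with
#'   `dx = 2` um and `L = 1.5 * xbar0` is used. Its `t_end` sets the chunk
#'   length (default 20 posterior periods).
#' @param tol periodicity criterion: `max_x |psi(x, t) - psi(x, t - T)|`
#'   below `tol * 2 * pi`.
#' @param t_max give up (with an error reporting the residual trace) if the
#'   state has not converged by this time, min.
#' @return An object of class `"periodic_state"`: list with `Omega`
#'   (rad/min), `T` (min), `x` and `psi` (stationary profile on
#'   `[0, xbar0]`), `xbar0`, `residual` (final periodicity residual, rad),
#'   `ode_residual` (sup-norm residual of the stationary phase equation on
#'   the PSM interior), and the final `phase_field` chunk (`field`).
#' @export
find_periodic_state <- function(mp, xbar0, sc = NULL, tol = 1e-4,
                                t_max = 20000) {
  stopifnot(inherits(mp, "model_parameters"))
  check_scalar(xbar0, "xbar0", positive = TRUE)
  T0 <- 2 * pi / mp$freq$omega0
  if (is.null(sc)) {
    sc <- simulation_config(t_end = 20 * T0, t0 = 0, dx = 2,
                            L = 1.5 * xbar0)
  }
  chunk <- sc$t_end - (sc$t0 %||% 0)
  t_now <- 0
  phi0 <- NULL
  residual <- Inf
  trace <- numeric(0)
  pf <- NULL
  repeat {
    sc$t0 <- t_now
    sc$t_end <- t_now + chunk
    pf <- simulate_constant_length(mp, xbar0, sc, phi0 = phi0)
    Omega <- posterior_frequency(pf, n_periods = 3)
    Tper <- 2 * pi / Omega
    psi <- relative_phase_profile(pf)
    nf <- nrow(psi)
    psi_end <- psi[nf, ]
    t_ref <- pf$t[nf] - Tper
    rows <- t_bracket(pf$t, t_ref)
    psi_ref <- (1 - rows$w) * psi[rows$i1, ] + rows$w * psi[rows$i2, ]
    inside <- pf$x <= xbar0
    residual <- max(abs(psi_end[inside] - psi_ref[inside]))
    trace <- c(trace, residual)
    if (residual < tol * 2 * pi) break
    t_now <- t_now + chunk
    phi0 <- pf$phi[nf, ]
    if (t_now + chunk > t_max) {
      stop(sprintf(
        "no time-periodic state by t = %g min; periodicity residuals: %s",
        t_now, paste(signif(trace, 3), collapse = ", ")), call. = FALSE)
    }
  }
  x_in <- pf$x[pf$x <= xbar0]
  psi_in <- psi_end[pf$x <= xbar0]
  structure(list(Omega = Omega, T = 2 * pi / Omega,
                 x = x_in, psi = psi_in, xbar0 = xbar0,
                 residual = residual,
                 ode_residual = stationary_residual(pf, Omega, xbar0),
                 field = pf),
            class = "periodic_state")
}

#' @export
print.periodic_state <- function(x, ...) {
  cat(sprintf("Time-periodic state at xbar0 = %g um\n", x$xbar0))
  cat(sprintf("  Omega = %.6g rad/min (T = %.4g min)\n", x$Omega, x$T))
  cat(sprintf("  waves K = %.3f, periodicity residual = %.3g rad\n",
              abs(x$psi[length(x$psi)]) / (2 * pi), x$residual))
  invisible(x)
}

# least-squares slope of phi(0, t) over the trailing n posterior periods
posterior_frequency <- function(pf, n_periods = 3) {
  T0 <- 2 * pi / pf$params$freq$omega0
  keep <- pf$t >= max(pf$t) - n_periods * T0
  tt <- pf$t[keep]
  yy <- pf$phi[keep, 1L]
  sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
}

# sup-norm residual of Omega + v psi' - omega - (eps/2) psi'' on the PSM
# interior (centered differences; nodes within 2 dx of the anterior
# frequency jump are excluded)
stationary_residual <- function(pf, Omega, xbar0) {
  nf <- nrow(pf$phi)
  psi <- pf$phi[nf, ] - pf$phi[nf, 1L]
  x <- pf$x
  dx <- x[2] - x[1]
  n <- length(x)
  dpsi <- c(0, (psi[3:n] - psi[1:(n - 2L)]) / (2 * dx), NA)
  d2psi <- c(2 * (psi[2L] - psi[1L]) / dx^2,
             (psi[3:n] - 2 * psi[2:(n - 1L)] + psi[1:(n - 2L)]) / dx^2, NA)
  mp <- pf$params
  om <- mp$freq$omega0 * eval_U(x / xbar0, mp$freq)
  vv <- mp$vel$v0 * eval_V(x / xbar0, mp$vel)
  res <- Omega + vv * dpsi - om - (mp$epsilon / 2) * d2psi
  keep <- x <= xbar0 - 2 * dx
  max(abs(res[keep]), na.rm = TRUE)
}

#' Weak-coupling approximation of the stationary phase profile
#'
#' For weak coupling the collective frequency is \eqn{\Omega \simeq \omega_0}
#' and the stationary profile follows from balancing advection against the
#' frequency mismatch:
#' \deqn{\psi(x) \simeq \int_0^x \frac{\omega(x') - \Omega}{v(x')}\,dx'.}
#' The integrand has a finite limit \eqn{\omega_0 U'(0)/(v_0 q)} at
#' \eqn{x = 0} when \eqn{\Omega = \omega_0} (both numerator and denominator
#' vanish linearly); for any other \eqn{\Omega} the integral diverges at the
#' posterior tip, which is reported as an error. Evaluated by adaptive
#' open quadrature between consecutive requested positions.
#'
#' @param mp a [model_parameters()].
#' @param xbar0 fixed PSM length, um.
#' @param x positions at which to evaluate the profile (default: 201 points
#'   spanning `[0, xbar0]`).
#' @param Omega collective frequency; defaults to `omega0` (the
#'   weak-coupling value), the only admissible choice.
#' @return A data frame with columns `x` and `psi` (rad), `psi[1] = 0`.
#' @export
weak_coupling_profile <- function(mp, xbar0, x = NULL, Omega = NULL) {
  stopifnot(inherits(mp, "model_parameters"))
  check_scalar(xbar0, "xbar0", positive = TRUE)
  omega0 <- mp$freq$omega0
  Omega <- Omega %||% omega0
  if (abs(Omega - omega0) > 1e-12) {
    stop("the profile integral diverges at x = 0 unless Omega = omega0 (v(0) = 0)",
         call. = FALSE)
  }
  if (is.null(x)) x <- seq(0, xbar0, length.out = 201L)
  x <- sort(x)
  if (x[1] < 0) stop("'x' must be >= 0", call. = FALSE)
  fp <- mp$freq; vp <- mp$vel
  limit0 <- omega0 * u_prime0(fp) / (vp$v0 * vp$q)
  f <- function(xx) {
    xi <- xx / xbar0
    val <- (omega0 * eval_U(xi, fp) - Omega) / (vp$v0 * eval_V(xi, vp))
    val[xx == 0] <- limit0
    val
  }
  psi <- numeric(length(x))
  for (i in seq_along(x)[-1]) {
    psi[i] <- psi[i - 1] +
      stats::integrate(f, x[i - 1], x[i], rel.tol = 1e-9,
                       stop.on.error = TRUE)$value
  }
  data.frame(x = x, psi = psi - psi[which.min(abs(x))] * 0)
}

# dU/dxi at xi = 0
u_prime0 <- function(fp) {
  -(1 - fp$sigma) * fp$k * exp(-fp$k) / (1 - exp(-fp$k))
}

#' Weak-coupling phase velocity
#'
#' Closed-form phase velocity of the periodic wave pattern,
#' \eqn{\tilde{v}(x) \simeq v(x) / (1 - \omega(x)/\omega_0)}: always positive
#' and larger than the cell velocity, so waves travel anteriorly faster than
#' the tissue. Diverges at the posterior tip where the frequency mismatch
#' vanishes; `x = 0` returns `Inf` (no error).
#'
#' @param x positions, um (>= 0).
#' @param mp a [model_parameters()].
#' @param xbar0 fixed PSM length, um.
#' @return Phase speed, um/min (`Inf` at `x = 0`; equals `v(x)` beyond the
#'   PSM where the intrinsic frequency is zero).
#' @export
phase_velocity_approx <- function(x, mp, xbar0) {
  stopifnot(inherits(mp, "model_parameters"))
  if (any(x < 0)) stop("'x' must be >= 0", call. = FALSE)
  xi <- x / xbar0
  vv <- mp$vel$v0 * eval_V(xi, mp$vel)
  uu <- eval_U(xi, mp$freq)
  out <- vv / (1 - uu)
  out[uu >= 1] <- Inf
  out
}

#' Clock-and-wavefront segment length
#'
#' The classical clock-and-wavefront estimate \eqn{S = v_0 T} with
#' \eqn{T = 2\pi/\Omega}: the anterior tissue advances one velocity-times-
#' period length per completed cycle. Holds approximately for time-periodic
#' patterns when \eqn{v(\bar{x}_0) \simeq v_0}.
#'
#' @param mp a [model_parameters()].
#' @param Omega collective angular frequency, rad/min (> 0).
#' @return Segment length, um.
#' @export
clock_wavefront_segment_length <- function(mp, Omega) {
  stopifnot(inherits(mp, "model_parameters"))
  check_scalar(Omega, "Omega", positive = TRUE)
  mp$vel$v0 * 2 * pi / Omega
}
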