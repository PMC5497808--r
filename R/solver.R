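#' Simulation configuration
#'
#' Grid and stepping controls for the phase-field solver. The solver uses the
#' method of lines on a fixed uniform lab-frame grid covering `[0, L]`; the
#' moving anterior end is interior to the grid. Advection is discretised by
#' first-order upwind differences (valid since the velocity is non-negative
#' everywhere) and phase coupling by centered second differences; time
#' stepping is explicit Euler.
#'
#' `dt = "auto"` selects `0.9 / (v_max/dx + epsilon/dx^2)`, the joint
#' advection-diffusion stability bound of the explicit scheme. An explicit
#' `dt` above that bound is rejected. The actual step is then rounded down so
#' that an integer number of steps spans `[t0, t_end]` and every
#' `output_stride`-th frame (plus the initial one) is stored.
#'
#' @param t_end end time, min.
#' @param t0 start time, min; defaults to the model's `t0` when `NULL`.
#' @param dx grid spacing, um.
#' @param L domain length, um; must exceed the largest PSM length reached
#'   during the run so that the anterior end stays interior.
#' @param dt time step, min, or `"auto"`.
#' @param output_stride keep every `output_stride`-th time step in the output.
#' @param coupling_beyond_psm logical; if `TRUE` (default) the coupling term
#'   acts on the whole domain including the arrested tissue beyond the
#'   anterior end, if `FALSE` it is switched off where \eqn{x > \bar{x}(t)}.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(t_end, t0 = NULL, dx = 1, L = 900, dt = "auto",
                              output_stride = 1L, coupling_beyond_psm = TRUE) {
  check_scalar(t_end, "t_end")
  if (!is.null(t0)) check_scalar(t0, "t0")
  check_scalar(dx, "dx", positive = TRUE)
  check_scalar(L, "L", positive = TRUE)
  if (!identical(dt, "auto")) check_scalar(dt, "dt", positive = TRUE)
  output_stride <- as.integer(output_stride)
  stopifnot(output_stride >= 1L, is.logical(coupling_beyond_psm))
  structure(list(t_end = t_end, t0 = t0, dx = dx, L = L, dt = dt,
                 output_stride = output_stride,
                 coupling_beyond_psm = coupling_beyond_psm),
            class = "simulation_config")
}

# explicit-scheme stability bound for upwind advection + centered diffusion
cfl_dt <- function(dx, vmax, epsilon) {
  denom <- vmax / dx + epsilon / dx^2
  if (denom <= 0) return(Inf)
  0.9 / denom
}

#' Simulate the phase field on a shortening PSM
#'
#' Integrates the phase dynamics
#' \deqn{\partial_t \phi + v \,\partial_x \phi = \omega +
#'   \tfrac{\varepsilon}{2} \partial_x^2 \phi}
#' on `[0, L]` from the spatially uniform initial condition \eqn{\phi \equiv 0}
#' at `t0`, with the no-flux condition \eqn{\partial_x \phi|_{x=0} = 0} at the
#' posterior tip (no oscillators beyond the tip) and an outflow closure
#' (zero second derivative) at `x = L`. The frequency and velocity fields are
#' rescaled each step to the current PSM length \eqn{\bar{x}(t)}; the
#' frequency discontinuity at the anterior end is kept sharp (each node is
#' classified by \eqn{\xi = x/\bar{x}(t)}, no smoothing).
#'
#' The solver is fully deterministic: identical configurations give
#' bit-identical output.
#'
#' @param mp a [model_parameters()] bundle.
#' @param sc a [simulation_config()].
#' @return A `phase_field` object: list with `x` (grid positions, um),
#'   `t` (output times, min), `phi` (matrix, rows = times, columns =
#'   positions; unwrapped phase in radians), `xbar` and `xbar_rate` (PSM
#'   length and its analytic rate at the output times), `params`, and the
#'   effective `config` (with the realised `dt`).
#' @seealso [simulate_constant_length()], [observable_series()]
#' @export
simulate_phase_field <- function(mp, sc) {
  stopifnot(inherits(mp, "model_parameters"), inherits(sc, "simulation_config"))
  lp <- mp$len
  run_solver(mp, sc,
             xbar_fun = function(t) lp$x0 + lp$x1 * tanh(lp$eta * (t - lp$tbar)),
             xbar_rate_fun = function(t) psm_length_rate(t, lp),
             xbar_constant = FALSE)
}

#' Simulate the phase field at constant PSM length
#'
#' As [simulate_phase_field()] but with the PSM length frozen at `xbar0`.
#' After a transient the solution attains a time-periodic state
#' \eqn{\phi(x,t) = \Omega t + \psi(x)}.
#'
#' @inheritParams simulate_phase_field
#' @param xbar0 fixed PSM length, um.
#' @param phi0 optional initial phase vector on the grid (defaults to zero);
#'   used to continue a previous run.
#' @return A `phase_field` object.
#' @export
simulate_constant_length <- function(mp, xbar0, sc, phi0 = NULL) {
  stopifnot(inherits(mp, "model_parameters"), inherits(sc, "simulation_config"))
  check_scalar(xbar0, "xbar0", positive = TRUE)
  run_solver(mp, sc,
             xbar_fun = function(t) xbar0,
             xbar_rate_fun = function(t) 0,
             xbar_constant = TRUE, phi0 = phi0)
}

run_solver <- function(mp, sc, xbar_fun, xbar_rate_fun, xbar_constant,
                       phi0 = NULL) {
  t0 <- sc$t0 %||% mp$t0
  t_end <- sc$t_end
  if (t_end <= t0) stop("t_end must exceed t0", call. = FALSE)
  dx <- sc$dx
  x <- seq(0, sc$L, by = dx)
  n <- length(x)

  # a moving anterior end must stay interior to the grid (a frozen length is
  # allowed to exceed it: the run then covers a posterior portion of the PSM)
  if (!xbar_constant) {
    xb_check <- vapply(seq(t0, t_end, length.out = 65L), xbar_fun, numeric(1))
    if (max(xb_check) >= sc$L) {
      stop(sprintf(
        "domain length L = %g um does not contain the PSM (max xbar = %g um)",
        sc$L, max(xb_check)), call. = FALSE)
    }
  }

  vmax <- mp$vel$v0
  dt_bound <- cfl_dt(dx, vmax, mp$epsilon)
  dt <- if (identical(sc$dt, "auto")) {
    # also resolve the oscillation itself (matters only for nearly
    # transport-free configurations where the stability bound is huge)
    min(dt_bound, 2 * pi / (20 * mp$freq$omega0))
  } else {
    sc$dt
  }
  if (dt > dt_bound * (1 + 1e-12)) {
    stop(sprintf(
      "explicit time step dt = %g min violates the stability bound %g min",
      dt, dt_bound), call. = FALSE)
  }
  stride <- sc$output_stride
  nsteps <- as.integer(stride * ceiling((t_end - t0) / (dt * stride)))
  dt <- (t_end - t0) / nsteps

  phi <- if (is.null(phi0)) numeric(n) else {
    stopifnot(length(phi0) == n)
    as.numeric(phi0)
  }

  nframes <- nsteps %/% stride + 1L
  out <- matrix(NA_real_, nframes, n)
  t_out <- numeric(nframes)
  xbar_out <- numeric(nframes)
  out[1L, ] <- phi
  t_out[1L] <- t0
  xbar_out[1L] <- xbar_fun(t0)

  omega0 <- mp$freq$omega0
  v0 <- mp$vel$v0
  half_eps <- mp$epsilon / 2
  inv_dx <- 1 / dx
  inv_dx2 <- inv_dx^2
  i_mid <- 2:(n - 1)
  no_outside_coupling <- !sc$coupling_beyond_psm

  # profile formulas inlined for the inner loop (identical to eval_U/eval_V)
  k_f <- mp$freq$k; sigma_f <- mp$freq$sigma
  u_denom <- 1 - exp(-k_f)
  q_v <- mp$vel$q
  profiles_at <- function(xi) {
    om <- omega0 * (sigma_f + (1 - sigma_f) * (1 - exp(k_f * (xi - 1))) / u_denom)
    outside <- xi > 1
    om[outside] <- 0
    list(om = om, vv = v0 * (1 - exp(-q_v * xi)), outside = outside)
  }

  if (xbar_constant) {  # hoist the profile evaluation out of the loop
    pr_c <- profiles_at(x / xbar_fun(t0))
  }

  for (s in seq_len(nsteps)) {
    t_now <- t0 + (s - 1) * dt
    pr <- if (xbar_constant) pr_c else profiles_at(x / xbar_fun(t_now))
    om <- pr$om; vv <- pr$vv
    adv <- c(0, phi[-1L] - phi[-n]) * inv_dx      # upwind, v >= 0
    lap <- c(2 * (phi[2L] - phi[1L]),             # Neumann ghost at x = 0
             phi[-(1:2)] - 2 * phi[i_mid] + phi[-((n - 1):n)],
             0) * inv_dx2                         # outflow closure at x = L
    if (no_outside_coupling) lap[pr$outside] <- 0
    phi <- phi + dt * (om - vv * adv + half_eps * lap)
    if (s %% stride == 0L) {
      if (anyNA(phi) || any(!is.finite(phi))) {
        stop(sprintf("non-finite phase at step %d (t = %g min)", s,
                     t_now + dt), call. = FALSE)
      }
      k <- s %/% stride + 1L
      out[k, ] <- phi
      t_out[k] <- t0 + s * dt
      xbar_out[k] <- xbar_fun(t0 + s * dt)
    }
  }

  sc$dt <- dt
  sc$t0 <- t0
  structure(list(x = x, t = t_out, phi = out,
                 xbar = xbar_out,
                 xbar_rate = vapply(t_out, xbar_rate_fun, numeric(1)),
                 params = mp, config = sc),
            class = "phase_field")
}

#' @export
print.phase_field <- function(x, ...) {
  cat(sprintf("Phase field: %d frames x %d nodes\n",
              nrow(x$phi), ncol(x$phi)))
  cat(sprintf("  t in [%g, %g] min (frame spacing %g min)\n",
              min(x$t), max(x$t), x$t[2] - x$t[1]))
  cat(sprintf("  x in [0, %g] um (dx = %g um); PSM length %g -> %g um\n",
              max(x$x), x$x[2] - x$x[1], x$xbar[1], x$xbar[length(x$xbar)]))
  invisible(x)
}

#' Kymograph plot of a phase field
#'
#' Displays \eqn{\sin \phi(x, t)} as a space-time density plot with the
#' anterior end \eqn{\bar{x}(t)} overlaid, the standard way wave patterns in
#' the PSM are visualised.
#'
#' @param x a `phase_field`.
#' @param ... passed to [graphics::image()].
#' @export
plot.phase_field <- function(x, ...) {
  graphics::image(x$t, x$x, sin(x$phi),
                  col = grDevices::hcl.colors(64, "Blue-Red 2"),
                  xlab = "time (min)", ylab = "position (um)", ...)
  graphics::lines(x$t, x$xbar, lwd = 2)
  invisible(x)
}

#' Interpolate the phase field
#'
#' Bilinear interpolation of the stored phase at arbitrary positions and
#' times (linear between the two flanking grid nodes / output frames).
#'
#' @param pf a `phase_field`.
#' @param x positions, um.
#' @param t times, min (recycled against `x`).
#' @return Phase values, rad.
#' @export
phase_at <- function(pf, x, t) {
  stopifnot(inherits(pf, "phase_field"))
  nn <- max(length(x), length(t))
  x <- rep_len(x, nn)
  t <- rep_len(t, nn)
  if (any(t < min(pf$t) - 1e-9) || any(t > max(pf$t) + 1e-9)) {
    stop("'t' outside the simulated range", call. = FALSE)
  }
  if (any(x < 0) || any(x > max(pf$x))) {
    stop("'x' outside the simulated domain", call. = FALSE)
  }
  vapply(seq_len(nn), function(i) {
    rows <- t_bracket(pf$t, t[i])
    v1 <- interp_row(pf$phi[rows$i1, ], pf$x, x[i])
    if (rows$i1 == rows$i2) return(v1)
    v2 <- interp_row(pf$phi[rows$i2, ], pf$x, x[i])
    (1 - rows$w) * v1 + rows$w * v2
  }, numeric(1))
}

# linear interpolation of one stored frame at position x0
interp_row <- function(row, x, x0) {
  dx <- x[2] - x[1]
  j <- min(max(1L, 1L + floor(x0 / dx)), length(x) - 1L)
  w <- (x0 - x[j]) / dx
  (1 - w) * row[j] + w * row[j + 1L]
}

t_bracket <- function(tgrid, t0) {
  i <- findInterval(t0, tgrid, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(tgrid) - 1L)
  w <- (t0 - tgrid[i]) / (tgrid[i + 1L] - tgrid[i])
  if (w < 0) w <- 0
  if (w > 1) w <- 1
  list(i1 = i, i2 = i + 1L, w = w)
}

# PSM length at arbitrary time, linear between output frames (consistent for
# both shortening and frozen-length runs)
xbar_at <- function(pf, t) {
  stats::approx(pf$t, pf$xbar, xout = t, rule = 2)$y
}
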