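#' Number of waves in the PSM
#'
#' The wave count \eqn{K(t) = (\phi(0,t) - \phi(\bar{x}(t),t))/2\pi}: the
#' total phase difference across the PSM in cycles, i.e. the number of
#' gene-expression waves simultaneously spanning the tissue. Real-valued,
#' not rounded.
#'
#' @param pf a `phase_field`.
#' @param t time(s) within the simulated range, min.
#' @return Dimensionless wave count.
#' @export
wave_count <- function(pf, t) {
  xb <- xbar_at(pf, t)
  (phase_at(pf, rep(0, length(t)), t) - phase_at(pf, xb, t)) / (2 * pi)
}

#' Number of formed segments
#'
#' The segment count \eqn{N(t) = \phi(\bar{x}(t),t)/2\pi}: one segment forms
#' with each completed oscillation cycle at the anterior end. With the
#' uniform zero initial phase, `N` counts cycles since `t0`; see
#' [extract_segments()] for the event records and numbering.
#'
#' @inheritParams wave_count
#' @return Real-valued segment count.
#' @export
segment_count <- function(pf, t) {
  phase_at(pf, xbar_at(pf, t), t) / (2 * pi)
}

#' Segment length at the anterior end
#'
#' The length of the segment forming at time `t` is the local wavelength of
#' the pattern at the anterior end. Two estimators are provided:
#' `"gradient"` uses \eqn{S \simeq 2\pi/|\partial_x \phi(\bar{x},t)|}
#' (valid when the gradient varies slowly over one wavelength), with the
#' spatial derivative taken one-sided from the PSM interior because the
#' phase profile is kinked at the anterior frequency jump; `"exact"` solves
#' \eqn{|\phi(\bar{x},t) - \phi(\bar{x}+S,t)| = 2\pi} for `S` by bracketing
#' on the stored (piecewise-linear) profile.
#'
#' @inheritParams wave_count
#' @param t a single time, min.
#' @param method `"gradient"` (default) or `"exact"`.
#' @return Segment length, um.
#' @export
segment_length_at_anterior <- function(pf, t, method = c("gradient", "exact")) {
  method <- match.arg(method)
  stopifnot(length(t) == 1L)
  xb <- xbar_at(pf, t)
  rows <- t_bracket(pf$t, t)
  row <- (1 - rows$w) * pf$phi[rows$i1, ] + rows$w * pf$phi[rows$i2, ]
  dx <- pf$x[2] - pf$x[1]
  if (method == "gradient") {
    # one-sided difference from the PSM interior over one grid spacing,
    # interpolated so the estimate varies smoothly as xbar crosses cells
    grad <- (phi_interior_slope(row, pf$x, xb))
    if (abs(grad) < 1e-12) {
      stop("phase gradient vanishes at the anterior end; segment length undefined",
           call. = FALSE)
    }
    return(2 * pi / abs(grad))
  }
  # exact: first 2*pi drop anterior of xbar on the interpolated profile
  phi_a <- interp_row(row, pf$x, xb)
  drop <- phi_a - row  # increases with x anterior of xbar (phase decreases)
  j0 <- floor(xb / dx) + 1L
  jhit <- which(drop >= 2 * pi & seq_along(row) > j0)
  if (!length(jhit)) {
    stop("no full 2*pi phase drop within the grid beyond the anterior end",
         call. = FALSE)
  }
  j <- jhit[1L]
  # linear interpolation inside the cell [x_{j-1}, x_j]
  w <- (2 * pi - drop[j - 1L]) / (drop[j] - drop[j - 1L])
  x_hit <- pf$x[j - 1L] + w * dx
  x_hit - xb
}

#' Relative phase profile
#'
#' \eqn{\psi(x,t) = \phi(x,t) - \phi(0,t)}: the wave pattern referenced to
#' the posterior tip. For time-periodic solutions this is the stationary
#' phase profile; on a shortening PSM it evolves as the wavelength shrinks.
#'
#' @inheritParams wave_count
#' @return A matrix of the same shape as `pf$phi` with \eqn{\psi(0,t) = 0}
#'   exactly; output times and positions in attributes `t` and `x`.
#' @export
relative_phase_profile <- function(pf) {
  psi <- pf$phi - pf$phi[, 1L]
  attr(psi, "t") <- pf$t
  attr(psi, "x") <- pf$x
  psi
}

#' Decompose the anterior segmentation frequency
#'
#' Splits the local frequency at the moving anterior end,
#' \eqn{\Omega_A = \frac{d}{dt}\phi(\bar{x}(t),t)}, into the posterior
#' frequency \eqn{\Omega_P = \partial_t \phi(0,t)}, the Doppler contribution
#' \eqn{\Omega_D = (d\bar{x}/dt)\,\partial_x \psi(\bar{x},t)} (the anterior
#' end travels through the wave pattern) and the dynamic-wavelength
#' contribution \eqn{\Omega_W = \partial_t \psi(\bar{x},t)} (the pattern's
#' wavelength changes in time at fixed position). The chain rule makes
#' \eqn{\Omega_A = \Omega_P + \Omega_D + \Omega_W} an identity; with the
#' discretisation used here it holds to second order in the frame spacing
#' at every interior frame.
#'
#' Temporal derivatives use centered differences on the output frames;
#' \eqn{d\bar{x}/dt} is the analytic rate stored with the run (never a
#' finite difference). The spatial derivative in \eqn{\Omega_D} is the
#' time-centered average of the two chord slopes of \eqn{\phi} swept by the
#' anterior end over the half-stencils
#' \eqn{[\bar{x}(t_i), \bar{x}(t_{i+1})]} and
#' \eqn{[\bar{x}(t_{i-1})), \bar{x}(t_i)]}, evaluated at \eqn{t_{i+1}} and
#' \eqn{t_{i-1}} respectively: a centered estimator of
#' \eqn{\partial_x\psi(\bar{x}(t), t)} that stays consistent with the
#' moving-point and fixed-point temporal differences, so the sum identity
#' is not polluted by the kink of the profile at the anterior frequency
#' jump. When the PSM length is (near-)constant the spatial slope falls
#' back to the one-sided difference from the PSM interior.
#'
#' @inheritParams wave_count
#' @return A data frame with columns `t`, `Omega_A`, `Omega_P`, `Omega_D`,
#'   `Omega_W` (rad/min) at the interior output frames.
#' @export
decompose_anterior_frequency <- function(pf) {
  t <- pf$t
  nf <- length(t)
  if (nf < 3L) stop("need at least three output frames", call. = FALSE)
  dt_out <- t[2] - t[1]
  check_frame_spacing(pf)
  x <- pf$x
  dx <- x[2] - x[1]
  xb <- pf$xbar
  rate <- pf$xbar_rate

  at <- function(i, j) interp_row(pf$phi[j, ], x, xb[i])  # phi(xbar_i, t_j)
  idx <- 2:(nf - 1L)
  p0 <- pf$phi[, 1L]
  Omega_P <- (p0[idx + 1L] - p0[idx - 1L]) / (2 * dt_out)
  a_prev <- vapply(idx, function(i) at(i - 1L, i - 1L), numeric(1))
  a_next <- vapply(idx, function(i) at(i + 1L, i + 1L), numeric(1))
  Omega_A <- (a_next - a_prev) / (2 * dt_out)
  w_prev <- vapply(idx, function(i) at(i, i - 1L), numeric(1)) - p0[idx - 1L]
  w_next <- vapply(idx, function(i) at(i, i + 1L), numeric(1)) - p0[idx + 1L]
  Omega_W <- (w_next - w_prev) / (2 * dt_out)
  Omega_D <- vapply(idx, function(i) {
    w_fwd <- xb[i + 1L] - xb[i]
    w_bwd <- xb[i] - xb[i - 1L]
    slope <- if (abs(w_fwd) > 1e-9 && abs(w_bwd) > 1e-9) {
      # time-centered average of the chord slopes swept by the anterior end
      # over the two half-stencils, consistent with the interpolation scheme
      0.5 * ((at(i + 1L, i + 1L) - at(i, i + 1L)) / w_fwd +
               (at(i, i - 1L) - at(i - 1L, i - 1L)) / w_bwd)
    } else {  # frozen length: interior one-sided slope (rate is ~0 anyway)
      phi_interior_slope(pf$phi[i, ], x, xb[i])
    }
    rate[i] * slope
  }, numeric(1))

  data.frame(t = t[idx], Omega_A = Omega_A, Omega_P = Omega_P,
             Omega_D = Omega_D, Omega_W = Omega_W)
}

#' Anterior-to-posterior frequency ratio for linear shortening
#'
#' Closed-form approximation of the time-averaged anterior frequency for a
#' PSM shortening linearly at speed `vbar`:
#' \deqn{\Omega_A \simeq (1 + \bar{v}/v_0)(1 - \Delta)\,\Omega_P,}
#' where the Doppler factor \eqn{1 + \bar{v}/v_0} is opposed by the
#' dynamic-wavelength factor \eqn{1 - \Delta} with
#' \deqn{\Delta = \int_0^1 \frac{\bar{v}/v_0}{(1 + \bar{v}\xi/v_0)^2}
#'   \frac{\omega(\xi)}{\omega_0}\, d\xi > 0.}
#' For a uniform frequency profile (`sigma = 1`) the two factors cancel
#' exactly (\eqn{\Delta = (\bar{v}/v_0)/(1+\bar{v}/v_0)}, evaluated in
#' closed form) and the ratio is 1; a decaying profile gives a ratio above 1:
#' segmentation runs faster than the fastest local oscillator.
#'
#' @param mp a [model_parameters()] (only the frequency-profile shape and
#'   `v0` are used).
#' @param vbar shortening speed of the PSM, um/min (>= 0).
#' @return The ratio \eqn{\Omega_A/\Omega_P} (dimensionless).
#' @export
anterior_frequency_ratio <- function(mp, vbar) {
  stopifnot(inherits(mp, "model_parameters"))
  check_scalar(vbar, "vbar")
  if (vbar < 0) stop("'vbar' must be >= 0", call. = FALSE)
  if (vbar == 0) return(1)
  a <- vbar / mp$vel$v0
  if (mp$freq$sigma == 1) {
    # uniform profile: Delta = a/(1+a) in closed form, so the Doppler factor
    # (1+a) and the dynamic-wavelength factor (1-Delta) cancel exactly
    return(1)
  } else {
    q <- stats::integrate(function(xi) {
      a / (1 + a * xi)^2 * eval_U(xi, mp$freq)
    }, 0, 1, rel.tol = 1e-10)
    if (q$message != "OK") {
      stop("quadrature for the shortening integral failed: ", q$message,
           call. = FALSE)
    }
    Delta <- q$value
  }
  (1 + a) * (1 - Delta)
}

#' Phase-velocity field of the wave pattern
#'
#' The velocity \eqn{\tilde{v} = -\partial_t \phi / \partial_x \phi} of
#' points of constant phase, estimated by centered differences on the stored
#' grid. Positions where the spatial gradient (numerically) vanishes are
#' returned as `NA` rather than raising an error.
#'
#' @inheritParams wave_count
#' @param gradient_floor spatial-gradient magnitude (rad/um) below which the
#'   phase velocity is masked as undefined.
#' @return A list with `t`, `x` (interior frames/nodes) and the matrix `v`
#'   (um/min).
#' @export
phase_velocity_field <- function(pf, gradient_floor = 1e-6) {
  nf <- nrow(pf$phi); nx <- ncol(pf$phi)
  if (nf < 3L || nx < 3L) stop("grid too small", call. = FALSE)
  dt_out <- pf$t[2] - pf$t[1]
  dx <- pf$x[2] - pf$x[1]
  dphidt <- (pf$phi[3:nf, ] - pf$phi[1:(nf - 2L), ]) / (2 * dt_out)
  dphidx <- (pf$phi[, 3:nx] - pf$phi[, 1:(nx - 2L)]) / (2 * dx)
  num <- dphidt[, 2:(nx - 1L)]
  den <- dphidx[2:(nf - 1L), ]
  v <- -num / den
  v[abs(den) < gradient_floor] <- NA_real_
  list(t = pf$t[2:(nf - 1L)], x = pf$x[2:(nx - 1L)], v = v)
}

#' Extract segment-formation events
#'
#' Locates the integer crossings of the segment count `N(t)` (one segment per
#' completed anterior oscillation cycle), interpolating linearly between
#' output frames. Each record carries the segment index (the integer crossed,
#' counted from the uniform zero phase at `t0`, plus `offset`), the formation
#' time, the segment length from [segment_length_at_anterior()] at that time,
#' and the position of the anterior end at formation.
#'
#' @inheritParams wave_count
#' @param offset integer added to the raw crossing index, for re-anchoring
#'   the numbering to an experimental staging convention.
#' @param method segment-length estimator, see [segment_length_at_anterior()].
#' @return A data frame of class `"segment_records"` with columns `index`,
#'   `formation_time`, `length`, `anterior_position`.
#' @export
extract_segments <- function(pf, offset = 0L, method = "gradient") {
  check_frame_spacing(pf)
  N <- segment_count(pf, pf$t)
  lo <- ceiling(min(N) + 1e-9)
  hi <- floor(max(N) - 1e-9)
  if (hi < lo) stop("the segment count does not span an integer", call. = FALSE)
  recs <- lapply(lo:hi, function(m) {
    i <- which(N >= m)[1L]
    if (i == 1L) return(NULL)  # crossing not bracketed by the output frames
    w <- (m - N[i - 1L]) / (N[i] - N[i - 1L])
    tm <- pf$t[i - 1L] + w * (pf$t[i] - pf$t[i - 1L])
    S <- tryCatch(segment_length_at_anterior(pf, tm, method),
                  error = function(e) NA_real_)
    data.frame(index = m + as.integer(offset),
               formation_time = tm,
               length = S,
               anterior_position = xbar_at(pf, tm))
  })
  out <- do.call(rbind, recs)
  class(out) <- c("segment_records", class(out))
  out
}

#' Staging offset for segment numbering
#'
#' Raw segment indices count anterior oscillation cycles from the uniform
#' zero phase at `t0`. Experimental staging instead numbers segments so that
#' a reference index forms at `t = 0` (for the zebrafish calibration, the
#' 7th). This helper returns the integer to add to the raw indices so the
#' record whose formation time is nearest zero carries `reference_index`.
#'
#' @param records a `"segment_records"` data frame (raw numbering).
#' @param reference_index staged index of the segment forming nearest
#'   `t = 0` (default 7, the zebrafish staging convention).
#' @return Integer offset.
#' @export
staging_offset <- function(records, reference_index = 7L) {
  stopifnot(nrow(records) >= 1L)
  as.integer(reference_index) -
    records$index[which.min(abs(records$formation_time))]
}

#' Advect segment boundaries through the tissue
#'
#' Once formed at the anterior end, a segment boundary is a material point
#' carried by the cell-velocity field: each boundary trajectory solves
#' \eqn{dx/dt = v(x, t)} from its formation position. Trajectories are
#' integrated with [deSolve::ode()] on the stored output times; portions
#' leaving the simulated domain are truncated with a warning. Used to emulate
#' experimental boundary tracking, from which the velocity profile can be
#' re-estimated ([fit_boundary_velocities()]).
#'
#' @inheritParams wave_count
#' @param records a `"segment_records"` data frame from [extract_segments()].
#' @param mp model parameters supplying the velocity profile; defaults to the
#'   ones stored with the run.
#' @return A data frame with columns `boundary` (segment index), `t`, `x`.
#' @export
track_boundaries <- function(pf, records, mp = pf$params) {
  stopifnot(nrow(records) >= 1L)
  L <- max(pf$x)
  vfun <- function(t, y, parms) {
    xb <- xbar_at(pf, t)
    list(mp$vel$v0 * (1 - exp(-mp$vel$q * y / xb)))
  }
  truncated <- FALSE
  out <- lapply(seq_len(nrow(records)), function(r) {
    t_form <- records$formation_time[r]
    times <- c(t_form, pf$t[pf$t > t_form])
    if (length(times) < 2L) return(NULL)
    sol <- deSolve::ode(y = c(x = records$anterior_position[r]),
                        times = times, func = vfun, parms = NULL)
    xs <- sol[, "x"]
    keep <- xs <= L
    if (!all(keep)) truncated <<- TRUE
    data.frame(boundary = records$index[r],
               t = sol[keep, "time"], x = xs[keep])
  })
  if (truncated) {
    warning("boundary trajectories truncated at the domain edge")
  }
  do.call(rbind, out)
}

#' Observable time series of a run
#'
#' Convenience wrapper evaluating the wave count `K`, segment count `N`,
#' anterior segment length `S` and the frequency decomposition at the
#' interior output frames of a run.
#'
#' @inheritParams wave_count
#' @return A data frame with columns `t`, `K`, `N`, `S`, `Omega_A`,
#'   `Omega_P`, `Omega_D`, `Omega_W`.
#' @export
observable_series <- function(pf) {
  dec <- decompose_anterior_frequency(pf)
  tt <- dec$t
  data.frame(t = tt,
             K = wave_count(pf, tt),
             N = segment_count(pf, tt),
             S = vapply(tt, function(ti)
               segment_length_at_anterior(pf, ti), numeric(1)),
             dec[, c("Omega_A", "Omega_P", "Omega_D", "Omega_W")])
}

# one-sided spatial slope at the anterior end from the PSM side, over one
# grid spacing, with both endpoints interpolated (the profile is kinked at
# the frequency jump, so only interior values are used)
phi_interior_slope <- function(row, x, xb) {
  dx <- x[2] - x[1]
  (interp_row(row, x, xb) - interp_row(row, x, max(0, xb - dx))) / dx
}

# the observable estimators assume frames resolve the oscillation:
# spacing below a tenth of a posterior period
check_frame_spacing <- function(pf) {
  dt_out <- pf$t[2] - pf$t[1]
  period <- 2 * pi / pf$params$freq$omega0
  if (dt_out > period / 10) {
    warning(sprintf(
      "output frame spacing (%.3g min) exceeds a tenth of the oscillation period (%.3g min); reduce output_stride",
      dt_out, period), call. = FALSE)
  }
  invisible(TRUE)
}
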