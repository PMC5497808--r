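# Shared, lazily computed simulation fixtures. The heavier runs (the full
# zebrafish shortening simulation, the periodic states, the seeded fit
# studies) are cached so several test files can reuse them.

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

# full shortening-PSM run with the zebrafish calibration, covering the
# burn-in from t0 = -256 min plus the 500-min observation window
zebrafish_run <- function() {
  cached("zebrafish_run", {
    simulate_phase_field(
      zebrafish_parameters(),
      simulation_config(t_end = 520, dx = 1, L = 900, output_stride = 2L))
  })
}

zebrafish_records <- function() {
  cached("zebrafish_records", extract_segments(zebrafish_run()))
}

zebrafish_decomposition <- function() {
  cached("zebrafish_decomposition",
         decompose_anterior_frequency(zebrafish_run()))
}

# time-periodic state at xbar0 = 417 um for a given coupling strength
periodic_state_eps <- function(eps) {
  key <- paste0("periodic_", eps)
  cached(key, {
    mp <- model_parameters(epsilon = eps)
    find_periodic_state(mp, 417)
  })
}

# seeded phase-kymograph fit study: relative errors of (k, sigma, q) and
# the absolute t0 error, one column per seed
phase_fit_errors <- function(sd, seeds) {
  key <- paste0("phase_fit_", sd, "_", paste(seeds, collapse = "_"))
  cached(key, {
    mp <- zebrafish_parameters()
    sc <- simulation_config(t_end = 300, dx = 8, L = 656)
    fixed <- list(omega0 = 0.15, v0 = 0.87, epsilon = 7)
    starts <- matrix(c(1, 0.25, 1.2, 3, 0.5, 2.5), ncol = 3, byrow = TRUE)
    vapply(seeds, function(s) {
      kymo <- make_phase_kymograph(mp, sc, t_keep = c(-200, 300),
                                   frame_every = 10, sd = sd,
                                   seed = if (sd > 0) s else NULL)
      est <- fit_phase_profile(kymo, mp$len, fixed, starts = starts,
                               control = list(maxit = 500, reltol = 1e-8)
                               )$estimates
      c(k = abs(est[["k"]] / 2.07 - 1),
        sigma = abs(est[["sigma"]] / 0.34 - 1),
        q = abs(est[["q"]] / 1.80 - 1),
        t0 = abs(est[["t0"]] + 256))
    }, numeric(4))
  })
}

# PSM length at arbitrary times, interpolated from the stored trajectory
xbar_at_times <- function(pf, t) {
  stats::approx(pf$t, pf$xbar, xout = t, rule = 2)$y
}

# hand-built phase field for a plane wave phi = omega*t - 2*pi*x/lambda on a
# frozen domain; an exact analytic object, independent of the solver
plane_wave_field <- function(omega = 0.15, lambda = 40, xbar0 = 300,
                             L = 400, dx = 1, t_end = 100, dt = 1) {
  x <- seq(0, L, by = dx)
  t <- seq(0, t_end, by = dt)
  mp <- model_parameters(freq = frequency_profile(omega0 = omega),
                         len = length_dynamics(x0 = xbar0, x1 = 0),
                         t0 = 0)
  structure(list(x = x, t = t,
                 phi = outer(t, x, function(tt, xx)
                   omega * tt - 2 * pi * xx / lambda),
                 xbar = rep(xbar0, length(t)),
                 xbar_rate = rep(0, length(t)),
                 params = mp,
                 config = simulation_config(t_end = t_end, t0 = 0, dx = dx,
                                            L = L, dt = dt)),
            class = "phase_field")
}
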