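test_that("a spatially uniform frequency keeps the phase uniform", {
  # frozen PSM longer than the grid and sigma = 1: omega = omega0 everywhere
  mp <- model_parameters(freq = frequency_profile(sigma = 1), t0 = 0)
  sc <- simulation_config(t_end = 100, t0 = 0, dx = 2, L = 200,
                          output_stride = 5L)
  pf <- simulate_constant_length(mp, 1000, sc)
  for (i in seq_along(pf$t)) {
    expect_equal(pf$phi[i, ], rep(0.15 * pf$t[i], length(pf$x)),
                 tolerance = 1e-12)
  }
})

test_that("decoupled resting oscillators integrate their local frequency exactly", {
  mp <- model_parameters(vel = velocity_profile(v0 = 0), epsilon = 0, t0 = 0)
  sc <- simulation_config(t_end = 80, t0 = 0, dx = 2, L = 450,
                          output_stride = 10L)
  pf <- simulate_constant_length(mp, 300, sc)
  om <- frequency_field(pf$x, 0, mp$freq, length_dynamics(x0 = 300, x1 = 0))
  i_end <- length(pf$t)
  expect_equal(pf$phi[i_end, ], om * pf$t[i_end], tolerance = 1e-12)
})

test_that("identical configurations give bit-identical runs", {
  mp <- zebrafish_parameters()
  sc <- simulation_config(t_end = -150, dx = 4, L = 700, output_stride = 2L)
  pf1 <- simulate_phase_field(mp, sc)
  pf2 <- simulate_phase_field(mp, sc)
  expect_identical(pf1$phi, pf2$phi)
  expect_identical(pf1$t, pf2$t)
})

test_that("the uncoupled solver matches the method-of-characteristics solution", {
  # independent oracle: integrate backwards along dx*/dt = v(x*) with
  # deSolve and accumulate the phase source along the characteristic
  mp <- model_parameters(epsilon = 0, t0 = 0)
  xbar0 <- 300
  sc <- simulation_config(t_end = 150, t0 = 0, dx = 0.1, L = 400,
                          output_stride = 50L)
  pf <- simulate_constant_length(mp, xbar0, sc)
  lp0 <- length_dynamics(x0 = xbar0, x1 = 0)
  t_end <- max(pf$t)
  oracle <- function(x_query) {
    back <- function(tau, y, parms) {
      list(c(-velocity_field(max(y[1], 0), 0, mp$vel, lp0),
             -frequency_field(max(y[1], 0), 0, mp$freq, lp0)))
    }
    sol <- deSolve::ode(y = c(x = x_query, phi = 0),
                        times = c(0, t_end), func = back, parms = NULL,
                        rtol = 1e-10, atol = 1e-10)
    unname(-sol[2, "phi"])  # phase accumulated forward along the characteristic
  }
  for (xq in c(60, 150, 240)) {
    expected <- oracle(xq)
    got <- phase_at(pf, xq, t_end)
    expect_equal(got, expected, tolerance = 1e-3)
  }
})

test_that("with no coupling, a larger frequency profile never lowers the phase", {
  sc <- simulation_config(t_end = 120, t0 = 0, dx = 4, L = 700, dt = 2,
                          output_stride = 20L)
  mk <- function(om0) model_parameters(freq = frequency_profile(omega0 = om0),
                                       epsilon = 0, t0 = 0)
  pf1 <- simulate_phase_field(mk(0.15), sc)
  pf2 <- simulate_phase_field(mk(0.16), sc)
  expect_true(all(pf2$phi - pf1$phi >= -1e-12))
})

test_that("the scheme self-converges under grid refinement", {
  mp <- zebrafish_parameters()
  run <- function(dx) {
    sc <- simulation_config(t_end = -100, dx = dx, L = 700,
                            output_stride = 1L)
    pf <- simulate_phase_field(mp, sc)
    phase_at(pf, c(100, 300, 500), -100)
  }
  coarse <- run(4); mid <- run(2); fine <- run(1)
  err_coarse <- max(abs(coarse - fine))
  err_mid <- max(abs(mid - fine))
  expect_lt(err_mid, err_coarse)      # refinement reduces the error
  expect_lt(err_mid, 0.1)             # and the error is small in radians
})

test_that("the no-flux condition holds at the posterior tip", {
  pf <- zebrafish_run()
  dx <- pf$x[2] - pf$x[1]
  idx <- seq(1, nrow(pf$phi), by = 50)
  grad0 <- abs(pf$phi[idx, 2] - pf$phi[idx, 1]) / dx
  curv <- abs(pf$phi[idx, 3] - 2 * pf$phi[idx, 2] + pf$phi[idx, 1]) / dx^2
  expect_true(all(grad0 <= 10 * dx * pmax(curv, 1e-6)))
})

test_that("configuration errors are caught before stepping", {
  mp <- zebrafish_parameters()
  expect_error(
    simulate_phase_field(mp, simulation_config(t_end = 100, dx = 1, L = 500)),
    "does not contain the PSM")
  expect_error(
    simulate_phase_field(mp, simulation_config(t_end = 100, dx = 1, L = 900,
                                               dt = 1)),
    "stability")
  expect_error(
    simulate_phase_field(mp, simulation_config(t_end = -300, dx = 1, L = 900)),
    "exceed")
})

test_that("phase interpolation and serialisation round-trip the field", {
  mp <- zebrafish_parameters()
  sc <- simulation_config(t_end = -200, dx = 4, L = 700, output_stride = 4L)
  pf <- simulate_phase_field(mp, sc)
  # interpolation agrees with stored nodes
  expect_equal(phase_at(pf, pf$x[10], pf$t[5]), pf$phi[5, 10])
  expect_error(phase_at(pf, 10, 1000), "outside")
  dir <- withr::local_tempdir()
  write_phase_field(pf, dir)
  back <- read_phase_field(dir)
  expect_identical(back$phi, unname(pf$phi))
  expect_identical(back$t, pf$t)
  expect_identical(back$xbar, pf$xbar)
})
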