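test_that("noiseless length series are recovered exactly", {
  mp <- zebrafish_parameters()
  d <- make_length_series(mp, t_end = 500, n = 20)
  fit <- fit_length_dynamics(d)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["x0"]], 417, tolerance = 1e-6)
  expect_equal(fit$estimates[["x1"]], 202, tolerance = 1e-6)
  expect_equal(fit$estimates[["eta"]], -5.09e-3, tolerance = 1e-6)
  expect_equal(fit$estimates[["tbar"]], 192, tolerance = 1e-6)
  # the implied peak shortening speed of the recovered sigmoid
  expect_equal(abs(fit$estimates[["x1"]] * fit$estimates[["eta"]]), 1.02818,
               tolerance = 1e-6)
  expect_error(fit_length_dynamics(d[1:3, ]), "4 data points")
})

test_that("noisy length series are recovered within the expected error", {
  mp <- zebrafish_parameters()
  fits <- vapply(1:100, function(s) {
    d <- make_length_series(mp, t_end = 500, n = 20, sd = 10, seed = s)
    fit_length_dynamics(d)$estimates
  }, numeric(4))
  err <- abs(sweep(fits, 1, c(417, 202, -5.09e-3, 192), "/") - 1)
  med <- apply(err, 1, stats::median)
  expect_lt(med[["x0"]], 0.05)
  expect_lt(med[["x1"]], 0.05)
  expect_lt(med[["eta"]], 0.15)
  # the shortening sign is identified in every replicate
  expect_true(all(fits["eta", ] < 0))
})

test_that("a constant length series yields a flagged flat fit", {
  d <- data.frame(t = seq(0, 400, length.out = 12), length = 400)
  expect_warning(fit <- fit_length_dynamics(d), "flat")
  expect_equal(fit$estimates[["x1"]], 0)
  expect_equal(fit$estimates[["eta"]], 0)
  expect_false(fit$converged)
})

test_that("boundary tracks recover the velocity profile", {
  mp <- zebrafish_parameters()
  sc <- simulation_config(t_end = 900, t0 = 0, dx = 2, L = 800,
                          output_stride = 4L)
  tracks <- suppressWarnings(
    make_boundary_tracks(mp, sc, constant_length = 417))
  fit <- fit_boundary_velocities(tracks)
  expect_equal(fit$estimates[["v0"]], 0.87, tolerance = 0.05)
  expect_equal(fit$estimates[["q_over_xbar"]], 1.8 / 417, tolerance = 0.05)
  expect_false(fit$wide_interval)
})

test_that("stationary tracks give zero velocity and short tracks are excluded", {
  tracks <- data.frame(boundary = rep(1:3, each = 5),
                       t = rep(seq(0, 40, by = 10), 3),
                       x = rep(c(100, 200, 300), each = 5))
  fit <- fit_boundary_velocities(tracks)
  expect_equal(fit$estimates[["v0"]], 0, tolerance = 1e-9)
  with_single <- rbind(tracks,
                       data.frame(boundary = 4, t = 0, x = 50))
  expect_warning(fit_boundary_velocities(with_single), "excluded")
})

test_that("far-field tracks identify v0 but leave the shape weakly constrained", {
  # boundaries already far anterior, where the profile has saturated
  a_true <- 1.8 / 417
  v_of <- function(x) 0.87 * (1 - exp(-a_true * x))
  tracks <- do.call(rbind, lapply(seq(1600, 2400, by = 100), function(x0) {
    tt <- seq(0, 60, by = 10)
    xx <- x0 + v_of(x0) * tt   # locally linear advection in the far field
    data.frame(boundary = x0, t = tt, x = xx)
  }))
  fit <- fit_boundary_velocities(tracks)
  expect_equal(fit$estimates[["v0"]], 0.87, tolerance = 0.05)
  expect_true(fit$wide_interval)
})

test_that("a noiseless kymograph is inverted to the generating parameters", {
  errs <- phase_fit_errors(0, 1)
  expect_lt(errs["k", 1], 0.02)
  expect_lt(errs["sigma", 1], 0.02)
  expect_lt(errs["q", 1], 0.02)
  expect_lt(errs["t0", 1], 5)
})

test_that("noisy kymographs are recovered within ten percent in the median", {
  errs <- phase_fit_errors(0.3, 1:20)
  med <- apply(errs, 1, stats::median)
  expect_lt(med[["k"]], 0.1)
  expect_lt(med[["sigma"]], 0.1)
  expect_lt(med[["q"]], 0.1)
  expect_lt(med[["t0"]], 5)
})

test_that("recovery error decreases with the phase-noise level", {
  seeds <- 1:5
  med_err <- vapply(c(0.5, 0.3, 0.1), function(sd) {
    errs <- phase_fit_errors(sd, seeds)
    stats::median(colMeans(errs[c("k", "sigma", "q"), ]))
  }, numeric(1))
  noiseless <- mean(phase_fit_errors(0, 1)[c("k", "sigma", "q"), 1])
  expect_true(all(diff(med_err) < 0))
  expect_lt(noiseless, med_err[3])
})

test_that("the kymograph objective ignores a constant phase offset", {
  mp <- zebrafish_parameters()
  sc <- simulation_config(t_end = 300, dx = 8, L = 656)
  kymo <- make_phase_kymograph(mp, sc, t_keep = c(-200, 300),
                               frame_every = 10, sd = 0.2, seed = 3)
  shifted <- kymo
  shifted$values <- kymo$values + 1.234
  fixed <- list(omega0 = 0.15, v0 = 0.87, epsilon = 7)
  starts <- matrix(c(1.5, 0.3, 1.5), ncol = 3)
  ctrl <- list(maxit = 120)
  f1 <- suppressWarnings(fit_phase_profile(kymo, mp$len, fixed,
                                           starts = starts, control = ctrl))
  f2 <- suppressWarnings(fit_phase_profile(shifted, mp$len, fixed,
                                           starts = starts, control = ctrl))
  expect_identical(f1$estimates, f2$estimates)
  expect_equal(f1$residual, f2$residual, tolerance = 1e-12)
})
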