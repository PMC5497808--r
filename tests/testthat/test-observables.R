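test_that("a plane wave yields exact wave count, segment length and phase velocity", {
  lambda <- 40
  omega <- 0.15
  pf <- plane_wave_field(omega = omega, lambda = lambda, xbar0 = 300)
  expect_equal(wave_count(pf, 50), 300 / lambda, tolerance = 1e-10)
  expect_equal(segment_length_at_anterior(pf, 50, "gradient"), lambda,
               tolerance = 1e-10)
  expect_equal(segment_length_at_anterior(pf, 50, "exact"), lambda,
               tolerance = 1e-8)
  pvf <- phase_velocity_field(pf)
  expect_equal(max(abs(pvf$v - omega * lambda / (2 * pi))), 0,
               tolerance = 1e-10)
})

test_that("wave and segment counts are zero for a uniform phase", {
  pf <- plane_wave_field(lambda = 1e12, xbar0 = 300)  # effectively uniform
  expect_equal(wave_count(pf, 10), 0, tolerance = 1e-6)
  pf$phi[] <- 0
  expect_equal(segment_count(pf, 10), 0)
  expect_error(wave_count(pf, 1e5), "outside")
})

test_that("the relative phase profile is referenced to the posterior tip", {
  pf <- zebrafish_run()
  psi <- relative_phase_profile(pf)
  expect_true(all(psi[, 1] == 0))
  # consistency of the wave count with the relative profile at the anterior
  tt <- seq(0, 400, by = 80)
  K <- wave_count(pf, tt)
  psi_ant <- phase_at(pf, xbar_at_times(pf, tt), tt) - phase_at(pf, 0 * tt, tt)
  expect_equal(K, -psi_ant / (2 * pi), tolerance = 1e-12)
  # shrinking run: anterior wavelength decreases over the observation window
  expect_lt(segment_length_at_anterior(pf, 450),
            segment_length_at_anterior(pf, 50))
})

test_that("the frequency decomposition reproduces the zebrafish sign structure", {
  dec <- zebrafish_decomposition()
  shortening <- dec$t >= 0 & dec$t <= 450
  expect_gt(mean(dec$Omega_D[shortening]), 0)
  expect_lt(mean(dec$Omega_W[shortening]), 0)
  expect_gt(abs(mean(dec$Omega_D[shortening])),
            abs(mean(dec$Omega_W[shortening])))
  # segmentation runs faster than the posterior clock on average
  expect_gt(mean(dec$Omega_A[shortening]), mean(dec$Omega_P[shortening]))
})

test_that("the segmentation rate equals the anterior frequency over two pi", {
  pf <- zebrafish_run()
  dec <- zebrafish_decomposition()
  dt_out <- pf$t[2] - pf$t[1]
  N <- segment_count(pf, pf$t)
  idx <- 2:(length(pf$t) - 1)
  dNdt <- (N[idx + 1] - N[idx - 1]) / (2 * dt_out)
  expect_equal(dNdt, dec$Omega_A / (2 * pi), tolerance = 1e-10)
})

test_that("frozen-length periodic runs have no Doppler or dynamic-wavelength part", {
  ps <- periodic_state_eps(7)
  dec <- decompose_anterior_frequency(ps$field)
  late <- dec$t > max(dec$t) - 3 * ps$T
  expect_equal(max(abs(dec$Omega_D[late])), 0, tolerance = 1e-12)
  expect_lt(max(abs(dec$Omega_W[late])), 1e-3)
  expect_equal(dec$Omega_A[late], dec$Omega_P[late], tolerance = 1e-2)
  expect_equal(mean(dec$Omega_P[late]), ps$Omega, tolerance = 1e-3)
})

test_that("the wave count substantially decreases during segmentation", {
  pf <- zebrafish_run()
  expect_gt(wave_count(pf, 0) - wave_count(pf, 450), 0.8)
})

test_that("segment records are ordered, positive, and non-monotonic in length", {
  recs <- zebrafish_records()
  expect_true(all(diff(recs$formation_time) > 0))
  expect_true(all(recs$length > 0, na.rm = TRUE))
  expect_true(all(diff(recs$anterior_position) < 0))  # shortening PSM
  # within the observation window the length curve has an interior maximum
  win <- recs[recs$formation_time >= 0 & recs$formation_time <= 500, ]
  imax <- which.max(win$length)
  expect_gt(imax, 1)
  expect_lt(imax, nrow(win))
  # staging: the record nearest t = 0 is anchored to index 7
  off <- staging_offset(recs)
  staged <- recs$index + off
  expect_identical(staged[which.min(abs(recs$formation_time))], 7L)
})

test_that("gradient and exact segment lengths agree where the wavelength varies slowly", {
  pf <- zebrafish_run()
  recs <- zebrafish_records()
  late <- recs$formation_time > 100 & recs$formation_time < 500
  S_exact <- vapply(recs$formation_time[late], function(ti)
    segment_length_at_anterior(pf, ti, "exact"), numeric(1))
  expect_equal(recs$length[late], S_exact, tolerance = 0.1)
})

test_that("uniform oscillations at frozen length form equally spaced segments", {
  mp <- model_parameters(freq = frequency_profile(sigma = 1),
                         vel = velocity_profile(v0 = 0), epsilon = 0, t0 = 0)
  sc <- simulation_config(t_end = 300, t0 = 0, dx = 4, L = 400,
                          output_stride = 1L)
  pf <- simulate_constant_length(mp, 300, sc)
  recs <- extract_segments(pf)
  expect_true(all(abs(diff(recs$formation_time) - 2 * pi / 0.15) < 1e-6))
  expect_true(all(is.na(recs$length)))  # uniform phase: no wavelength
})

test_that("boundary tracks advect with the velocity field", {
  pf <- zebrafish_run()
  recs <- zebrafish_records()
  suppressWarnings(tracks <- track_boundaries(pf, recs))
  expect_setequal(unique(tracks$boundary), recs$index)
  # early-formed boundaries end up far anterior, moving at nearly v0
  tr1 <- tracks[tracks$boundary == recs$index[1], ]
  n <- nrow(tr1)
  late_speed <- (tr1$x[n] - tr1$x[n - 50]) / (tr1$t[n] - tr1$t[n - 50])
  xi_late <- tr1$x[n] / xbar_at_times(pf, tr1$t[n])
  expect_equal(late_speed, 0.87 * (1 - exp(-1.8 * xi_late)), tolerance = 0.01)
  # v0 = 0: boundaries stay where they formed
  mp0 <- model_parameters(vel = velocity_profile(v0 = 1e-12), epsilon = 0,
                          t0 = 0)
  sc <- simulation_config(t_end = 150, t0 = 0, dx = 4, L = 400,
                          output_stride = 1L)
  pf0 <- simulate_constant_length(mp0, 300, sc)
  recs0 <- extract_segments(pf0)
  tracks0 <- track_boundaries(pf0, recs0, mp0)
  expect_lt(max(abs(tracks0$x - 300)), 1e-6)
})

test_that("the linear-shortening frequency ratio behaves as derived", {
  mp <- zebrafish_parameters()
  expect_identical(anterior_frequency_ratio(mp, 0), 1)
  # uniform profile: Doppler and dynamic-wavelength effects cancel exactly
  mp_flat <- model_parameters(freq = frequency_profile(sigma = 1))
  expect_identical(anterior_frequency_ratio(mp_flat, 1.03), 1)
  # independent Riemann-sum oracle for the zebrafish profile
  r <- anterior_frequency_ratio(mp, 1.03)
  expect_gt(r, 1)
  a <- 1.03 / 0.87
  xi <- (seq_len(2e5) - 0.5) / 2e5  # midpoint rule
  Delta <- mean(a / (1 + a * xi)^2 * eval_U(xi, mp$freq))
  expect_equal(r, (1 + a) * (1 - Delta), tolerance = 1e-5)
})

test_that("the observable series bundles the derived quantities consistently", {
  pf <- zebrafish_run()
  obs <- observable_series(pf)
  expect_named(obs, c("t", "K", "N", "S", "Omega_A", "Omega_P", "Omega_D",
                      "Omega_W"))
  expect_true(all(diff(obs$N) > 0))
  expect_equal(obs$K, wave_count(pf, obs$t), tolerance = 1e-12)
})
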