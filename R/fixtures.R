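#' Synthetic PSM-length time series
#'
#' Emulates staged measurements of PSM length during segmentation: the
#' sigmoidal length law evaluated at `n` equally spaced times plus i.i.d.
#' Gaussian noise (embryo-to-embryo and measurement variability). A seed is
#' mandatory whenever the noise is nonzero so every fixture is reproducible.
#'
#' @param mp a [model_parameters()] (the length dynamics and `t0` are used).
#' @param t_end last sampling time, min.
#' @param n number of samples (>= 2), spanning `[t0, t_end]`.
#' @param sd Gaussian noise standard deviation, um (>= 0).
#' @param seed integer seed; required if `sd > 0`.
#' @return A data frame with columns `t` (min) and `length` (um).
#' @export
make_length_series <- function(mp, t_end = 500, n = 20L, sd = 0,
                               seed = NULL) {
  stopifnot(inherits(mp, "model_parameters"), n >= 2L, sd >= 0)
  tt <- seq(mp$t0, t_end, length.out = n)
  y <- psm_length(tt, mp$len) + fixture_noise(n, sd, seed)
  data.frame(t = tt, length = y)
}

#' Synthetic segment-boundary tracks
#'
#' Emulates boundary-tracking data: runs the full phase-field simulation,
#' extracts the segment-formation events, advects each boundary through the
#' velocity field ([track_boundaries()]) and adds Gaussian positional noise.
#'
#' @inheritParams make_length_series
#' @param sc a [simulation_config()]; must be long enough for at least two
#'   segments to form.
#' @param sd positional noise standard deviation, um.
#' @param constant_length optional fixed PSM length, um: when supplied the
#'   run is at frozen length, so the fitted inverse length `q_over_xbar`
#'   corresponds exactly to `q / constant_length`.
#' @return A data frame with columns `boundary`, `t`, `x`, as
#'   [track_boundaries()] returns.
#' @export
make_boundary_tracks <- function(mp, sc, sd = 0, seed = NULL,
                                 constant_length = NULL) {
  stopifnot(inherits(mp, "model_parameters"), sd >= 0)
  pf <- if (is.null(constant_length)) {
    simulate_phase_field(mp, sc)
  } else {
    simulate_constant_length(mp, constant_length, sc)
  }
  recs <- extract_segments(pf)
  if (nrow(recs) < 2L) {
    stop("simulation too short: fewer than 2 segments formed", call. = FALSE)
  }
  tracks <- track_boundaries(pf, recs, mp)
  tracks$x <- tracks$x + fixture_noise(nrow(tracks), sd, seed)
  tracks
}

#' Synthetic phase kymograph
#'
#' Emulates an averaged experimental phase kymograph: runs the phase-field
#' simulation, extracts the relative phase \eqn{\psi(x,t)} (referenced to
#' the posterior tip, so \eqn{\psi(0,t) = 0} in every noise-free frame),
#' restricts to the requested observation window, and adds Gaussian phase
#' noise. Noise is applied to the unwrapped phase and reported unwrapped;
#' wrapping is the consumer's concern (the circular fit objective of
#' [fit_phase_profile()] is insensitive to it).
#'
#' @inheritParams make_boundary_tracks
#' @param t_keep length-2 numeric: observation window, min (frames outside
#'   are dropped, emulating data that starts well after oscillations began).
#' @param frame_every keep roughly one frame per this many minutes.
#' @param sd phase noise standard deviation, rad.
#' @return A list of class `"kymograph"` with `x`, `t`, `values` (rows =
#'   times, columns = positions) and attribute `what = "psi"`.
#' @export
make_phase_kymograph <- function(mp, sc, t_keep = NULL, frame_every = NULL,
                                 sd = 0, seed = NULL) {
  stopifnot(inherits(mp, "model_parameters"), sd >= 0)
  pf <- simulate_phase_field(mp, sc)
  psi <- relative_phase_profile(pf)
  keep <- rep(TRUE, length(pf$t))
  if (!is.null(t_keep)) {
    keep <- pf$t >= t_keep[1] & pf$t <= t_keep[2]
  }
  if (!is.null(frame_every)) {
    stride <- max(1L, round(frame_every / (pf$t[2] - pf$t[1])))
    keep <- keep & (seq_along(pf$t) - 1L) %% stride == 0L
  }
  vals <- psi[keep, , drop = FALSE]
  vals <- vals + matrix(fixture_noise(length(vals), sd, seed),
                        nrow(vals), ncol(vals))
  structure(list(x = pf$x, t = pf$t[keep], values = vals, what = "psi"),
            class = "kymograph")
}

fixture_noise <- function(n, sd, seed) {
  if (sd == 0) return(numeric(n))
  if (is.null(seed)) {
    stop("a seed is required whenever the noise sd is nonzero", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  stats::rnorm(n, sd = sd)
}
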