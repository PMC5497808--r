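#' Fit the PSM length dynamics
#'
#' Nonlinear least squares of the sigmoidal length law
#' \eqn{\bar{x}(t) = x_0 + x_1 \tanh(\eta(t - \bar{t}))} to a
#' (time, length) table, via [minpack.lm::nlsLM()]. Starting values are
#' derived from the data (midrange, half-range, secant slope). The sign
#' convention `x1 >= 0` is enforced after fitting (the law is invariant
#' under jointly flipping the signs of `x1` and `eta`); a shortening series
#' therefore returns `eta < 0`. A (near-)constant series cannot constrain
#' the sigmoid and returns a flat fit (`x1 = eta = 0`) with a warning.
#'
#' @param data a data frame with columns `t` (min) and `length` (um),
#'   at least 4 points spanning some curvature of the sigmoid.
#' @return An object of class `"seg_fit"`: list with `estimates` (named
#'   x0, x1, eta, tbar), `residual` (residual sum of squares), `n_points`,
#'   `converged`, and the underlying `fit` object (or `NULL` for the
#'   degenerate flat fit).
#' @export
fit_length_dynamics <- function(data) {
  stopifnot(is.data.frame(data), all(c("t", "length") %in% names(data)))
  data <- data[stats::complete.cases(data[, c("t", "length")]), ]
  if (nrow(data) < 4L) stop("need at least 4 data points", call. = FALSE)
  y <- data$length
  tt <- data$t
  if (stats::sd(y) < sqrt(.Machine$double.eps) * max(1, mean(abs(y)))) {
    warning("constant length series: returning a flat fit with eta = 0")
    return(seg_fit(c(x0 = mean(y), x1 = 0, eta = 0, tbar = mean(tt)),
                   residual = sum((y - mean(y))^2), n_points = nrow(data),
                   converged = FALSE, fit = NULL))
  }
  x1_0 <- diff(range(y)) / 2
  slope <- stats::cov(tt, y) / stats::var(tt)
  start <- list(x0 = mean(range(y)), x1 = x1_0,
                eta = slope / x1_0,
                tbar = tt[which.min(abs(y - mean(range(y))))])
  fit <- minpack.lm::nlsLM(length ~ x0 + x1 * tanh(eta * (t - tbar)),
                           data = data, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  if (est[["x1"]] < 0) {  # canonical sign convention
    est[["x1"]] <- -est[["x1"]]
    est[["eta"]] <- -est[["eta"]]
  }
  seg_fit(est[c("x0", "x1", "eta", "tbar")],
          residual = sum(stats::resid(fit)^2), n_points = nrow(data),
          converged = fit$convInfo$isConv, fit = fit)
}

#' Fit the velocity profile to segment-boundary tracks
#'
#' Reduces each boundary track to its mean velocity (least-squares slope of
#' position against time) and mean position, then fits the saturating
#' profile \eqn{v = v_0 (1 - e^{-a x})} through the (position, velocity)
#' points, with the inverse length \eqn{a = q/\bar{x}} treated as a single
#' parameter (boundary tracking mixes epochs with different PSM lengths, so
#' only the combination is identified). Tracks with fewer than 2 points are
#' excluded with a warning. If far-field tracks alone are supplied
#' (positions well beyond \eqn{1/a}) the profile is flat there and `a` is
#' weakly constrained; the `wide_interval` flag reports this, based on the
#' relative standard error of `a` and on whether the saturating term
#' \eqn{e^{-ax}} varies by less than 5 percentage points across the
#' sampled positions.
#'
#' @param tracks a data frame with columns `boundary`, `t`, `x` (as returned
#'   by [track_boundaries()]), or a list of per-boundary data frames with
#'   columns `t`, `x`.
#' @return A `"seg_fit"` with `estimates` named `v0` (um/min) and
#'   `q_over_xbar` (1/um), plus a `summary` data frame of per-boundary mean
#'   positions and velocities and a `wide_interval` flag.
#' @export
fit_boundary_velocities <- function(tracks) {
  if (is.data.frame(tracks)) {
    stopifnot(all(c("boundary", "t", "x") %in% names(tracks)))
    tracks <- split(tracks[, c("t", "x")], tracks$boundary)
  }
  keep <- vapply(tracks, nrow, integer(1)) >= 2L
  if (!all(keep)) {
    warning(sprintf("%d track(s) with < 2 points excluded", sum(!keep)))
    tracks <- tracks[keep]
  }
  if (length(tracks) < 2L) stop("need at least 2 usable tracks", call. = FALSE)
  summ <- do.call(rbind, lapply(tracks, function(d) {
    data.frame(position = mean(d$x),
               velocity = stats::cov(d$t, d$x) / stats::var(d$t))
  }))
  if (max(abs(summ$velocity)) < 1e-9) {  # all boundaries stationary
    return(seg_fit(c(v0 = 0, q_over_xbar = NA_real_),
                   residual = sum(summ$velocity^2),
                   n_points = nrow(summ), converged = TRUE, fit = NULL,
                   summary = summ, wide_interval = TRUE))
  }
  start <- list(v0 = max(summ$velocity), a = 1 / mean(summ$position))
  fit <- minpack.lm::nlsLM(velocity ~ v0 * (1 - exp(-a * position)),
                           data = summ, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(v0 = NA_real_, a = NA_real_))
  # the shape is identified only where the saturating term still varies
  # over the sampled positions; a far-field-only design leaves it flat
  sat_range <- exp(-est[["a"]] * min(summ$position)) -
    exp(-est[["a"]] * max(summ$position))
  wide <- !is.finite(se[["a"]]) || se[["a"]] > 0.5 * abs(est[["a"]]) ||
    sat_range < 0.05
  seg_fit(c(v0 = est[["v0"]], q_over_xbar = est[["a"]]),
          residual = sum(stats::resid(fit)^2), n_points = nrow(summ),
          converged = fit$convInfo$isConv, fit = fit,
          summary = summ, wide_interval = wide)
}

#' Fit profile-shape parameters to a phase kymograph
#'
#' Estimates the frequency-profile shape `(k, sigma)`, the velocity-profile
#' shape `q` and the initial time `t0` by matching the forward-simulated
#' relative phase \eqn{\psi(x,t) = \phi(x,t) - \phi(0,t)} to a measured
#' phase kymograph over the PSM region. The mismatch is the circular loss
#' \eqn{\sum (1 - \cos(\psi_{model} - \psi_{data} - \hat{c}))} over grid
#' points with \eqn{0 \le x \le \bar{x}(t)}, where \eqn{\hat{c}} is the
#' maximum-likelihood global circular offset of the residuals: the loss is
#' insensitive to any \eqn{2\pi} wrapping of the data and exactly invariant
#' to a constant phase added to all data (\eqn{\psi} is referenced to the
#' posterior tip, so a global offset carries no information). The PSM
#' length dynamics
#' are supplied, not fitted (fit them first with [fit_length_dynamics()]),
#' and `omega0`, `v0`, `epsilon` are held fixed, as they are sourced from
#' direct measurement rather than the wave pattern.
#'
#' Optimisation is derivative-free Nelder-Mead on transformed parameters
#' (`log k`, `logit sigma`, `log q`, and `log(t_min - t0)` so the phase
#' field always starts before the data), started from a coarse grid of 8
#' points over `(k, sigma, q)` to guard against the sigma-k trade-off; the
#' best start's optimum is polished with a second Nelder-Mead pass.
#'
#' @param kymo a kymograph as returned by [make_phase_kymograph()] or
#'   [read_kymograph()]: list with `x` (um, uniform), `t` (min) and matrix
#'   `values` (rad, rows = times).
#' @param lp a [length_dynamics()] describing \eqn{\bar{x}(t)}.
#' @param fixed named list with `omega0`, `v0`, `epsilon`.
#' @param starts optional matrix of starting values (columns k, sigma, q).
#' @param t0_init initial guess for `t0`, min (default: 200 min before the
#'   first kymograph frame).
#' @param control passed to [stats::optim()] (Nelder-Mead); the default
#'   allows 600 iterations per start at `reltol = 1e-10`.
#' @return A `"seg_fit"` with `estimates` named `k`, `sigma`, `q`, `t0`.
#' @export
fit_phase_profile <- function(kymo, lp, fixed, starts = NULL, t0_init = NULL,
                              control = list(maxit = 600, reltol = 1e-10)) {
  stopifnot(is.list(kymo), all(c("x", "t", "values") %in% names(kymo)),
            inherits(lp, "length_dynamics"),
            all(c("omega0", "v0", "epsilon") %in% names(fixed)))
  x <- kymo$x
  dxs <- diff(x)
  if (max(abs(dxs - dxs[1])) > 1e-8 * dxs[1]) {
    stop("kymograph positions must be uniformly spaced", call. = FALSE)
  }
  t_min <- min(kymo$t)
  t0_init <- t0_init %||% (t_min - 200)
  if (t0_init >= t_min) stop("'t0_init' must precede the first frame",
                             call. = FALSE)
  mask <- outer(psm_length(kymo$t, lp), x, `>=`)  # x <= xbar(t) per frame
  psi_data <- kymo$values

  sc <- simulation_config(t_end = max(kymo$t), t0 = NULL,
                          dx = dxs[1], L = max(x))
  objective <- function(theta) {
    k <- exp(theta[1])
    sigma <- stats::plogis(theta[2])
    q <- exp(theta[3])
    t0 <- t_min - exp(theta[4])
    mp <- model_parameters(
      freq = frequency_profile(fixed$omega0, k, sigma),
      vel = velocity_profile(fixed$v0, q),
      len = lp, epsilon = fixed$epsilon, t0 = t0)
    pf <- tryCatch(simulate_phase_field(mp, sc), error = function(e) NULL)
    if (is.null(pf)) return(1e6)
    psi <- relative_phase_profile(pf)
    # model frames interpolated onto the data times
    psi_m <- t(vapply(kymo$t, function(ti) {
      rows <- t_bracket(pf$t, ti)
      (1 - rows$w) * psi[rows$i1, ] + rows$w * psi[rows$i2, ]
    }, numeric(length(x))))
    delta <- (psi_m - psi_data)[mask]
    # quotient out one global circular offset (its ML estimate), so the
    # objective is exactly invariant to adding a constant to the data phases
    offset <- atan2(mean(sin(delta)), mean(cos(delta)))
    sum(1 - cos(delta - offset))
  }

  if (is.null(starts)) {
    starts <- as.matrix(expand.grid(k = c(1, 3), sigma = c(0.2, 0.6),
                                    q = c(1, 3)))
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    theta0 <- c(log(starts[i, 1]), stats::qlogis(starts[i, 2]),
                log(starts[i, 3]), log(t_min - t0_init))
    opt <- stats::optim(theta0, objective, method = "Nelder-Mead",
                        control = control)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  best <- stats::optim(best$par, objective, method = "Nelder-Mead",
                       control = control)  # polish
  est <- c(k = unname(exp(best$par[1])),
           sigma = unname(stats::plogis(best$par[2])),
           q = unname(exp(best$par[3])),
           t0 = unname(t_min - exp(best$par[4])))
  converged <- best$convergence == 0L
  if (!converged) {
    warning("phase-profile fit did not converge; returning the best iterate")
  }
  seg_fit(est, residual = best$value,
          n_points = sum(mask), converged = converged, fit = best)
}

seg_fit <- function(estimates, residual, n_points, converged, fit, ...) {
  structure(list(estimates = estimates, residual = residual,
                 n_points = n_points, converged = converged, fit = fit, ...),
            class = "seg_fit")
}

#' @export
print.seg_fit <- function(x, ...) {
  cat("Parameter fit", if (!x$converged) "(NOT converged)", "\n")
  print(signif(x$estimates, 6))
  cat(sprintf("  objective = %.6g over %d points\n", x$residual, x$n_points))
  invisible(x)
}
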