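# Minimum-jerk reference trajectories and perturbations.

new_reference_trajectory <- function(times, theta, thetadot, thetaddot,
                                     duration, theta_start, theta_end,
                                     sample_rate) {
  structure(list(times = times, theta_des = theta, thetadot_des = thetadot,
                 thetaddot_des = thetaddot, duration = duration,
                 theta_start = theta_start, theta_end = theta_end,
                 sample_rate = sample_rate),
            class = "reference_trajectory")
}

grid_times <- function(duration, sample_rate) {
  n <- round(duration * (sample_rate - 1)) + 1L
  seq(0, duration, length.out = n)
}

#' Minimum-jerk reference trajectory
#'
#' The quintic point-to-point motion
#' \eqn{\theta(t) = \theta_0 + \Delta\theta\,(10s^3 - 15s^4 + 6s^5)},
#' \eqn{s = t/T}, which minimizes integrated squared jerk and has zero velocity
#' and acceleration at both endpoints.  Analytic first and second derivatives
#' are returned on the same inclusive grid (121 samples for a 1 s task at the
#' default 121 Hz).
#'
#' @param theta_start,theta_end endpoint elbow angles (rad).
#' @param duration movement time (s); the study uses 1 s (fast) and 2 s (slow).
#' @param sample_rate grid rate (Hz).
#' @return an object of class `reference_trajectory`.
#' @export
make_min_jerk <- function(theta_start = 0, theta_end = pi / 2, duration = 1,
                          sample_rate = 121) {
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0, got ", duration, call. = FALSE)
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be > 0, got ", sample_rate, call. = FALSE)
  t <- grid_times(duration, sample_rate)
  s <- t / duration
  dth <- theta_end - theta_start
  theta <- theta_start + dth * (10 * s^3 - 15 * s^4 + 6 * s^5)
  thetadot <- dth / duration * (30 * s^2 - 60 * s^3 + 30 * s^4)
  thetaddot <- dth / duration^2 * (60 * s - 180 * s^2 + 120 * s^3)
  new_reference_trajectory(t, theta, thetadot, thetaddot, duration,
                           theta_start, theta_end, sample_rate)
}

# C^2 compact-support bump (1 - x^2)^3 on |x| < 1 and its derivatives.
bump3 <- function(x) ifelse(abs(x) < 1, (1 - x^2)^3, 0)
bump3_d1 <- function(x) ifelse(abs(x) < 1, -6 * x * (1 - x^2)^2, 0)
bump3_d2 <- function(x) ifelse(abs(x) < 1, -6 * (1 - x^2)^2 + 24 * x^2 * (1 - x^2), 0)

smoothstep <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5
smoothstep_d1 <- function(s) 30 * s^2 - 60 * s^3 + 30 * s^4
smoothstep_d2 <- function(s) 60 * s - 180 * s^2 + 120 * s^3

#' Perturb a reference trajectory
#'
#' Adds a smooth disturbance with analytically consistent derivatives, used by
#' the robustness checks of the closed loop.  `rapid_change` adds one
#' compact-support bump centered mid-span; `intermittent` adds a
#' ramp-hold-ramp plateau occupying the middle half of the motion.  Both leave
#' the endpoint angle, velocity and acceleration unchanged.
#'
#' @param traj a [make_min_jerk()] trajectory.
#' @param kind `"rapid_change"` or `"intermittent"`.
#' @param magnitude disturbance amplitude (rad).
#' @return a perturbed `reference_trajectory`.
#' @export
perturb_trajectory <- function(traj, kind = c("rapid_change", "intermittent"),
                               magnitude = 0.1) {
  kind <- match.arg(kind)
  t <- traj$times
  T <- traj$duration
  if (kind == "rapid_change") {
    w <- T / 8
    x <- (t - T / 2) / w
    add <- magnitude * bump3(x)
    add1 <- magnitude * bump3_d1(x) / w
    add2 <- magnitude * bump3_d2(x) / w^2
  } else {
    # plateau: rise over [T/4, 3T/8], hold, fall over [5T/8, 3T/4]
    r1 <- pmin(pmax((t - T / 4) / (T / 8), 0), 1)
    r2 <- pmin(pmax((t - 5 * T / 8) / (T / 8), 0), 1)
    add <- magnitude * (smoothstep(r1) - smoothstep(r2))
    add1 <- magnitude * (smoothstep_d1(r1) - smoothstep_d1(r2)) / (T / 8)
    add2 <- magnitude * (smoothstep_d2(r1) - smoothstep_d2(r2)) / (T / 8)^2
  }
  out <- traj
  out$theta_des <- traj$theta_des + add
  out$thetadot_des <- traj$thetadot_des + add1
  out$thetaddot_des <- traj$thetaddot_des + add2
  out
}

#' Export a trajectory as a two-column CSV
#'
#' @param traj a `reference_trajectory`.
#' @param path output path; columns `time`, `theta`.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(data.frame(time = traj$times, theta = traj$theta_des),
                   path, row.names = FALSE)
  invisible(path)
}

#' Import a trajectory from a two-column CSV
#'
#' Reads a (time, angle) series and recovers consistent velocity and
#' acceleration with a smoothing spline resampled on the package grid.
#'
#' @param path CSV with columns `time` (s) and `theta` (rad).
#' @param sample_rate output grid rate (Hz).
#' @param spar smoothing parameter passed to [stats::smooth.spline()]; `NULL`
#'   lets the spline interpolate nearly exactly.
#' @return a `reference_trajectory`.
#' @export
read_trajectory_csv <- function(path, sample_rate = 121, spar = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time", "theta") %in% names(d)))
    stop("trajectory CSV needs columns 'time' and 'theta'", call. = FALSE)
  duration <- max(d$time) - min(d$time)
  sp <- if (is.null(spar)) stats::smooth.spline(d$time, d$theta, spar = 0.1)
        else stats::smooth.spline(d$time, d$theta, spar = spar)
  t <- grid_times(duration, sample_rate) + min(d$time)
  theta <- stats::predict(sp, t)$y
  thetadot <- stats::predict(sp, t, deriv = 1)$y
  thetaddot <- stats::predict(sp, t, deriv = 2)$y
  new_reference_trajectory(t - min(d$time), theta, thetadot, thetaddot,
                           duration, theta[1], theta[length(theta)],
                           sample_rate)
}

#' @export
print.reference_trajectory <- function(x, ...) {
  cat(sprintf(
    "<reference_trajectory> %.3g -> %.3g rad in %.3g s (%d samples @ %g Hz)\n",
    x$theta_start, x$theta_end, x$duration, length(x$times), x$sample_rate))
  invisible(x)
}

#' @export
plot.reference_trajectory <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(oldpar))
  graphics::plot(x$times, x$theta_des, type = "l", xlab = "time (s)",
                 ylab = expression(theta ~ "(rad)"), ...)
  graphics::plot(x$times, x$thetadot_des, type = "l", xlab = "time (s)",
                 ylab = expression(dot(theta) ~ "(rad/s)"))
  graphics::plot(x$times, x$thetaddot_des, type = "l", xlab = "time (s)",
                 ylab = expression(ddot(theta) ~ "(rad/s"^2 * ")"))
  invisible(x)
}
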