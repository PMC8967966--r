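# Hill-type muscle mechanics: geometry, force multipliers, activation dynamics.
#
# Curve constants follow the Thelen-family defaults: active force-length
# Gaussian width 0.45, eccentric plateau 1.4, passive exponential shape 4 with
# strain 0.6 at maximal passive force.  A rigid tendon with a
# constant-thickness pennation model keeps every quantity algebraic in the
# joint state.

THETA_FIT_RANGE <- c(-0.1, 1.8)  # rad, validity of the fixture polynomials

#' Evaluate muscle geometry at a joint state
#'
#' Computes MTU length and signed moment arm from the fixture polynomials,
#' then fiber length, pennation and fiber velocity under the rigid-tendon,
#' constant-thickness assumptions (`l sin(phi) = l_opt sin(phi_opt)`).
#' Fiber velocity is negative when shortening.
#'
#' @param muscle a [muscle_params()].
#' @param theta elbow angle (rad); values outside the polynomial fit range
#'   [-0.1, 1.8] are clamped.
#' @param thetadot elbow angular velocity (rad/s).
#' @param activation optional activation stored in the state (default `NA`).
#' @return an object of class `muscle_state` with fields `fiber_length`,
#'   `norm_fiber_length`, `fiber_velocity`, `norm_fiber_velocity`,
#'   `pennation`, `moment_arm`, `mtu_length`, `activation`, `clamped`.
#' @export
evaluate_geometry <- function(muscle, theta, thetadot = 0, activation = NA_real_) {
  clamped <- theta < THETA_FIT_RANGE[1] || theta > THETA_FIT_RANGE[2]
  th <- min(max(theta, THETA_FIT_RANGE[1]), THETA_FIT_RANGE[2])
  lmt <- polyval(muscle$mtu_length_coeffs, th)
  d <- polyval(muscle$moment_arm_coeffs, th)
  h <- muscle$optimal_fiber_length * sin(muscle$pennation_at_optimal)
  proj <- lmt - muscle$tendon_slack_length  # fiber length along the tendon line
  if (proj <= 1e-6) proj <- 1e-6            # degenerate guard
  l <- sqrt(proj^2 + h^2)
  cosphi <- proj / l
  # dl/dt = (proj / l) * dLmt/dtheta * thetadot; dLmt/dtheta = -sign*|d|
  dlmt_dtheta <- polyval(polyder(muscle$mtu_length_coeffs), th)
  v <- cosphi * dlmt_dtheta * thetadot
  structure(list(
    fiber_length = l,
    norm_fiber_length = l / muscle$optimal_fiber_length,
    fiber_velocity = v,
    norm_fiber_velocity = v / (muscle$max_contraction_velocity *
                                 muscle$optimal_fiber_length),
    pennation = acos(min(cosphi, 1)),
    moment_arm = d,
    mtu_length = lmt,
    activation = activation,
    clamped = clamped
  ), class = "muscle_state")
}

#' Active force-length multiplier
#'
#' Gaussian-type curve \eqn{f(\tilde l) = \exp(-(\tilde l - 1)^2/\gamma)}.
#'
#' @param norm_fiber_length fiber length / optimal fiber length.
#' @param gamma curve width, default 0.45.
#' @return multiplier in [0, 1].
#' @export
active_force_length <- function(norm_fiber_length, gamma = 0.45) {
  exp(-(norm_fiber_length - 1)^2 / gamma)
}

#' Force-velocity multiplier
#'
#' Hill-hyperbola concentric branch reaching 0 at maximal shortening
#' (normalized velocity -1) and a rational eccentric branch rising to the
#' lengthening plateau `fmlen` with a slope-continuous junction at zero
#' velocity.  The effective velocity scale shrinks at submaximal activation
#' (`0.25 + 0.75 a`), after the Thelen treatment.
#'
#' @param norm_fiber_velocity fiber velocity / maximal shortening velocity,
#'   negative when shortening.
#' @param activation muscle activation, default 1.
#' @param af Hill shape parameter, default 0.25.
#' @param fmlen eccentric plateau, default 1.4.
#' @return force multiplier, nonnegative.
#' @export
force_velocity <- function(norm_fiber_velocity, activation = 1,
                           af = 0.25, fmlen = 1.4) {
  v <- norm_fiber_velocity / (0.25 + 0.75 * activation)
  conc <- pmax(0, (1 + v) / (1 - v / af))
  c0 <- (fmlen - 1) * af / (1 + af)  # slope continuity at v = 0
  ecc <- (fmlen * v + c0) / (v + c0)
  ifelse(v < 0, conc, ecc)
}

#' Passive force-length multiplier
#'
#' Exponential passive-elastic curve, zero at or below slack
#' (\eqn{\tilde l \le 1}) and increasing above it:
#' \eqn{f_p = (e^{k(\tilde l - 1)/\epsilon_0} - 1)/(e^k - 1)}.
#'
#' @param norm_fiber_length fiber length / optimal fiber length.
#' @param kf exponential shape, default 4.
#' @param e0 passive strain at maximal isometric force, default 0.6.
#' @return multiplier, nonnegative.
#' @export
passive_force_length <- function(norm_fiber_length, kf = 4, e0 = 0.6) {
  x <- pmax(norm_fiber_length - 1, 0)
  (exp(kf * x / e0) - 1) / (exp(kf) - 1)
}

#' Hill-type muscle force
#'
#' \eqn{F = F_m [f(l) f(v) a + f_p(l)] \cos\phi}; never negative.  The force
#' is linear in activation: the force-velocity multiplier is a pure velocity
#' curve (evaluated at full activation), which keeps the forward model
#' consistent with the linear-in-activation moment equality that static
#' optimization enforces.
#'
#' @param params a [muscle_params()].
#' @param state a `muscle_state` from [evaluate_geometry()] with `activation`
#'   set.
#' @return fiber force projected on the tendon line (N).
#' @export
muscle_force <- function(params, state) {
  a <- state$activation
  fl <- active_force_length(state$norm_fiber_length)
  fv <- force_velocity(state$norm_fiber_velocity, activation = 1)
  fp <- passive_force_length(state$norm_fiber_length)
  f <- params$max_isometric_force * (fl * fv * a + fp) * cos(state$pennation)
  max(f, 0)
}

#' Activation dynamics rate
#'
#' First-order excitation-to-activation lag with a state-dependent time
#' constant: \eqn{da/dt = (u - a)/\kappa(a, u)} where
#' \eqn{\kappa = \kappa_{act}(0.5 + 1.5a)} while activating (`u > a`) and
#' \eqn{\kappa = \kappa_{deact}/(0.5 + 1.5a)} while deactivating.
#'
#' @param a activation in [0, 1].
#' @param u excitation in [0, 1].
#' @param params a [muscle_params()] supplying the time constants.
#' @return da/dt (1/s).
#' @export
activation_derivative <- function(a, u, params) {
  if (any(a < -1e-12 | a > 1 + 1e-12) || any(u < -1e-12 | u > 1 + 1e-12))
    stop("activation and excitation must lie in [0, 1]", call. = FALSE)
  kappa <- ifelse(u > a,
                  params$act_time_constant * (0.5 + 1.5 * a),
                  params$deact_time_constant / (0.5 + 1.5 * a))
  (u - a) / kappa
}

#' Invert the activation dynamics for the excitation
#'
#' Given an activation and its desired rate, solves the activation ODE for the
#' excitation.  A positive rate is only consistent with the activating branch
#' and a nonpositive rate with the deactivating branch, so the branch choice
#' is determined by the sign of `dadt`; the result is clamped to [0, 1] and
#' the clamp recorded in the `"clamped"` attribute.
#'
#' @param a activation in [0, 1].
#' @param dadt target activation rate (1/s).
#' @param params a [muscle_params()].
#' @return excitation in [0, 1] with attribute `clamped`.
#' @export
excitation_from_activation <- function(a, dadt, params) {
  u <- ifelse(dadt > 0,
              a + params$act_time_constant * (0.5 + 1.5 * a) * dadt,
              a + params$deact_time_constant / (0.5 + 1.5 * a) * dadt)
  uc <- pmin(pmax(u, 0), 1)
  structure(uc, clamped = any(uc != u))
}
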