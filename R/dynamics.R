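# Single-DOF rigid-body dynamics: inverse dynamics with PD feedback, forward
# integration of the joint + activation states, and the elbow joint-reaction
# force balance.

SOFT_STOP <- c(-0.2, 2.0)  # rad, simulation aborts outside

#' Rotational inertia about the elbow
#'
#' Forearm inertia (tabulated sagittal-plane component, used as-is in the
#' default `"elbow"` frame interpretation, or augmented by `m lc^2` under the
#' `"com"` interpretation) plus the point-load term `M ll^2`.
#'
#' @param model an [arm_model()].
#' @return inertia (kg m^2).
#' @export
mass_about_elbow <- function(model) {
  I <- model$segment$inertia_about_elbow
  if (identical(model$inertia_frame, "com"))
    I <- I + model$segment$forearm_mass * model$segment$com_distance^2
  I + model$load$external_mass * model$load$load_distance^2
}

#' Gravity-demanded flexion moment
#'
#' \eqn{G(\theta) = (m g l_c + M g l_l)\sin\theta}: the muscle moment required
#' to hold the forearm and load against gravity at angle theta from vertical.
#'
#' @param model an [arm_model()].
#' @param theta elbow angle (rad).
#' @return moment (N m).
#' @export
gravity_moment <- function(model, theta) {
  g <- model$gravity
  (model$segment$forearm_mass * g * model$segment$com_distance +
     model$load$external_mass * g * model$load$load_distance) * sin(theta)
}

#' Inverse dynamics with PD-augmented acceleration
#'
#' The commanded acceleration is the reference acceleration plus PD feedback
#' on the tracking error,
#' \eqn{\ddot\theta = \ddot\theta_{des} + k_p\Delta\theta + k_v\Delta\dot\theta},
#' and the net muscle moment is \eqn{\tau = I\ddot\theta + G(\theta) - A}
#' (gravity and inertia evaluated at the fed-back state; the
#' centripetal/Coriolis term is identically zero for a single revolute joint).
#' `literal_form = TRUE` switches to the all-minus composition
#' \eqn{\tau = I\ddot\theta - G - A} kept for archaeology.
#'
#' @param model an [arm_model()].
#' @param traj_sample list with `theta`, `thetadot`, `thetaddot` of the
#'   reference at this instant.
#' @param feedback list with measured `theta`, `thetadot`.
#' @param gains a [pd_gains()].
#' @param assist_moment external assist moment A (N m).
#' @param literal_form use the literal minus-sign composition.
#' @return net muscle moment (N m) with attribute `thetaddot_cmd`.
#' @export
inverse_dynamics_moment <- function(model, traj_sample, feedback,
                                    gains = pd_gains(), assist_moment = 0,
                                    literal_form = FALSE) {
  dth <- traj_sample$theta - feedback$theta
  dthd <- traj_sample$thetadot - feedback$thetadot
  acc <- traj_sample$thetaddot + gains$kp * dth + gains$kv * dthd
  I <- mass_about_elbow(model)
  G <- gravity_moment(model, feedback$theta)
  tau <- if (literal_form) I * acc - G - assist_moment
         else I * acc + G - assist_moment
  attr(tau, "thetaddot_cmd") <- acc
  tau
}

# Right-hand side of the forward model: theta, thetadot, six activations.
# Controls (excitations and cable tensions) are held constant over a step.
forward_rhs <- function(model, include_muscle_forces = TRUE) {
  I <- mass_about_elbow(model)
  muscles <- model$muscles
  has_suit <- !is.null(model$exosuit)
  kap <- muscles_kappa(muscles)
  function(t, y, parms) {
    theta <- y[1]; thetadot <- y[2]
    a <- pmin(pmax(y[3:8], 0), 1)
    tau <- 0
    if (include_muscle_forces) {
      for (i in seq_along(muscles)) {
        st <- evaluate_geometry(muscles[[i]], theta, thetadot, activation = a[i])
        tau <- tau + st$moment_arm * muscle_force(muscles[[i]], st)
      }
    }
    if (has_suit && (parms$T1 > 0 || parms$T2 > 0)) {
      cg <- cable_geometry(model$exosuit, theta)
      tau <- tau + cg$r1 * parms$T1 - cg$r2 * parms$T2
    }
    acc <- (tau - gravity_moment(model, theta)) / I
    da <- activation_derivative(a, parms$u, kap)
    list(c(thetadot, acc, da))
  }
}

# activation_derivative() accepts vectorized time constants via this shim
muscles_kappa <- function(muscles) {
  list(act_time_constant = vapply(muscles, `[[`, numeric(1), "act_time_constant"),
       deact_time_constant = vapply(muscles, `[[`, numeric(1),
                                    "deact_time_constant"))
}

#' Advance the forward model by one control interval
#'
#' Integrates the joint state together with the six activation ODEs over `dt`
#' with an adaptive Dormand-Prince scheme, holding the control frame
#' (excitations and cable tensions) constant.
#'
#' @param model an [arm_model()].
#' @param state list with `theta`, `thetadot` and `activations` (6-vector).
#' @param controls list with `excitations` (6-vector in [0,1]) and tensions
#'   `T1`, `T2` (N).
#' @param dt step duration (s).
#' @param settings a [sim_settings()].
#' @param include_muscle_forces internal switch used by the integrator energy
#'   audit (pendulum-only dynamics).
#' @return list with the advanced `theta`, `thetadot`, `activations`.
#' @export
forward_step <- function(model, state, controls, dt, settings = sim_settings(),
                         include_muscle_forces = TRUE) {
  y0 <- c(state$theta, state$thetadot, state$activations)
  rhs <- forward_rhs(model, include_muscle_forces)
  parms <- list(u = controls$excitations, T1 = controls$T1, T2 = controls$T2)
  sol <- deSolve::ode(y = y0, times = c(0, dt), func = rhs, parms = parms,
                      method = "ode45", rtol = settings$rtol,
                      atol = settings$atol, hmax = settings$integrator_max_step,
                      hmin = settings$integrator_min_step,
                      hini = min(dt, settings$integrator_max_step))
  yf <- sol[nrow(sol), -1]
  if (any(!is.finite(yf)))
    stop(sprintf("integration failure at dt = %.4g s: non-finite state [%s]",
                 dt, paste(signif(yf, 4), collapse = ", ")), call. = FALSE)
  if (yf[1] < SOFT_STOP[1] || yf[1] > SOFT_STOP[2])
    stop(sprintf(
      "soft joint stop exceeded: theta = %.4g rad outside [%g, %g] (thetadot = %.4g)",
      yf[1], SOFT_STOP[1], SOFT_STOP[2], yf[2]), call. = FALSE)
  list(theta = unname(yf[1]), thetadot = unname(yf[2]),
       activations = pmin(pmax(unname(yf[3:8]), 0), 1))
}

#' Elbow joint reaction force
#'
#' Newton-Euler force balance on the forearm plus load: the world-frame force
#' the upper arm exerts on the forearm at the elbow is
#' \eqn{R = m_{tot} a_{com} - m_{tot} g - \sum F_{muscle} - F_{cable}}.
#' Muscle force vectors act along the straight line from each muscle's
#' effective insertion (on the forearm) toward its effective origin (on the
#' upper arm), as reconstructed from the fixture geometry.
#'
#' @param model an [arm_model()].
#' @param state list with `theta`, `thetadot`, `thetaddot`.
#' @param muscle_forces 6-vector of muscle tendon forces (N).
#' @param cable_force_on_forearm world-frame cable force vector (N, N).
#' @return list with `fx`, `fy`, `magnitude` (N).
#' @export
joint_reaction <- function(model, state, muscle_forces,
                           cable_force_on_forearm = c(0, 0)) {
  m <- model$segment$forearm_mass
  M <- model$load$external_mass
  mt <- m + M
  r_com <- (m * model$segment$com_distance +
              M * model$load$load_distance) / mt
  d <- forearm_axis(state$theta)
  n <- forearm_perp(state$theta)
  a_com <- r_com * (state$thetaddot * n - state$thetadot^2 * d)
  fmus <- c(0, 0)
  for (i in seq_along(model$muscles)) {
    mus <- model$muscles[[i]]
    p_ins <- mus$insertion_s * d + mus$insertion_offset * n
    v <- mus$origin_xy - p_ins
    fmus <- fmus + muscle_forces[i] * v / sqrt(sum(v^2))
  }
  gvec <- c(0, -model$gravity * mt)
  r <- mt * a_com - gvec - fmus - cable_force_on_forearm
  list(fx = r[1], fy = r[2], magnitude = sqrt(sum(r^2)))
}
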