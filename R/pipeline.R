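# Closed-loop computed-muscle-control pipeline.
#
# Per control step on the sampling grid: read the fed-back joint state from
# the forward model; compute the gravity-compensation assist moment from the
# measured angle (assist ON); inverse dynamics with PD feedback; static
# optimization for target activations; backward-difference target-activation
# rate inverted through the activation dynamics for excitations; cable
# tensions from the assist moment; forward dynamics to the next grid point
# with controls held.  Fully deterministic.

#' Run one closed-loop elbow flexion simulation
#'
#' The central entry point: simulates the six-muscle elbow tracking a
#' reference trajectory under computed muscle control, optionally assisted by
#' the gravity-compensation cable exosuit, and assembles the full time-series
#' record (kinematics, joint moment, activations, excitations, muscle forces,
#' cable tensions, strap interaction forces, elbow reaction force, metabolic
#' breakdown).
#'
#' @param model an [arm_model()].
#' @param trajectory a [make_min_jerk()] reference.
#' @param gains a [pd_gains()].
#' @param assist logical: exosuit actuator ON/OFF.
#' @param settings a [sim_settings()].
#' @param label free-text run label.
#' @return an object of class `exosim_result`.
#' @export
simulate_flexion <- function(model, trajectory, gains = pd_gains(),
                             assist = FALSE, settings = sim_settings(),
                             label = "") {
  validate_arm_model(model)
  t <- trajectory$times
  n <- length(t)
  if (n < 2) stop("trajectory needs at least two samples", call. = FALSE)
  dt <- diff(t)
  muscles <- model$muscles
  nm <- vapply(muscles, `[[`, character(1), "name")
  I <- mass_about_elbow(model)

  theta <- thetadot <- thetaddot <- tau <- assist_m <- T1 <- T2 <- numeric(n)
  rx <- ry <- rmag <- fnorm <- fshear <- reserve <- numeric(n)
  act <- exc <- tgt <- force <- nfl <- fvel <- matrix(0, n, 6,
                                                     dimnames = list(NULL, nm))
  state <- list(theta = trajectory$theta_des[1], thetadot = 0,
                activations = rep(0, 6))
  a_prev <- NULL
  clamp_events <- 0L

  for (k in seq_len(n)) {
    th <- state$theta; thd <- state$thetadot
    A <- gc_assist_moment(model, th, enabled = assist)
    tau_k <- inverse_dynamics_moment(
      model,
      list(theta = trajectory$theta_des[k],
           thetadot = trajectory$thetadot_des[k],
           thetaddot = trajectory$thetaddot_des[k]),
      list(theta = th, thetadot = thd), gains, assist_moment = A)
    prob <- build_problem(model, th, thd, as.numeric(tau_k))
    a_tgt <- solve_redundancy(prob, warm_start = a_prev, quiet = TRUE)
    reserve[k] <- attr(a_tgt, "reserve_moment")
    rate <- if (is.null(a_prev)) rep(0, 6)
            else (as.numeric(a_tgt) - as.numeric(a_prev)) / dt[max(k - 1, 1)]
    u <- excitation_from_activation(as.numeric(a_tgt), rate,
                                    muscles_kappa(muscles))
    if (isTRUE(attr(u, "clamped"))) clamp_events <- clamp_events + 1L
    u <- as.numeric(u)
    cg <- cable_geometry(model$exosuit, th)
    tens <- cable_tensions(A, cg$r1, cg$r2)
    if (k == 1) state$activations <- as.numeric(a_tgt)  # startup convention

    # record the frame at the current grid point
    theta[k] <- th; thetadot[k] <- thd
    tau[k] <- tau_k; assist_m[k] <- A; T1[k] <- tens[1]; T2[k] <- tens[2]
    tgt[k, ] <- a_tgt; exc[k, ] <- u; act[k, ] <- state$activations
    tau_mus <- 0
    for (i in 1:6) {
      st <- evaluate_geometry(muscles[[i]], th, thd,
                              activation = state$activations[i])
      force[k, i] <- muscle_force(muscles[[i]], st)
      nfl[k, i] <- st$norm_fiber_length
      fvel[k, i] <- st$fiber_velocity
      tau_mus <- tau_mus + st$moment_arm * force[k, i]
    }
    tau_cable <- cg$r1 * tens[1] - cg$r2 * tens[2]
    thetaddot[k] <- (tau_mus + tau_cable - gravity_moment(model, th)) / I
    inter <- interaction_forces(model$exosuit, th, tens[1], tens[2])
    fnorm[k] <- inter$normal; fshear[k] <- inter$shear
    jr <- joint_reaction(model,
                         list(theta = th, thetadot = thd,
                              thetaddot = thetaddot[k]),
                         force[k, ], inter$force)
    rx[k] <- jr$fx; ry[k] <- jr$fy; rmag[k] <- jr$magnitude

    if (k < n) {
      state <- tryCatch(
        forward_step(model, state,
                     list(excitations = u, T1 = tens[1], T2 = tens[2]),
                     dt[k], settings),
        error = function(e) stop("at step ", k, " (t = ", signif(t[k], 4),
                                 " s): ", conditionMessage(e), call. = FALSE))
    }
    a_prev <- a_tgt
  }

  met <- metabolic_rate(model, t, exc, act, nfl, fvel, force)
  series <- data.frame(
    time = t, theta = theta, thetadot = thetadot, thetaddot = thetaddot,
    theta_ref = trajectory$theta_des, tau = tau, assist_moment = assist_m,
    T1 = T1, T2 = T2, reserve_moment = reserve,
    reaction_fx = rx, reaction_fy = ry, reaction = rmag,
    strap_normal = fnorm, strap_shear = fshear,
    metabolic_rate = met$rates$total_rate
  )
  structure(list(
    series = series, activations = act, excitations = exc,
    target_activations = tgt, muscle_forces = force,
    norm_fiber_lengths = nfl, fiber_velocities = fvel,
    metabolics = met, model = model, trajectory = trajectory, gains = gains,
    assist = assist, settings = settings, label = label,
    diagnostics = list(excitation_clamp_events = clamp_events,
                       max_reserve_moment = max(abs(reserve)))
  ), class = "exosim_result")
}

#' Run a factorial sweep of simulations
#'
#' @param specs nonempty list of run specifications, each a list with
#'   elements `model`, `trajectory`, and optionally `gains`, `assist`,
#'   `settings`, `label`.  Labels must be unique.
#' @return list of [simulate_flexion()] results (or error conditions for
#'   failed cells, marked in the `failed` attribute), named by label.
#' @export
run_sweep <- function(specs) {
  if (length(specs) == 0) stop("empty sweep", call. = FALSE)
  labels <- vapply(seq_along(specs), function(i) {
    if (is.null(specs[[i]]$label) || !nzchar(specs[[i]]$label))
      paste0("run", i) else specs[[i]]$label
  }, character(1))
  if (anyDuplicated(labels))
    stop("sweep labels must be unique", call. = FALSE)
  out <- vector("list", length(specs))
  failed <- logical(length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    out[[i]] <- tryCatch(
      simulate_flexion(s$model, s$trajectory,
                       gains = s$gains %||% pd_gains(),
                       assist = isTRUE(s$assist),
                       settings = s$settings %||% sim_settings(),
                       label = labels[i]),
      error = function(e) { e })
    failed[i] <- inherits(out[[i]], "error")
  }
  names(out) <- labels
  attr(out, "failed") <- labels[failed]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specifications for the study's 2 x 3 x 2 task design
#'
#' Two movement durations (1 s fast, 2 s slow), three hand loads (0, 2, 5 kg)
#' and assist OFF/ON: twelve runs.
#'
#' @param durations movement times (s).
#' @param loads external masses (kg).
#' @param load_distance elbow-to-load distance (m).
#' @param sample_rate grid rate (Hz).
#' @return list of run specifications for [run_sweep()].
#' @export
task_sweep_specs <- function(durations = c(1, 2), loads = c(0, 2, 5),
                             load_distance = 0.35, sample_rate = 121) {
  specs <- list()
  for (dur in durations) for (load in loads) for (assist in c(FALSE, TRUE)) {
    specs[[length(specs) + 1L]] <- list(
      model = default_model(external_mass = load, load_distance = load_distance),
      trajectory = make_min_jerk(0, pi / 2, dur, sample_rate),
      assist = assist,
      label = sprintf("%s_%gkg_%s", if (dur <= min(durations)) "fast" else "slow",
                      load, if (assist) "on" else "off"))
  }
  specs
}

#' Assistance summary metrics for a matched run pair
#'
#' RMS values per channel over the task window and the headline percent
#' reductions (assisted vs unassisted): mean biceps-group activation,
#' net joint moment, elbow reaction force and total metabolic rate, plus the
#' peak strap interaction forces of the assisted run.  The biceps group
#' defaults to the three elbow flexors; the two-headed biceps-only grouping is
#' reported alongside.
#'
#' @param off,on [simulate_flexion()] results differing only in the assist
#'   flag.
#' @param biceps_group muscle names averaged as "the biceps muscles".
#' @return an object of class `exosim_summary`.
#' @export
summarize_assistance <- function(off, on,
                                 biceps_group = c("biceps_long", "biceps_short",
                                                  "brachialis")) {
  if (!identical(off$series$time, on$series$time))
    stop("mismatched time grids between runs", call. = FALSE)
  if (isTRUE(off$assist) || !isTRUE(on$assist))
    stop("expected `off` unassisted and `on` assisted", call. = FALSE)
  pct <- function(roff, ron) 100 * (roff - ron) / roff
  group_rms <- function(res, group)
    mean(vapply(group, function(g) rms(res$activations[, g]), numeric(1)))
  tri <- c("triceps_long", "triceps_medial", "triceps_lateral")
  metrics <- list(
    biceps_rms_off = group_rms(off, biceps_group),
    biceps_rms_on = group_rms(on, biceps_group),
    biceps2_rms_off = group_rms(off, c("biceps_long", "biceps_short")),
    biceps2_rms_on = group_rms(on, c("biceps_long", "biceps_short")),
    triceps_rms_off = group_rms(off, tri),
    triceps_rms_on = group_rms(on, tri),
    moment_rms_off = rms(off$series$tau),
    moment_rms_on = rms(on$series$tau),
    reaction_rms_off = rms(off$series$reaction),
    reaction_rms_on = rms(on$series$reaction),
    metabolic_rms_off = rms(off$series$metabolic_rate),
    metabolic_rms_on = rms(on$series$metabolic_rate),
    peak_normal = max(on$series$strap_normal),
    peak_shear = max(on$series$strap_shear)
  )
  metrics$biceps_reduction <- pct(metrics$biceps_rms_off, metrics$biceps_rms_on)
  metrics$biceps2_reduction <- pct(metrics$biceps2_rms_off, metrics$biceps2_rms_on)
  metrics$moment_reduction <- pct(metrics$moment_rms_off, metrics$moment_rms_on)
  metrics$reaction_reduction <- pct(metrics$reaction_rms_off,
                                    metrics$reaction_rms_on)
  metrics$metabolic_reduction <- pct(metrics$metabolic_rms_off,
                                     metrics$metabolic_rms_on)
  metrics$labels <- c(off = off$label, on = on$label)
  structure(metrics, class = "exosim_summary")
}

#' @export
print.exosim_summary <- function(x, ...) {
  cat("<exosim_summary>", x$labels["off"], "vs", x$labels["on"], "\n")
  cat(sprintf("  biceps-group activation RMS: %.4f -> %.4f  (-%.1f%%)\n",
              x$biceps_rms_off, x$biceps_rms_on, x$biceps_reduction))
  cat(sprintf("  joint moment RMS [N m]:      %.3f -> %.3f  (-%.1f%%)\n",
              x$moment_rms_off, x$moment_rms_on, x$moment_reduction))
  cat(sprintf("  reaction force RMS [N]:      %.2f -> %.2f  (-%.1f%%)\n",
              x$reaction_rms_off, x$reaction_rms_on, x$reaction_reduction))
  cat(sprintf("  metabolic rate RMS [W]:      %.2f -> %.2f  (-%.1f%%)\n",
              x$metabolic_rms_off, x$metabolic_rms_on, x$metabolic_reduction))
  cat(sprintf("  strap peaks (assisted): normal %.1f N, shear %.1f N\n",
              x$peak_normal, x$peak_shear))
  invisible(x)
}
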