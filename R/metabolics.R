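# Muscle energetics: whole-task metabolic rate, Umberger-family model.
#
# Total rate = basal + activation + maintenance + shortening/lengthening +
# mechanical work, summed over the six modeled muscles.  Coefficients follow
# the Umberger-2003 parameterization: activation+maintenance heat
# (128 FT + 25) W/kg scaled by A^0.6, shortening heat proportional to
# normalized fiber velocity with slow/fast-twitch coefficients, lengthening
# heat with coefficient 4 alpha_ST and first-power activation dependence, an
# aerobic scale S = 1.5, and a 1 W/kg lower bound on total heat rate.  The
# (128 FT + 25) term is attributed 40% to activation heat and 60% (the
# length-scaled share) to maintenance heat for reporting; `merged = TRUE`
# reports the two as one activation term.

UMBERGER_DENSITY <- 1059.7   # kg/m^3
SPECIFIC_TENSION <- 0.25e6   # Pa

#' Muscle mass from architecture
#'
#' \eqn{m = \rho F_m l_{opt} / \sigma} with muscle density
#' 1059.7 kg/m^3 and specific tension 0.25 MPa.
#'
#' @param params a [muscle_params()].
#' @param density,specific_tension override the standard constants.
#' @return mass (kg).
#' @export
muscle_mass <- function(params, density = UMBERGER_DENSITY,
                        specific_tension = SPECIFIC_TENSION) {
  density * params$max_isometric_force * params$optimal_fiber_length /
    specific_tension
}

#' Metabolic rate time series
#'
#' Computes the per-muscle and summed energetic rates for aligned time series
#' of excitation, activation, fiber kinematics and fiber force.  The
#' bookkeeping identity `total = basal + activation + maintenance +
#' shortening + work` holds exactly at every sample.
#'
#' @param model an [arm_model()].
#' @param times sample times (s).
#' @param excitations,activations n-by-6 matrices in [0, 1].
#' @param norm_fiber_lengths n-by-6 matrix of fiber length / optimal length.
#' @param fiber_velocities n-by-6 matrix (m/s, shortening negative).
#' @param fiber_forces n-by-6 matrix of muscle forces (N).
#' @param basal_rate_per_kg basal rate (W per kg muscle mass), default 1.2.
#' @param merged report activation and maintenance heat as one activation
#'   term (the simpler probe variant).
#' @param allow_negative_work keep negative (absorbed) mechanical work rates;
#'   by default lengthening work is clamped to zero at the muscle level.
#' @param aerobic_scale Umberger S factor, default 1.5.
#' @return object of class `metabolic_breakdown`: a list with the summed
#'   `rates` data frame (columns `time`, `basal_rate`, `activation_rate`,
#'   `maintenance_rate`, `shortening_rate`, `work_rate`, `total_rate`, W) and
#'   the n-by-6 `per_muscle` total-rate matrix.
#' @export
metabolic_rate <- function(model, times, excitations, activations,
                           norm_fiber_lengths, fiber_velocities, fiber_forces,
                           basal_rate_per_kg = 1.2, merged = FALSE,
                           allow_negative_work = FALSE, aerobic_scale = 1.5) {
  n <- length(times)
  mats <- list(excitations, activations, norm_fiber_lengths,
               fiber_velocities, fiber_forces)
  if (any(vapply(mats, function(m) !all(dim(m) == c(n, 6L)), logical(1))))
    stop("metabolic_rate: misaligned series (need n-by-6 matrices matching times)",
         call. = FALSE)
  hA <- hM <- hS <- hW <- matrix(0, n, 6)
  mass <- vapply(model$muscles, muscle_mass, numeric(1))
  for (i in 1:6) {
    mus <- model$muscles[[i]]
    u <- excitations[, i]; a <- activations[, i]
    lt <- norm_fiber_lengths[, i]
    v_norm <- fiber_velocities[, i] / mus$optimal_fiber_length  # lopt/s
    A <- ifelse(u > a, u, (u + a) / 2)
    f_iso <- active_force_length(lt)
    ft <- mus$fast_twitch_fraction
    am_base <- (128 * ft + 25) * A^0.6 * aerobic_scale      # W/kg
    len_scale <- ifelse(lt > 1, f_iso, 1)
    act <- 0.4 * am_base
    mnt <- 0.6 * am_base * len_scale
    vmax_ft <- mus$max_contraction_velocity
    vmax_st <- vmax_ft / 2.5
    a_st <- 100 / vmax_st
    a_ft <- 153 / vmax_ft
    short <- ifelse(v_norm < 0,
                    -(a_st * (1 - ft) + a_ft * ft) * v_norm * A^2 *
                      aerobic_scale * len_scale,
                    4 * a_st * v_norm * A * aerobic_scale * len_scale)
    # enforce the 1 W/kg minimum total heat rate via the maintenance term
    heat <- act + mnt + short
    mnt <- mnt + pmax(1 - heat, 0)
    w <- -fiber_forces[, i] * fiber_velocities[, i]          # W, + shortening
    if (!allow_negative_work) w <- pmax(w, 0)
    hA[, i] <- act * mass[i]
    hM[, i] <- mnt * mass[i]
    hS[, i] <- short * mass[i]
    hW[, i] <- w
  }
  basal <- rep(basal_rate_per_kg * sum(mass), n)
  if (merged) { hA <- hA + hM; hM <- hM * 0 }
  per_muscle <- hA + hM + hS + hW + basal_rate_per_kg *
    matrix(mass, n, 6, byrow = TRUE)
  rates <- data.frame(
    time = times,
    basal_rate = basal,
    activation_rate = rowSums(hA),
    maintenance_rate = rowSums(hM),
    shortening_rate = rowSums(hS),
    work_rate = rowSums(hW)
  )
  rates$total_rate <- rates$basal_rate + rates$activation_rate +
    rates$maintenance_rate + rates$shortening_rate + rates$work_rate
  colnames(per_muscle) <- vapply(model$muscles, `[[`, character(1), "name")
  structure(list(rates = rates, per_muscle = per_muscle),
            class = "metabolic_breakdown")
}
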