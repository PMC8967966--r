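# Static optimization: per-instant muscle redundancy resolution.
#
# minimize    sum(a_i^2)  (+ w * rho^2 for the optional reserve moment rho)
# subject to  sum(d_i * cap_i * a_i) + sum(passive_i) + rho = tau_required
#             0 <= a_i <= 1
#
# With a separable quadratic objective and one linear equality, the KKT
# conditions give a_i = clamp(mu * c_i, 0, 1) and rho = mu * (1/w) up to a
# common multiplier mu; the delivered moment is continuous and nondecreasing
# in mu, so the exact solution is found by a monotone root solve on mu.  This
# replaces a generic interior-point iteration with the problem's closed-form
# structure; tests verify it against an independent projected-KKT derivation
# and a brute-force grid oracle.

#' Build the instantaneous redundancy problem
#'
#' Evaluates, at the current joint state, each muscle's signed moment arm,
#' active moment capacity (force at full activation with zero passive
#' contribution) and passive moment contribution.
#'
#' @param model an [arm_model()].
#' @param theta,thetadot joint state used for muscle kinematics.
#' @param required_moment net muscle moment demanded by inverse dynamics (N m).
#' @return an object of class `redundancy_problem` with vectors `moment_arm`,
#'   `active_capacity` (N), `passive_moment` (N m) and the scalar
#'   `required_moment`.
#' @export
build_problem <- function(model, theta, thetadot, required_moment) {
  n <- length(model$muscles)
  d <- cap <- pas <- numeric(n)
  for (i in seq_len(n)) {
    mus <- model$muscles[[i]]
    st <- evaluate_geometry(mus, theta, thetadot)
    fl <- active_force_length(st$norm_fiber_length)
    fv <- force_velocity(st$norm_fiber_velocity, activation = 1)
    fp <- passive_force_length(st$norm_fiber_length)
    d[i] <- st$moment_arm
    cap[i] <- mus$max_isometric_force * fl * fv * cos(st$pennation)
    pas[i] <- d[i] * mus$max_isometric_force * fp * cos(st$pennation)
  }
  structure(list(required_moment = required_moment, moment_arm = d,
                 active_capacity = cap, passive_moment = pas,
                 names = vapply(model$muscles, `[[`, character(1), "name")),
            class = "redundancy_problem")
}

#' Solve the activation-redundancy problem
#'
#' Returns the activation vector minimizing the summed squared activations
#' subject to the joint-moment equality and activation bounds.  When the
#' demanded moment exceeds the total muscle capacity and `reserve = TRUE`
#' (default), an idealized reserve actuator supplies the residual moment at a
#' quadratic penalty (weight 1000) and a warning records its use; with
#' `reserve = FALSE` an infeasible demand is an error reporting the moment
#' gap.
#'
#' @param problem a [build_problem()] result.
#' @param warm_start previous activation vector; accepted for interface
#'   stability (the solver is exact and deterministic, so it does not need a
#'   starting point).
#' @param reserve logical, enable the reserve actuator.
#' @param reserve_weight quadratic penalty weight on the reserve moment.
#' @param tol moment-equality tolerance (N m).
#' @param quiet suppress the reserve warning (used inside the pipeline, which
#'   records reserve use in its diagnostics instead).
#' @return numeric activation 6-vector with attributes `reserve_moment` (N m)
#'   and `achieved_moment` (N m).
#' @export
solve_redundancy <- function(problem, warm_start = NULL, reserve = TRUE,
                             reserve_weight = 1000, tol = 1e-6, quiet = FALSE) {
  c_vec <- problem$moment_arm * problem$active_capacity
  target <- problem$required_moment - sum(problem$passive_moment)
  deliver <- function(mu) {
    a <- pmin(pmax(mu * c_vec, 0), 1)
    sum(c_vec * a) + if (reserve) mu / reserve_weight else 0
  }
  m_max <- sum(c_vec[c_vec > 0])
  m_min <- sum(c_vec[c_vec < 0])
  if (!reserve && (target > m_max + tol || target < m_min - tol)) {
    gap <- if (target > m_max) target - m_max else target - m_min
    stop(sprintf(
      "static optimization infeasible: moment gap %.4g N m (demand %.4g, achievable [%.4g, %.4g])",
      gap, target, m_min, m_max), call. = FALSE)
  }
  if (!reserve) target <- min(max(target, m_min), m_max)
  if (all(c_vec == 0) && !reserve) {
    if (abs(target) > tol)
      stop("static optimization infeasible: all moment capacities are zero",
           call. = FALSE)
    a <- numeric(length(c_vec))
    attr(a, "reserve_moment") <- 0
    attr(a, "achieved_moment") <- sum(problem$passive_moment)
    return(a)
  }
  # bracket the monotone multiplier: beyond |mu| = 1/min|c| every bound is
  # active; the reserve term then grows linearly, so doubling always brackets
  nz <- abs(c_vec[c_vec != 0])
  b0 <- if (length(nz)) 1 / min(nz) else 1
  grow <- function(mu_bound, dir) {
    k <- 0
    while (dir * (deliver(mu_bound) - target) < 0 && k < 200) {
      mu_bound <- mu_bound * 2
      k <- k + 1
    }
    mu_bound
  }
  hi_mu <- grow(max(b0, 1), +1)
  lo_mu <- grow(-max(b0, 1), -1)
  root <- stats::uniroot(function(mu) deliver(mu) - target,
                         lower = lo_mu, upper = hi_mu,
                         tol = .Machine$double.eps^0.75, maxiter = 2000)
  mu <- root$root
  a <- pmin(pmax(mu * c_vec, 0), 1)
  res <- if (reserve) mu / reserve_weight else 0
  achieved <- sum(c_vec * a) + sum(problem$passive_moment)
  if (abs(achieved + res - problem$required_moment) > max(tol, 1e-6))
    warning(sprintf("moment equality met to %.3g N m only",
                    abs(achieved + res - problem$required_moment)))
  if (reserve && abs(res) > tol && !quiet)
    warning(sprintf("reserve actuator engaged: %.4g N m residual moment", res))
  names(a) <- problem$names
  attr(a, "reserve_moment") <- res
  attr(a, "achieved_moment") <- achieved
  a
}
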