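test_that("inertia about the elbow combines forearm and point-load terms", {
  expect_equal(mass_about_elbow(default_model(0)), 0.02)
  expect_equal(mass_about_elbow(default_model(2)), 0.02 + 2 * 0.35^2)
  expect_equal(mass_about_elbow(default_model(0, load_distance = 0.29)), 0.02)
})

test_that("gravity moment reproduces direct evaluations", {
  m0 <- default_model(0); m2 <- default_model(2)
  expect_equal(gravity_moment(m0, 0), 0)
  expect_equal(gravity_moment(m2, pi / 2), 1.53 * 9.81 * 0.18 + 2 * 9.81 * 0.35)
  expect_equal(gravity_moment(m0, pi / 2), 1.53 * 9.81 * 0.18)
})

test_that("inverse dynamics reduces to statics and pure inertia in limit cases", {
  m <- default_model(0)
  hold <- list(theta = 0.7, thetadot = 0, thetaddot = 0)
  fb <- list(theta = 0.7, thetadot = 0)
  expect_equal(as.numeric(inverse_dynamics_moment(m, hold, fb)),
               gravity_moment(m, 0.7))
  expect_equal(as.numeric(inverse_dynamics_moment(m, hold, fb,
                                                  assist_moment = gravity_moment(m, 0.7))),
               0)
  m$gravity <- 0
  acc <- list(theta = 0.7, thetadot = 0, thetaddot = 1)
  expect_equal(as.numeric(inverse_dynamics_moment(m, acc, fb)), 0.02)
})

test_that("forward step respects equilibria and the sign of gravity", {
  m <- default_model(0)
  m0g <- m; m0g$gravity <- 0
  rest <- list(theta = 0.5, thetadot = 0, activations = rep(0, 6))
  ctrl <- list(excitations = rep(0, 6), T1 = 0, T2 = 0)
  nxt <- forward_step(m0g, rest, ctrl, 0.01, include_muscle_forces = FALSE)
  expect_equal(nxt$theta, 0.5, tolerance = 1e-10)
  expect_equal(nxt$thetadot, 0, tolerance = 1e-10)
  # with gravity the bare pendulum falls toward extension
  start <- list(theta = 0.1, thetadot = 0, activations = rep(0, 6))
  nxt <- forward_step(m, start, ctrl, 0.01, include_muscle_forces = FALSE)
  expect_lt(nxt$thetadot, 0)
  # soft stop aborts with diagnostics
  expect_error(forward_step(m, list(theta = 1.99, thetadot = 10,
                                    activations = rep(0, 6)),
                            ctrl, 0.05, include_muscle_forces = FALSE),
               "soft joint stop")
})

test_that("integrated activation trace matches a dense-Euler oracle", {
  m <- default_model(0)
  m$gravity <- 0
  st <- list(theta = 0.5, thetadot = 0, activations = rep(0, 6))
  ctrl <- list(excitations = rep(0.5, 6), T1 = 0, T2 = 0)
  for (i in 1:10)
    st <- forward_step(m, st, ctrl, 0.005, include_muscle_forces = FALSE)
  ref <- euler_activation(0, 0.5, 0.010, 0.040, 0.05)
  expect_equal(st$activations, rep(ref, 6), tolerance = 1e-4)
})

test_that("free-swing mechanical energy is conserved by the integrator", {
  m <- default_model(0)
  energy <- function(s) 0.5 * mass_about_elbow(m) * s$thetadot^2 -
    m$segment$forearm_mass * m$gravity * m$segment$com_distance * cos(s$theta)
  st <- list(theta = 0.19, thetadot = 0, activations = rep(0, 6))
  e0 <- energy(st)
  ctrl <- list(excitations = rep(0, 6), T1 = 0, T2 = 0)
  for (i in 1:120)
    st <- forward_step(m, st, ctrl, 1 / 120, include_muscle_forces = FALSE)
  expect_lt(abs(energy(st) - e0) / abs(e0), 0.001)
})

test_that("joint reaction force balances weight, muscles and cable", {
  m <- default_model(0)
  # no gravity, no forces, at rest
  m0g <- m; m0g$gravity <- 0
  jr <- joint_reaction(m0g, list(theta = 0.3, thetadot = 0, thetaddot = 0),
                       rep(0, 6))
  expect_equal(jr$magnitude, 0)
  # static hang transmits the full weight through the joint
  m5 <- default_model(5)
  jr <- joint_reaction(m5, list(theta = 0, thetadot = 0, thetaddot = 0),
                       rep(0, 6))
  expect_equal(jr$magnitude, (1.53 + 5) * 9.81)
  expect_equal(jr$fy, (1.53 + 5) * 9.81)   # upward support
  # a gravity-compensating cable lowers the static reaction vs muscles alone
  th <- pi / 2
  tau_d <- gravity_moment(m5, th)
  prob <- build_problem(m5, th, 0, tau_d)
  a <- solve_redundancy(prob, quiet = TRUE)
  f_mus <- a * prob$active_capacity +
    vapply(seq_len(6), function(i) {
      mus <- m5$muscles[[i]]
      st <- evaluate_geometry(mus, th, 0)
      mus$max_isometric_force * passive_force_length(st$norm_fiber_length) *
        cos(st$pennation)
    }, numeric(1))
  r_unassisted <- joint_reaction(m5, list(theta = th, thetadot = 0,
                                          thetaddot = 0), f_mus)
  cg <- cable_geometry(m5$exosuit, th)
  tens <- cable_tensions(tau_d, cg$r1, cg$r2)
  inter <- interaction_forces(m5$exosuit, th, tens[1], tens[2])
  prob_on <- build_problem(m5, th, 0, 0)
  a_on <- solve_redundancy(prob_on, quiet = TRUE)
  f_on <- a_on * prob_on$active_capacity +
    vapply(seq_len(6), function(i) {
      mus <- m5$muscles[[i]]
      st <- evaluate_geometry(mus, th, 0)
      mus$max_isometric_force * passive_force_length(st$norm_fiber_length) *
        cos(st$pennation)
    }, numeric(1))
  r_assisted <- joint_reaction(m5, list(theta = th, thetadot = 0,
                                        thetaddot = 0), f_on, inter$force)
  expect_lt(r_assisted$magnitude, r_unassisted$magnitude)
})

test_that("closed-loop tracking error stays small without assistance", {
  # robustness of the loop across both speeds and all loads
  for (dur in c(1, 2)) for (load in c(0, 2, 5)) {
    res <- simulate_flexion(default_model(load), make_min_jerk(0, pi / 2, dur),
                            assist = FALSE)
    expect_lt(max(abs(residuals(res))), 0.05)
  }
})
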