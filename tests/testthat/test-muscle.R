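fixture <- default_muscle_fixture()
flexor <- fixture[[1]]                       # biceps long head
extensor <- fixture[[4]]                     # triceps long head

test_that("force multiplier curves have the documented values and shapes", {
  expect_equal(active_force_length(1), 1)
  expect_equal(active_force_length(0.5), active_force_length(1.5))
  expect_equal(active_force_length(1.3), exp(-0.2))
  expect_equal(force_velocity(0), 1)
  expect_equal(force_velocity(-1), 0)
  v <- seq(-1, 1, length.out = 200)
  expect_true(all(diff(force_velocity(v)) >= 0))   # monotone nondecreasing
  expect_lt(force_velocity(5), 1.4)                # below eccentric plateau
  expect_equal(passive_force_length(0.8), 0)
  l <- seq(1.0, 1.6, length.out = 100)
  expect_true(all(diff(passive_force_length(l)) > 0))
  expect_lt(passive_force_length(1 + 1e-9), 1e-7)  # continuous at slack
})

test_that("Hill force law reproduces direct evaluations and stays nonnegative", {
  mk_state <- function(lt, vt, a, phi = 0) {
    structure(list(norm_fiber_length = lt, norm_fiber_velocity = vt,
                   activation = a, pennation = phi), class = "muscle_state")
  }
  m <- muscle_params("biceps_long", 1, 1000, 0.1, 0.2,
                     moment_arm_coeffs = c(0.03), mtu_length_coeffs = c(0.3, -0.03))
  expect_equal(muscle_force(m, mk_state(1, 0, 0)), 0)
  expect_equal(muscle_force(m, mk_state(1, 0, 1)), 1000)
  expect_equal(muscle_force(m, mk_state(1, 0, 0.5)), 500)
  # random admissible states: force never negative
  set.seed(11)
  for (i in 1:100) {
    st <- mk_state(runif(1, 0.5, 1.6), runif(1, -1.2, 1.2), runif(1),
                   runif(1, 0, 0.4))
    expect_gte(muscle_force(m, st), 0)
  }
})

test_that("geometry evaluation is consistent with the length polynomials", {
  st0 <- evaluate_geometry(flexor, pi / 4, 0)
  expect_equal(st0$fiber_velocity, 0)
  # flexors shorten with flexion
  expect_lt(evaluate_geometry(flexor, pi / 2)$fiber_length,
            evaluate_geometry(flexor, 0)$fiber_length)
  # extensors stretch with flexion
  expect_gt(evaluate_geometry(extensor, pi / 2)$fiber_length,
            evaluate_geometry(extensor, 0)$fiber_length)
  # moment arm equals -sign * d(mtu)/dtheta numerically, every muscle
  th <- seq(0.01, pi / 2 - 0.01, length.out = 50)
  for (m in fixture) {
    num <- vapply(th, function(x)
      (evaluate_geometry(m, x + 1e-6)$mtu_length -
         evaluate_geometry(m, x - 1e-6)$mtu_length) / 2e-6, numeric(1))
    ma <- vapply(th, function(x) evaluate_geometry(m, x)$moment_arm, numeric(1))
    expect_lt(max(abs(num + m$sign * abs(ma))), 1e-4)
  }
  # out-of-range angles clamp and flag
  expect_true(evaluate_geometry(flexor, 2.5)$clamped)
  expect_false(evaluate_geometry(flexor, 1.0)$clamped)
})

test_that("activation dynamics match direct evaluation of the two-branch law", {
  m <- flexor  # kact = 0.010, kdeact = 0.040
  expect_equal(activation_derivative(0.4, 0.4, m), 0)
  expect_equal(activation_derivative(0, 1, m), 1 / (0.010 * 0.5))   # 200 /s
  expect_equal(activation_derivative(1, 0, m), -1 / (0.040 / 2.0))  # -50 /s
  expect_error(activation_derivative(1.4, 0.5, m), "0, 1")
})

test_that("excitation inversion round-trips the activation rate", {
  m <- flexor
  expect_equal(as.numeric(excitation_from_activation(0.3, 0, m)), 0.3)
  expect_equal(as.numeric(excitation_from_activation(0.9, 1e5, m)), 1)
  set.seed(42)
  for (i in 1:100) {
    a <- runif(1, 0.05, 0.95)
    d <- runif(1, -30, 30)
    u <- excitation_from_activation(a, d, m)
    if (!isTRUE(attr(u, "clamped")))
      expect_equal(activation_derivative(a, as.numeric(u), m), d,
                   tolerance = 1e-9)
  }
})

test_that("activation stays inside [0,1] under bounded excitation (forward invariance)", {
  m <- flexor
  for (start in c(0, 1)) for (u in c(0, 1)) {
    a <- start
    dt <- 1e-4
    for (i in 1:2000) a <- a + dt * activation_derivative(a, u, m)
    expect_gte(a, 0); expect_lte(a, 1)
  }
  # activation (u=1 from 0) is faster than deactivation (u=0 from 1)
  rise <- euler_activation(0, 1, 0.010, 0.040, 0.05)
  fall <- euler_activation(1, 0, 0.010, 0.040, 0.05)
  expect_gt(rise, 1 - fall)
})
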