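test_that("problem capacities agree with the Hill force law at full activation", {
  m <- default_model(2)
  prob <- build_problem(m, 0.6, 0.8, 3)
  for (i in seq_len(6)) {
    mus <- m$muscles[[i]]
    st <- evaluate_geometry(mus, 0.6, 0.8, activation = 1)
    # independent route: Hill force with a = 1 and passive removed
    f_full <- muscle_force(mus, st)
    f_pass <- mus$max_isometric_force *
      passive_force_length(st$norm_fiber_length) * cos(st$pennation)
    expect_equal(prob$active_capacity[i], f_full - f_pass, tolerance = 1e-10)
    expect_equal(prob$passive_moment[i], st$moment_arm * f_pass,
                 tolerance = 1e-10)
    expect_equal(prob$moment_arm[i], st$moment_arm)
  }
  # below-slack fibers contribute no passive moment
  flexed <- build_problem(m, 1.4, 0, 1)
  expect_equal(flexed$passive_moment[1:3], rep(0, 3))
})

make_problem <- function(c_vec, tau, passive = rep(0, length(c_vec))) {
  structure(list(required_moment = tau, moment_arm = sign(c_vec),
                 active_capacity = abs(c_vec), passive_moment = passive,
                 names = paste0("m", seq_along(c_vec))),
            class = "redundancy_problem")
}

test_that("identical agonists share the demand equally", {
  prob <- make_problem(c(10, 10, 0, 0, 0, 0), tau = 10)
  a <- solve_redundancy(prob, reserve = FALSE, quiet = TRUE)
  expect_equal(as.numeric(a[1:2]), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(as.numeric(a[3:6]), rep(0, 4))
})

test_that("a demand met by passive moments alone needs no activation", {
  prob <- make_problem(c(10, 8, -6, 0, 0, 0), tau = 1.5,
                       passive = c(1, 0.5, 0, 0, 0, 0))
  a <- solve_redundancy(prob, quiet = TRUE)
  expect_equal(as.numeric(a), rep(0, 6), tolerance = 1e-9)
})

test_that("antagonists stay silent when agonists suffice", {
  set.seed(7)
  for (i in 1:20) {
    c_vec <- c(runif(3, 5, 30), -runif(3, 5, 30))
    tau <- runif(1, 0, 0.8 * sum(c_vec[1:3]))
    a <- solve_redundancy(make_problem(c_vec, tau), quiet = TRUE)
    expect_equal(as.numeric(a[4:6]), rep(0, 3))
  }
})

test_that("solutions match the projected-KKT closed form on interior problems", {
  set.seed(19)
  for (i in 1:50) {
    c_vec <- c(runif(3, 5, 40), -runif(3, 5, 40))
    # keep the interior: modest demand, no bound becomes active
    tau <- runif(1, 0.01, 0.3) * sum(c_vec[c_vec > 0]^2) / max(c_vec)
    a <- solve_redundancy(make_problem(c_vec, tau), reserve = FALSE,
                          quiet = TRUE)
    oracle <- kkt_interior(c_vec, tau)
    expect_equal(as.numeric(a), oracle, tolerance = 1e-8)
    expect_equal(sum(abs(a)^2), sum(oracle^2), tolerance = 1e-6)
    # moment equality satisfied
    expect_equal(sum(c_vec * a), tau, tolerance = 1e-6)
  }
})

test_that("solutions are optimal against a brute-force grid oracle", {
  set.seed(23)
  for (i in 1:2) {
    c_vec <- c(runif(3, 2, 8), -runif(3, 2, 8))
    tau <- runif(1, 0.5, 0.9) * sum(c_vec[c_vec > 0])
    a <- solve_redundancy(make_problem(c_vec, tau), reserve = FALSE,
                          quiet = TRUE)
    step <- 0.1
    best_grid <- grid_search_objective(c_vec, tau, step = step)
    # the grid candidates are exactly feasible, so the solver optimum can be
    # no worse, and must approach the grid minimum from below
    expect_lte(sum(a^2), best_grid + 1e-9)
    expect_gte(sum(a^2), best_grid - 6 * step^2)
    expect_equal(sum(c_vec * a), tau, tolerance = 1e-6)
  }
})

test_that("the solution varies continuously with the demanded moment", {
  c_vec <- c(20, 15, 10, -18, -12, -9)
  base <- solve_redundancy(make_problem(c_vec, 5), quiet = TRUE)
  for (eps in c(1e-4, 1e-3, 1e-2)) {
    pert <- solve_redundancy(make_problem(c_vec, 5 + eps), quiet = TRUE)
    expect_lt(max(abs(pert - base)), 10 * eps)
  }
})

test_that("infeasible demands engage the reserve or error with the moment gap", {
  prob <- make_problem(c(5, 4, 3, -2, -2, -2), tau = 50)
  expect_error(solve_redundancy(prob, reserve = FALSE), "moment gap")
  expect_warning(a <- solve_redundancy(prob, reserve = TRUE), "reserve")
  expect_equal(as.numeric(a[1:3]), c(1, 1, 1))
  expect_equal(attr(a, "achieved_moment") + attr(a, "reserve_moment"), 50,
               tolerance = 1e-6)
})

test_that("solving is deterministic regardless of warm start", {
  prob <- make_problem(c(12, 9, 7, -10, -8, -6), tau = 7)
  a1 <- solve_redundancy(prob, quiet = TRUE)
  a2 <- solve_redundancy(prob, warm_start = runif(6), quiet = TRUE)
  expect_identical(as.numeric(a1), as.numeric(a2))
})
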