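# Independent oracles used by the unit and property tests.  These never call
# the code paths they are checking.

# trapezoidal quadrature
trapz <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

# central finite differences on a uniform grid (endpoints one-sided)
fd_deriv <- function(t, y) {
  n <- length(t)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  d
}

# dense explicit-Euler integration of the activation ODE (independent of the
# package's adaptive integrator)
euler_activation <- function(a0, u, kact, kdeact, t_end, dt = 1e-5) {
  a <- a0
  for (i in seq_len(round(t_end / dt))) {
    kappa <- if (u > a) kact * (0.5 + 1.5 * a) else kdeact / (0.5 + 1.5 * a)
    a <- a + dt * (u - a) / kappa
  }
  a
}

# closed-form interior KKT solution of min sum(a^2) s.t. sum(c a) = tau,
# a >= 0: the positive-capacity muscles share the load proportionally to c
kkt_interior <- function(c_vec, tau) {
  pos <- c_vec > 0
  a <- numeric(length(c_vec))
  a[pos] <- tau * c_vec[pos] / sum(c_vec[pos]^2)
  a
}

# brute-force search: grid the last five activations, solve the first
# coordinate exactly from the moment equality, keep candidates inside the box;
# returns the smallest objective over these exactly-feasible points
grid_search_objective <- function(c_vec, tau, step = 0.1) {
  stopifnot(c_vec[1] != 0)
  grid <- seq(0, 1, by = step)
  G <- as.matrix(expand.grid(rep(list(grid), length(c_vec) - 1)))
  a1 <- (tau - as.numeric(G %*% c_vec[-1])) / c_vec[1]
  ok <- a1 >= 0 & a1 <= 1
  if (!any(ok)) return(Inf)
  min(a1[ok]^2 + rowSums(G[ok, , drop = FALSE]^2))
}

# local Horner evaluation so fixture checks do not reuse package internals
polyval_oracle <- function(coeffs, x)
  sum(coeffs * x^(seq_along(coeffs) - 1))
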