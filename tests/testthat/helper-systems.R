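# Small factory systems shared across test files. All are fast to build
# (< 1 s) and sized for unit tests, not for physics production.

# a small confined chain + envelope
tiny_params <- function(n_m = 60, n_v = 80, R = 6, seed = 7, ...) {
  sim_params(N_m = n_m, N_v = n_v, R = R, k_bend_max = 10, seed = seed, ...)
}

tiny_state <- function(...) {
  system_state(tiny_params(...))
}

# numerical gradient of the configurational energy along one coordinate
num_grad <- function(state, particle, coord, h = 1e-6) {
  up <- state
  up$pos[particle, coord] <- up$pos[particle, coord] + h
  dn <- state
  dn$pos[particle, coord] <- dn$pos[particle, coord] - h
  (total_forces(up)$potential - total_forces(dn)$potential) / (2 * h)
}

# random rotation matrix (uniform via QR of gaussian matrix)
random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

expect_close <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
    label = sprintf(
      "%s within %g of %s", deparse(substitute(object)), tol,
      deparse(substitute(expected))
    )
  )
}

# positions of a discrete worm-like chain drawn from the Boltzmann
# bond-angle distribution p(cos) ~ exp(k cos) (inverse-CDF sampling);
# used both as an estimator oracle and as an equilibrium initialization
wlc_positions <- function(n, k, seed) {
  set.seed(seed)
  t <- matrix(0, n, 3)
  t[1, ] <- c(0, 0, 1)
  for (i in 2:n) {
    u <- runif(1)
    cosb <- log(exp(-k) + u * (exp(k) - exp(-k))) / k
    phi <- runif(1, 0, 2 * pi)
    sinb <- sqrt(max(0, 1 - cosb^2))
    e1 <- t[i - 1, ]
    a <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e2 <- a - sum(a * e1) * e1
    e2 <- e2 / sqrt(sum(e2^2))
    e3 <- c(
      e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
      e1[1] * e2[2] - e1[2] * e2[1]
    )
    t[i, ] <- cosb * e1 + sinb * (cos(phi) * e2 + sin(phi) * e3)
  }
  apply(rbind(c(0, 0, 0), t), 2, cumsum)
}
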