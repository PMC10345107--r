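# Integrator and neighbor-search contracts: NVE limit, equipartition,
# determinism, descent, and cell-list/brute-force equivalence.

test_that("neighbor search matches the brute-force oracle", {
  set.seed(5)
  pos <- matrix(runif(600, 0, 12), ncol = 3) # random 200-particle gas
  expect_identical(
    neighbor_pairs(pos, 1.7, "cell"),
    neighbor_pairs(pos, 1.7, "brute")
  )
  # collinear triplet at 0.9 cutoff spacing: only consecutive pairs
  tri <- cbind(c(0, 0.9, 1.8), 0, 0)
  expect_equal(
    neighbor_pairs(tri, 1.0),
    matrix(c(1L, 2L, 2L, 3L), 2, byrow = TRUE),
    ignore_attr = TRUE
  )
  expect_equal(nrow(neighbor_pairs(matrix(numeric(), 0, 3), 1)), 0)
})

test_that("cell-list and all-pairs force evaluation agree", {
  st <- tiny_state(n_m = 100, n_v = 100, R = 8)
  st$triplet_k[] <- 4
  fc <- total_forces(st, "cell")$forces
  fb <- total_forces(st, "brute")$forces
  expect_lt(max(abs(fc - fb)) / max(abs(fb)), 1e-10)
})

test_that("without friction or noise the integrator conserves energy", {
  # bonded chain in a large envelope, gamma = 0: velocity-Verlet limit.
  # dt is set so that even the stiffest (envelope) spring is integrated
  # far below its stability limit and the Verlet energy oscillation is
  # negligible against the drift tolerance.
  p <- sim_params(N_m = 12, N_v = 60, R = 25, seed = 3)
  st <- system_state(p)
  set.seed(4)
  st$vel[seq_len(12), ] <- matrix(rnorm(36, sd = 0.5), ncol = 3)
  energy <- function(s) total_forces(s)$potential + 0.5 * sum(s$vel^2)
  e0 <- energy(st)
  st2 <- md_run(st, 10000, dt = 5e-4, gamma = 0, kT = 0)
  expect_lt(abs(energy(st2) - e0) / abs(e0), 1e-4)
})

test_that("free particles thermalize to equipartition", {
  # monomers of distinct chains, no pair in range: an ideal gas
  p <- sim_params(N_m = 400, N_v = 60, R = 200, k_chrom = 15, seed = 1)
  st <- system_state(p)
  st$pos[seq_len(400), ] <- matrix(runif(1200, -60, 60), ncol = 3)
  st$chain_id <- seq_len(400L) # no bonds
  st <- md_run(st, 3000) # burn-in
  ke <- c()
  for (k in 1:10) {
    st <- md_run(st, 400)
    ke <- c(ke, 0.5 * sum(st$vel[seq_len(400), ]^2) / 400)
  }
  expect_equal(mean(ke), 1.5, tolerance = 0.02)
})

test_that("trajectories are exactly reproducible for the same seed", {
  st <- tiny_state(seed = 13)
  a <- md_run(st, 500)
  b <- md_run(st, 500)
  expect_identical(a$pos, b$pos)
  expect_identical(a$vel, b$vel)
  # and advance the stream between calls
  c2 <- md_run(a, 500)
  expect_false(identical(c2$pos, a$pos))
})

test_that("zero-temperature dynamics descends the potential energy", {
  st <- tiny_state(n_m = 80, n_v = 100, R = 8)
  pe <- total_forces(st)$potential
  for (k in 1:5) {
    st <- md_run(st, 400, kT = 0)
    pe2 <- total_forces(st)$potential
    expect_lte(pe2, pe + 1e-8 * abs(pe))
    pe <- pe2
  }
})

test_that("repulsive pair forces are equal, opposite and match the derivative", {
  p <- sim_params(N_m = 4, N_v = 60, R = 30, seed = 2)
  st <- system_state(p)
  st$chain_id <- c(1L, 1L, 2L, 3L)
  # non-bonded pair (3,4) at half overlap, everything else far away
  st$pos[seq_len(4), ] <- rbind(
    c(-5, 0, 0), c(-4, 0, 0), c(0.25, 0, 0), c(-0.25, 0, 0)
  )
  f <- total_forces(st)$forces
  expect_equal(f[3, ], -f[4, ])
  expect_equal(f[3, 1], soft_repulsion_force(0.5, eps_chrom = p$eps_chrom))
  # monomer-vertex pair beyond its cutoff feels nothing
  expect_lt(max(abs(f[1, ])), max(abs(f[2, 1])) + 1e-12) # bond only
})

test_that("the step-size guard rejects unstable timesteps", {
  st <- tiny_state()
  expect_error(md_run(st, 10, dt = 0.1), "stability")
})

test_that("chain crossing is possible but rare (topoisomerase emulation)", {
  # two threaded 24-bead rings; the finite soft barrier lets them unlink
  ring <- function(n, R, center, normal_axis) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    if (normal_axis == "z") {
      cbind(center[1] + R * cos(th), center[2] + R * sin(th), center[3])
    } else {
      cbind(center[1] + R * cos(th), center[2], center[3] + R * sin(th))
    }
  }
  n <- 24
  r_ring <- n / (2 * pi)
  p <- sim_params(N_m = 2 * n, N_v = 60, R = 60, seed = 5)
  st <- system_state(p)
  st$chain_id <- rep(c(1L, 2L), each = n)
  st$pos[seq_len(2 * n), ] <- rbind(
    ring(n, r_ring, c(0, 0, 0), "z"),
    ring(n, r_ring, c(r_ring, 0, 0), "x")
  )
  st$extra_bonds <- rbind(c(1L, n), c(n + 1L, 2L * n)) # close the rings
  linking_number <- function(a, b) {
    # discrete Gauss double sum over the two closed curves
    da <- rbind(diff(a), a[1, ] - a[nrow(a), ])
    db <- rbind(diff(b), b[1, ] - b[nrow(b), ])
    lk <- 0
    for (i in seq_len(nrow(a))) {
      r <- sweep(-b, 2, a[i, ], `+`)
      cr <- cbind(
        da[i, 2] * db[, 3] - da[i, 3] * db[, 2],
        da[i, 3] * db[, 1] - da[i, 1] * db[, 3],
        da[i, 1] * db[, 2] - da[i, 2] * db[, 1]
      )
      lk <- lk + sum(rowSums(r * cr) / pmax(rowSums(r^2)^(3 / 2), 1e-9))
    }
    lk / (4 * pi)
  }
  m0 <- monomer_positions(st)
  expect_equal(abs(linking_number(m0[1:n, ], m0[(n + 1):(2 * n), ])), 1,
    tolerance = 0.1
  )
  unlinked <- FALSE
  for (k in 1:40) {
    st <- md_run(st, 25000)
    m <- monomer_positions(st)
    lk <- linking_number(m[1:n, ], m[(n + 1):(2 * n), ])
    if (abs(lk) < 0.5) {
      unlinked <- TRUE
      break
    }
  }
  expect_true(unlinked)
})
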