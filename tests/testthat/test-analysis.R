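# Q-tensor stack, radial profiles and persistence-length estimation
# against closed-form oracles.

test_that("Q-tensor reproduces closed-form eigenvalue sets", {
  # perfect axial order
  q <- q_tensor_3d(matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE))
  expect_equal(sort(eigen(q)$values), c(-1 / 2, -1 / 2, 1), tolerance = 1e-12)
  expect_equal(sum(diag(q)), 0, tolerance = 1e-12)
  # half x, half y: planar-degenerate spectrum (-1/2, 1/4, 1/4)
  q2 <- q_tensor_3d(rbind(
    matrix(rep(c(1, 0, 0), 8), ncol = 3, byrow = TRUE),
    matrix(rep(c(0, 1, 0), 8), ncol = 3, byrow = TRUE)
  ))
  expect_equal(sort(eigen(q2)$values), c(-1 / 2, 1 / 4, 1 / 4),
    tolerance = 1e-12
  )
  expect_equal(alignment_from_q(q2), 0) # lambda3 = lambda2
  # head-tail symmetry
  b <- matrix(rnorm(30), ncol = 3)
  expect_equal(q_tensor_3d(b), q_tensor_3d(-b))
  # isotropy: eigenvalues shrink as O(n^-1/2)
  set.seed(8)
  for (n in c(500, 50000)) {
    g <- matrix(rnorm(3 * n), ncol = 3)
    ev <- eigen(q_tensor_3d(g))$values
    expect_lt(max(abs(ev)), 4 / sqrt(n))
  }
  expect_warning(q_tensor_3d(rbind(c(0, 0, 0), c(1, 0, 0))), "zero-length")
  expect_error(suppressWarnings(q_tensor_3d(matrix(0, 1, 3))), "non-zero")
})

test_that("alpha is rotation invariant and 1 for perfect order", {
  b <- matrix(rep(c(0.3, -0.4, 0.866), 20), ncol = 3, byrow = TRUE)
  expect_equal(alignment_from_q(q_tensor_3d(b)), 1, tolerance = 1e-9)
  set.seed(2)
  g <- matrix(rnorm(900), ncol = 3)
  a0 <- alignment_from_q(q_tensor_3d(g))
  a1 <- alignment_from_q(q_tensor_3d(g %*% random_rotation(3)))
  expect_equal(a0, a1, tolerance = 1e-10)
})

test_that("element-wise alpha equals the pooled closed form on one element", {
  set.seed(4)
  bonds <- matrix(rnorm(60), ncol = 3)
  bonds <- bonds / sqrt(rowSums(bonds^2))
  mid <- matrix(0.05 * rnorm(60), ncol = 3) # all in the central element
  prof <- local_alignment(bonds, mid = mid, R = 1, n_shells = 4,
                          n_sectors = 1)
  expect_equal(
    prof$alpha_r[1],
    alignment_from_q(q_tensor_3d(bonds)),
    tolerance = 1e-12
  )
  expect_true(all(is.na(prof$alpha_r[2:4]))) # empty shells are NA, not 0
})

test_that("local alignment is ~1 for an axial bundle and low for a coil", {
  bun <- make_axial_bundle(n_fibers = 16, length = 20, spacing = 1.5)
  cb <- diff(bun$positions)
  keep <- bun$chain_id[-length(bun$chain_id)] == bun$chain_id[-1]
  mid <- (bun$positions[-1, ] + bun$positions[-nrow(bun$positions), ]) / 2
  prof <- local_alignment(cb[keep, ], mid = mid[keep, ], R = 12, n_shells = 5)
  expect_gt(min(prof$alpha_r, na.rm = TRUE), 0.95)
  coil <- make_random_coil(3000, seed = 2)
  cbonds <- diff(coil$positions)
  cmid <- (coil$positions[-1, ] + coil$positions[-3000, ]) / 2
  ball <- bulk_surface_alignment(cbonds,
    mid = cmid, R = max(sqrt(rowSums(cmid^2))),
    center = colMeans(coil$positions)
  )
  expect_lt(ball$alpha_bulk, 0.1)
})

test_that("bulk/surface split follows the 0.85R threshold", {
  # axial bonds at two radii: both regions report perfect alignment
  bonds <- matrix(rep(c(0, 0, 1), 40), ncol = 3, byrow = TRUE)
  mid <- rbind(
    cbind(0.2, 0, seq(-0.5, 0.5, length.out = 20)),
    cbind(0.95, 0, seq(-0.5, 0.5, length.out = 20))
  )
  ba <- bulk_surface_alignment(bonds, mid = mid, R = 1)
  expect_equal(ba$alpha_bulk, 1, tolerance = 1e-9)
  expect_equal(ba$alpha_surface, 1, tolerance = 1e-9)
  expect_equal(ba$n_bulk, 20)
  expect_equal(ba$n_surface, 20)
  # empty region is NA
  ba2 <- bulk_surface_alignment(bonds[1:20, ], mid = mid[1:20, ], R = 1)
  expect_true(is.na(ba2$alpha_surface))
})

test_that("radial density counts per equal-volume shell and normalizes to 1", {
  set.seed(6)
  # uniform points in a ball: all bins ~1
  u <- matrix(rnorm(30000), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * runif(10000)^(1 / 3)
  prof <- radial_density(u, R = 1, n_shells = 8)
  expect_true(all(abs(prof$rho_r - 1) < 0.12))
  # counting identity: volume-weighted mean is exactly 1
  expect_equal(mean(prof$rho_r), 1, tolerance = 1e-12)
  # all mass in the outermost shell
  sh <- u / sqrt(rowSums(u^2)) * 0.999
  prof2 <- radial_density(sh, R = 1, n_shells = 5)
  expect_equal(prof2$rho_r, c(0, 0, 0, 0, 5), tolerance = 1e-12)
  expect_error(radial_density(u, R = 1, n_shells = 1), "n_shells")
})

test_that("persistence length estimation recovers the discrete WLC value", {
  # oracle: freely rotating discrete WLC sampled directly from the
  # Boltzmann bond-angle distribution, independent of the MD engine
  sample_wlc <- function(n, k, seed) {
    set.seed(seed)
    t <- matrix(0, n, 3)
    t[1, ] <- c(0, 0, 1)
    for (i in 2:n) {
      # p(cos) ~ exp(k cos): inverse-CDF sampling
      u <- runif(1)
      cosb <- log(exp(-k) + u * (exp(k) - exp(-k))) / k
      phi <- runif(1, 0, 2 * pi)
      sinb <- sqrt(max(0, 1 - cosb^2))
      # build frame around previous tangent
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
  k <- 10
  frames <- lapply(1:6, function(s) sample_wlc(400, k, s))
  est <- persistence_length_estimate(frames)
  l_theory <- -1 / log(1 / tanh(k) - 1 / k) # <cos> = coth(k) - 1/k
  expect_true(est$reliable)
  expect_equal(est$l_p, l_theory, tolerance = 0.1)
  # freely jointed limit: l_p below 1.5 bonds
  fj <- lapply(1:4, function(s) {
    set.seed(s)
    st <- matrix(rnorm(900), ncol = 3)
    apply(rbind(c(0, 0, 0), st / sqrt(rowSums(st^2))), 2, cumsum)
  })
  expect_lt(persistence_length_estimate(fj)$l_p, 1.5)
  # rigid rod: correlation ~1 everywhere, fit flagged unreliable
  rod <- cbind(0, 0, seq_len(120))
  est_rod <- persistence_length_estimate(rod)
  expect_false(est_rod$reliable)
  expect_true(all(est_rod$correlation$C > 0.99))
})
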