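# Envelope construction: sphere lattices, Delaunay-by-hull topology,
# rest-length geometry, pole selection and the stretch-force gradient.

test_that("sphere lattices put all vertices at radius R with small centroid", {
  for (n in c(4, 100, 1000)) {
    v <- make_sphere_vertices(n, R = 3)
    expect_equal(sqrt(rowSums(v^2)), rep(3, n), tolerance = 1e-12)
    expect_lt(max(abs(colMeans(v))), 3 * 10 / n + 1e-9)
  }
  expect_error(make_sphere_vertices(3, 1), "N_v")
  expect_error(make_sphere_vertices(10, -1), "positive")
  # random mode also lands on the sphere, differs between seeds
  a <- make_sphere_vertices(50, 2, mode = "random", seed = 1)
  b <- make_sphere_vertices(50, 2, mode = "random", seed = 2)
  expect_equal(sqrt(rowSums(a^2)), rep(2, 50), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a, b)))
})

test_that("triangulation satisfies Euler's relation on known and large inputs", {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(nrow(triangulate(tet)$edges), 6)
  oct <- rbind(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
    c(0, 0, 1), c(0, 0, -1)
  )
  expect_equal(nrow(triangulate(oct)$edges), 12)
  v <- make_sphere_vertices(5560, 23.33)
  topo <- triangulate(v)
  expect_equal(nrow(topo$edges), 3 * 5560 - 6)
  expect_gte(min(tabulate(topo$edges, nbins = 5560)), 3)
  # degenerate input is refused
  flat <- cbind(runif(10), runif(10), 0)
  expect_error(triangulate(flat), "degenerate|inside")
})

test_that("rest length follows the mean-spacing formula and its scalings", {
  # R = 0.7 um, N_v = 5560 -> ~35.8 nm
  expect_equal(rest_length_from_geometry(0.7e-6, 5560) * 1e9, 35.76,
    tolerance = 1e-3
  )
  r1 <- rest_length_from_geometry(1, 500)
  expect_equal(rest_length_from_geometry(2, 500), 2 * r1)
  expect_equal(rest_length_from_geometry(1, 2000), r1 / 2)
  # realized nearest-neighbor spacing of the lattice is close to it
  v <- make_sphere_vertices(5560, 23.33)
  set.seed(1)
  idx <- sample(5560, 200)
  nn <- vapply(idx, function(i) {
    d2 <- colSums((t(v) - v[i, ])^2)
    sqrt(min(d2[-i]))
  }, numeric(1))
  expect_equal(mean(nn), rest_length_from_geometry(23.33, 5560),
    tolerance = 0.15
  )
})

test_that("pole selection maximizes the axis projection with swap symmetry", {
  oct <- rbind(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
    c(0, 0, 1), c(0, 0, -1)
  )
  env <- list(vertices = oct, edges = triangulate(oct)$edges)
  class(env) <- "envelope_state"
  e1 <- select_poles(env, c(0, 0, 1))
  expect_equal(e1$poles$a, 5)
  expect_equal(e1$poles$b, 6)
  e2 <- select_poles(env, c(0, 0, -1))
  expect_equal(e2$poles$a, 6)
  expect_equal(e2$poles$b, 5)
  # equivariance: rotating vertices and axis together selects the same
  # vertices
  v <- make_sphere_vertices(200, 5)
  env3 <- list(vertices = v, edges = triangulate(v)$edges)
  class(env3) <- "envelope_state"
  axis <- c(0.3, -0.5, 0.81)
  p0 <- select_poles(env3, axis)$poles
  rot <- random_rotation(9)
  env4 <- env3
  env4$vertices <- v %*% rot
  p1 <- select_poles(env4, as.vector(axis %*% rot))$poles
  expect_equal(p1$a, p0$a)
  expect_equal(p1$b, p0$b)
})

test_that("stretch force gradient applies F, F/2 antisymmetrically and sums to zero", {
  v <- make_sphere_vertices(300, 8)
  env <- list(vertices = v, edges = triangulate(v)$edges)
  class(env) <- "envelope_state"
  env <- select_poles(env, c(0, 0, 1))
  f0 <- stretch_forces(env, 0)
  expect_equal(f0, matrix(0, 300, 3))
  f <- stretch_forces(env, 10)
  expect_equal(f[env$poles$a, ], c(0, 0, 10))
  expect_equal(f[env$poles$b, ], c(0, 0, -10))
  for (i in env$poles$nbr_a) expect_equal(f[i, ], c(0, 0, 5))
  n_a <- length(env$poles$nbr_a)
  n_b <- length(env$poles$nbr_b)
  expect_lte(
    sqrt(sum(colSums(f)^2)),
    10 * abs(n_a - n_b) / 2 + 1e-12
  )
  if (n_a == n_b) expect_equal(colSums(f), c(0, 0, 0))
  expect_error(stretch_forces(env, -1), "non-negative")
  # SI magnitude of the maximal published force
  expect_equal(to_si(2e5, "force") * 1e9, 27, tolerance = 0.01)
})

test_that("shape metrics are 1 for spheres and track imposed anisotropy", {
  v <- make_sphere_vertices(2000, 4)
  m <- envelope_shape_metrics(v)
  expect_equal(m$aspect_ratio, 1, tolerance = 0.02)
  expect_lt(abs(m$asphericity), 0.01)
  v3 <- v %*% diag(c(1, 1, 3))
  expect_equal(envelope_shape_metrics(v3)$aspect_ratio, 3, tolerance = 0.05)
})

test_that("constructed envelopes start unstressed and satisfy Euler's count", {
  p <- tiny_params()
  env <- make_envelope(p)
  expect_equal(nrow(env$edges), 3 * p$N_v - 6)
  lens <- sqrt(rowSums((env$vertices[env$edges[, 1], ] -
                          env$vertices[env$edges[, 2], ])^2))
  expect_equal(lens, env$edge_rest, tolerance = 1e-12)
  expect_equal(mean(env$edge_rest), p$r0, tolerance = 0.05)
})

test_that("OFF mesh export writes a valid header and all elements", {
  v <- make_sphere_vertices(20, 2)
  topo <- triangulate(v)
  f <- withr::local_tempfile(fileext = ".off")
  write_off_mesh(v, topo$faces, f)
  lines <- readLines(f)
  expect_equal(lines[1], "OFF")
  expect_equal(lines[2], sprintf("20 %d 0", nrow(topo$faces)))
  expect_length(lines, 2 + 20 + nrow(topo$faces))
})
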