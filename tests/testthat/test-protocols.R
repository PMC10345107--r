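# Protocol bookkeeping: ramp arithmetic, tag monotonicity, domain
# spreading, twist geometry, and the structural contracts that do not
# need long dynamics (physics-level behavior is exercised in
# test-acceptance.R on a shared scaled-down pipeline).

fast_sched <- function(kind, n = 4, steps = 60, ...) {
  schedule(kind, n_increments = n, steps_per_increment = steps, ...)
}

test_that("schedules validate their fields", {
  expect_error(schedule("warp"), "unknown schedule")
  expect_error(schedule("relax", n_increments = 0), "at least 1")
  s <- schedule("elongate", 10, 100, F_max = 3)
  expect_s3_class(s, "protocol_schedule")
  expect_equal(s$F_max, 3)
})

test_that("relaxation requires a flexible chain and zero steps is identity", {
  st <- tiny_state()
  st0 <- run_relaxation(st, schedule("relax", 1, 1))
  expect_equal(st0$time, 0.005) # a single step
  st$triplet_k[5] <- 1
  expect_error(run_relaxation(st, fast_sched("relax")), "flexible")
})

test_that("uniform rigidification ramps all triplets linearly to k_max", {
  st <- tiny_state()
  k_max <- st$params$k_bend_max
  # mid-ramp: run a truncated schedule and inspect the stiffness
  st2 <- rigidify_uniform(st, schedule("rigidify_uniform", 2, 40))
  expect_equal(unique(st2$triplet_k[2:(st2$N_m - 1)]), k_max)
  expect_true(all(st2$tag == 2L))
  # interior triplets share one value after every increment (spot check
  # at increment 1 of 4 via a single-increment schedule at k/4)
  st3 <- st
  st3$params$k_bend_max <- k_max / 4
  st3 <- rigidify_uniform(st3, schedule("rigidify_uniform", 1, 20))
  expect_equal(
    unique(st3$triplet_k[2:(st3$N_m - 1)]),
    k_max / 4
  )
})

test_that("nucleated rigidification tags, ramps, spreads and terminates", {
  st <- tiny_state(n_m = 120, n_v = 100, R = 7, seed = 5)
  sch <- schedule("rigidify_nucleated",
    n_increments = 2, steps_per_increment = 25,
    d_nucleation = 2.5, N_spread = 15
  )
  st2 <- rigidify_nucleated(st, sch)
  tr <- st2$log$rigidify_nucleated
  expect_true(all(st2$tag == 2L))
  expect_equal(
    unique(st2$triplet_k[2:119]), st$params$k_bend_max
  )
  # tagged fraction grows monotonically and starts small
  expect_true(all(diff(tr$tagged_fraction) >= 0))
  expect_lt(tr$tagged_fraction[1], 0.5)
  expect_equal(tail(tr$rigid_fraction, 1), 1)
  # terminal mechanical parameters identical to the uniform protocol
  stu <- rigidify_uniform(
    tiny_state(n_m = 120, n_v = 100, R = 7, seed = 5),
    schedule("rigidify_uniform", 2, 25)
  )
  expect_identical(st2$triplet_k, stu$triplet_k)
  # a nucleation radius capturing no monomer is an error
  expect_error(
    rigidify_nucleated(st, schedule("rigidify_nucleated", 1, 10,
      d_nucleation = 1e-6
    )),
    "no monomer"
  )
})

test_that("domain spreading extends and merges tagged intervals", {
  tag <- rep(FALSE, 60)
  tag[20:24] <- TRUE
  tag[30:32] <- TRUE
  dom <- spoolsim:::tag_domains(tag)
  expect_equal(dom, cbind(start = c(20L, 30L), end = c(24L, 32L)),
    ignore_attr = TRUE
  )
  # [a, b] with N_spread = 10 becomes [a-10, b+10] clipped to chain ends;
  # colliding domains merge into one interval
  grown <- rep(FALSE, 60)
  for (k in seq_len(nrow(dom))) {
    grown[max(1, dom[k, 1] - 10):min(60, dom[k, 2] + 10)] <- TRUE
  }
  dom2 <- spoolsim:::tag_domains(grown)
  expect_equal(nrow(dom2), 1)
  expect_equal(dom2[1, ], c(start = 10L, end = 42L), ignore_attr = TRUE)
})

test_that("triplet stiffness follows the all-tagged rule with untagged zeros", {
  tag <- c(0L, 2L, 2L, 2L, 1L, 1L, 0L, 0L)
  k <- spoolsim:::triplet_stiffness(tag, k_max = 10, ramp_level = 0.5)
  expect_equal(k[3], 10) # fully rigid triplet
  expect_equal(k[5], 5) # triplet within rigid+ramping set: ramp level
  expect_equal(k[2], 0) # touches an untagged monomer
  expect_equal(k[7], 0)
  expect_equal(k[c(1, 8)], c(0, 0)) # chain ends carry no triplet
})

test_that("twist rotates linearly about the axis and preserves axial coords", {
  st <- tiny_state(n_m = 40, n_v = 60, R = 6)
  cen <- nucleus_center(st)
  # particle nearest the axis barely moves; off-axis midpoint rotates
  rel <- sweep(st$pos, 2, cen)
  z <- rel[, 3]
  st2 <- apply_twist(st, axis = c(0, 0, 1), twist_total = 10 * pi)
  rel2 <- sweep(st2$pos, 2, cen)
  expect_equal(rel2[, 3], z, tolerance = 1e-12)
  on_axis <- which.min(rel[, 1]^2 + rel[, 2]^2)
  expect_equal(
    sqrt(sum((rel2[on_axis, 1:2] - rel[on_axis, 1:2])^2)),
    0,
    tolerance = 2 * sqrt(sum(rel[on_axis, 1:2]^2)) + 1e-9
  )
  # rotation angle matches the linear field
  phi_exp <- 10 * pi * (z - min(z)) / (max(z) - min(z))
  phi_obs <- atan2(rel2[, 2], rel2[, 1]) - atan2(rel[, 2], rel[, 1])
  dphi <- (phi_obs - phi_exp) %% (2 * pi)
  dphi <- pmin(dphi, 2 * pi - dphi)
  off_axis <- rel[, 1]^2 + rel[, 2]^2 > 0.5
  expect_lt(max(dphi[off_axis]), 1e-6)
  # degenerate axial extent is refused
  stf <- st
  stf$pos[, 3] <- 0
  expect_error(apply_twist(stf, c(0, 0, 1), pi), "degenerate|z_max")
})

test_that("decondensation zeroes forces and traces the aspect ratio", {
  st <- tiny_state(n_m = 30, n_v = 80, R = 6)
  st$envelope$stretch_F <- 5
  ev <- list(vertices = vertex_positions(st), edges = st$envelope$edges)
  class(ev) <- "envelope_state"
  st$envelope$poles <- select_poles(ev)$poles
  st2 <- run_decondensation(st, schedule("decondense", 4, 50))
  expect_equal(st2$envelope$stretch_F, 0)
  tr <- st2$log$decondensation
  expect_equal(nrow(tr), 5)
  # spherical input: the trace stays near 1 throughout
  expect_true(all(abs(tr$aspect_ratio - 1) < 0.12))
  # determinism: identical traces for identical input
  st3 <- run_decondensation(st, schedule("decondense", 4, 50))
  expect_identical(st3$log$decondensation, tr)
})

test_that("elongation ramps the force and stores pole bookkeeping", {
  st <- tiny_state(n_m = 30, n_v = 80, R = 6, seed = 3)
  st <- rigidify_uniform(st, schedule("rigidify_uniform", 1, 30))
  sch <- schedule("elongate",
    n_increments = 3, steps_per_increment = 40,
    F_max = 30, axis = c(0, 0, 1)
  )
  st2 <- run_elongation(st, sch)
  tr <- st2$log$elongation
  expect_equal(tr$F, c(10, 20, 30))
  expect_equal(st2$envelope$stretch_F, 30)
  expect_false(is.null(st2$envelope$poles))
  # F = 0 keeps the envelope spherical
  st0 <- run_elongation(st, schedule("elongate", 2, 40, F_max = 0))
  expect_equal(
    envelope_shape_metrics(vertex_positions(st0))$aspect_ratio, 1,
    tolerance = 0.1
  )
  # the overstretch guard aborts when engaged
  expect_error(
    run_elongation(st, schedule("elongate", 2, 200,
      F_max = 5e4,
      max_spring_stretch = 1.5
    )),
    "overstretch"
  )
})
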