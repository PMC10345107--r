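# Synthetic fixtures double as analysis oracles: every fixture's
# quantification must match its construction.

test_that("the ideal spool concentrates aligned mass at the periphery", {
  sp <- make_ideal_spool(n_turns = 14, R = 12)
  pos <- sp$positions
  bonds <- diff(pos)
  mid <- (pos[-1, ] + pos[-nrow(pos), ]) / 2
  keep <- sqrt(rowSums(bonds^2)) < 1.5 # drop the ring-to-ring joins
  # fine angular sectors resolve the winding as locally parallel
  prof <- local_alignment(bonds[keep, ],
    mid = mid[keep, ], R = 12,
    n_shells = 5, n_sectors = 32
  )
  occupied <- which(prof$n_bonds > 20)
  expect_true(all(occupied >= 4)) # only the outer shells hold mass
  expect_gt(prof$alpha_r[max(occupied)], 0.9)
  # octant sectors: azimuthal tangents span a quarter turn, whose
  # closed-form alignment is 2(l3 - l2)/3 of eigenvalues from
  # M = [[1/2, -1/pi], [-1/pi, 1/2]]: alpha = (1/2 + 3/(2*pi)) - ...
  oct_prof <- local_alignment(bonds[keep, ],
    mid = mid[keep, ], R = 12,
    n_shells = 5, n_sectors = 8
  )
  m_ev <- c(1 / 2 + 1 / pi, 1 / 2 - 1 / pi, 0)
  q_ev <- sort((3 * m_ev - 1) / 2)
  alpha_oct <- 2 * (q_ev[3] - q_ev[2]) / 3
  expect_equal(oct_prof$alpha_r[max(occupied)], alpha_oct, tolerance = 0.1)
  dens <- radial_density(pos, R = 12, n_shells = 5)
  expect_equal(sum(dens$n[1:3]), 0)
  # near-equatorial rings pooled: planar-degenerate Q spectrum
  eq_ring <- abs(mid[, 3]) < 2.5 & keep
  expect_gt(sum(eq_ring), 20)
  ev <- sort(eigen(q_tensor_3d(bonds[eq_ring, ]))$values)
  expect_equal(ev, c(-1 / 2, 1 / 4, 1 / 4), tolerance = 0.06)
  expect_error(make_ideal_spool(n_turns = 100, R = 5), "overlap")
})

test_that("twisted bundles reduce to axial bundles at zero twist", {
  b0 <- make_twisted_bundle(n_fibers = 9, length = 24, twist_per_length = 0)
  ba <- make_axial_bundle(n_fibers = 9, length = 24)
  expect_equal(b0$positions, ba$positions)
  # a particle at the axial midpoint is rotated by half the total twist
  # (10*pi over the length -> 5*pi = pi mod 2*pi at the midpoint)
  tw <- 10 * pi / 24
  bt <- make_twisted_bundle(n_fibers = 9, length = 24, twist_per_length = tw)
  z <- ba$positions[, 3]
  i <- which(abs(z - min(z) - 12) < 0.51 & ba$positions[, 1] != 0)[1]
  expected_phi <- tw * (z[i] - min(z))
  v0 <- ba$positions[i, 1:2]
  v1 <- bt$positions[i, 1:2]
  ang <- (atan2(v1[2], v1[1]) - atan2(v0[2], v0[1])) %% (2 * pi)
  expect_equal(ang, expected_phi %% (2 * pi), tolerance = 1e-9)
  expect_equal(bt$positions[, 3], ba$positions[, 3]) # axial coords kept
})

test_that("rendered sections recover the fixture's known orientation", {
  bun <- make_axial_bundle(n_fibers = 7, length = 30, spacing = 2.5)
  img <- render_section(bun,
    plane = "xz", thickness = 3, psf_sigma = 1,
    noise_sigma = 0.02, seed = 3
  )
  of <- orientation_field(img)
  modal <- of$P_theta$theta[which.max(of$P_theta$density)]
  # fibers run along z = image y axis: orientation +-pi/2 from x
  expect_lt(abs(abs(modal) - pi / 2), 2 * pi / 180)
  expect_gt(of$S2d, 0.7)
})

test_that("rendering is deterministic and degrades gracefully", {
  bun <- make_axial_bundle(n_fibers = 4, length = 10)
  a <- render_section(bun, seed = 9)
  b <- render_section(bun, seed = 9)
  expect_identical(a, b)
  c2 <- render_section(bun, seed = 10)
  expect_false(identical(a, c2))
  # clean render without blur or noise is binary
  bin <- render_section(bun, psf_sigma = 0, noise_sigma = 0)
  expect_true(all(bin %in% c(0, 1)))
  expect_warning(
    blank <- render_section(bun, plane = "xy", offset = 100),
    "empty slab"
  )
  expect_equal(max(blank), 0)
})

test_that("an isotropic coil renders to a near-isotropic image", {
  coil <- make_random_coil(4000, seed = 11)
  img <- render_section(coil,
    plane = "xy", thickness = 4, px_per_sigma = 6,
    noise_sigma = 0.02, seed = 1
  )
  expect_gte(min(dim(img)), 100)
  of <- orientation_field(img)
  expect_lt(of$S2d, 0.25)
})

test_that("cross-sections of twisted bundles carry in-plane signal", {
  n <- 32
  untw <- make_twisted_bundle(25, length = 20, twist_per_length = 0,
                              spacing = 3)
  tw <- make_twisted_bundle(25, length = 20, twist_per_length = 10 * pi / 20,
                            spacing = 3)
  img_u <- render_section(untw, plane = "xy", thickness = 2, seed = 2,
                          noise_sigma = 0)
  img_t <- render_section(tw, plane = "xy", thickness = 2, seed = 2,
                          noise_sigma = 0)
  # twisted fibers pierce the section obliquely: their in-plane tracks
  # carry a tangential orientation signal absent in the axial control
  wu <- orientation_field(img_u)
  wt <- orientation_field(img_t)
  expect_gt(sum(wt$weights), sum(wu$weights))
})

test_that("images round-trip through PNG and TIFF", {
  skip_if_not_installed("png")
  skip_if_not_installed("tiff")
  img <- stripe_image(64, 48, angle = 0.3)
  fp <- withr::local_tempfile(fileext = ".png")
  write_image(img, fp)
  back <- read_image(fp)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 0.01) # 8/16-bit quantization
  ft <- withr::local_tempfile(fileext = ".tiff")
  write_image(img, ft)
  expect_lt(max(abs(read_image(ft) - img)), 1e-3)
})
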