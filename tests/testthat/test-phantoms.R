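test_that("make_subunit is deterministic and geometrically consistent", {
  a <- make_subunit("p", "blob-cluster", seed = 5)
  b <- make_subunit("p", "blob-cluster", seed = 5)
  expect_identical(a$beads, b$beads)
  expect_false(identical(a$beads,
                         make_subunit("p", "blob-cluster", seed = 6)$beads))
  ## Y geometry oracle: recompute the tail -> long-arm-tip distance from
  ## the construction parameters and compare with the realised beads
  pars <- list(stem = 30, arm_long = 15, arm_short = 9, arm_angle = 50,
               arm_lift = 35, spacing = 2.5, bead_radius = 1.5)
  y <- make_subunit("Y", "Y", pars)
  tail_y <- -pars$stem * 0.8
  head_xy <- c(sin(pi * 50 / 180) * 15,
               pars$stem * 0.2 + cos(pi * 50 / 180) * 15)
  expected <- sqrt(head_xy[1]^2 + (head_xy[2] - tail_y)^2)
  expect_equal(model_extent(y), expected, tolerance = pars$bead_radius)
  ## head/tail roles present exactly once
  expect_equal(sum(y$beads$role == "head"), 1)
  expect_equal(sum(y$beads$role == "tail"), 1)
  ## degenerate rod: single bead at origin
  r1 <- make_subunit("r", "rod", list(length = 0))
  expect_equal(nrow(r1$beads), 1)
  expect_equal(unlist(r1$beads[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))
  expect_error(make_subunit("x", "banana"), "arg")
})

test_that("build_assembly places the documented copy numbers", {
  subs <- default_subunits()
  ## 8 cytoplasmic + 16 nuclear Y copies = 24 in the full phantom
  asm <- build_assembly(crnpc_spec(), subs)
  expect_equal(sum(asm$ground_truth$subunit == "Y"), 24)
  ## 8 spokes x 4 stacked protomers = 32 in the inner ring
  expect_equal(sum(asm$ground_truth$subunit == "protomer"), 32)
  expect_equal(nrow(asm$ground_truth), total_copies(crnpc_spec()))
  ir <- build_assembly(inner_ring_spec(), subs)
  expect_equal(nrow(ir$ground_truth), 32)
  ## single ring, 1 copy, radius 0 -> copy at the origin
  s1 <- architecture_spec(list(list(label = "Y", ring = "R", copies = 1,
                                    radius = 0, z = 0, phase = 30,
                                    asymmetric = TRUE)))
  a1 <- build_assembly(s1, subs)
  expect_equal(unlist(a1$ground_truth[1, c("tx", "ty", "tz")]),
               c(tx = 0, ty = 0, tz = 0))
  expect_equal(a1$ground_truth$phi[1], 30)
  expect_error(build_assembly(crnpc_spec(), subs["Y"]), "protomer")
  ## rings must respect the symmetry order unless declared asymmetric
  expect_error(architecture_spec(list(list(label = "Y", ring = "R",
                                           copies = 6, radius = 10,
                                           z = 0))), "divisible")
})

test_that("ring radius is recoverable from rendered copy centroids", {
  spec <- ring_spec(copies = 8, radius = 30)
  subs <- default_subunits()
  asm <- build_assembly(spec, subs)
  m <- render_density(asm$model, 2, 110, 6)
  ## centre of mass of the density near each planted copy
  d <- dim(m$values)
  for (i in c(1, 4)) {
    g <- asm$ground_truth[i, ]
    cvox <- round(c(g$tx, g$ty, g$tz) / 2 + (d + 1) / 2)
    w <- 8
    ir <- (cvox[1] - w):(cvox[1] + w)
    jr <- (cvox[2] - w):(cvox[2] + w)
    kr <- (cvox[3] - w):(cvox[3] + w)
    sub <- m$values[ir, jr, kr]
    tot <- sum(sub)
    cx <- sum(sweep(sub, 1, ir, `*`)) / tot
    cy <- sum(aperm(sweep(aperm(sub, c(2, 1, 3)), 1, jr, `*`),
                    c(2, 1, 3))) / tot
    com <- (c(cx, cy) - (d[1:2] + 1) / 2) * 2
    r_meas <- sqrt(sum(com^2))
    expect_lt(abs(r_meas - 30), 2.5)      # within ~1 voxel
  }
})

test_that("render_density integrates to the bead weight with the stated width", {
  b1 <- bead_model(data.frame(x = 0, y = 0, z = 0, weight = 2,
                              radius = 0.5), "pt")
  bm <- render_density(b1, 1, 31, 6)
  expect_equal(sum(bm$values) * 1^3, 2, tolerance = 0.01)
  ## global maximum at the bead position (grid centre of an odd box)
  expect_equal(as.integer(which.max(bm$values)),
               as.integer(which(array(seq_len(31^3), rep(31, 3)) ==
                                ((31^3 + 1) / 2))))
  ## doubling weights doubles the integral
  b2 <- bead_model(data.frame(x = 0, y = 0, z = 0, weight = 4,
                              radius = 0.5), "pt")
  expect_equal(sum(render_density(b2, 1, 31, 6)$values),
               2 * sum(bm$values), tolerance = 1e-9)
  ## measured FWHM equals the rendering resolution within a voxel
  prof <- bm$values[, 16, 16]
  half <- max(prof) / 2
  above <- which(prof >= half)
  lo <- min(above); hi <- max(above)
  ## interpolate the crossings
  xl <- lo - 1 + (prof[lo - 1] - half) / (prof[lo - 1] - prof[lo])
  xr <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  expect_equal(xr - xl, 6, tolerance = 1)
  expect_error(render_density(b1, 1, 31, 0.5), "voxel_size")
  far <- bead_model(data.frame(x = 100, y = 0, z = 0, weight = 1,
                               radius = 1), "far")
  expect_error(render_density(far, 1, 31, 6), "offending beads: 1")
})

test_that("simulate_particle honours its noise and wedge contract", {
  amap <- y_map(voxel = 3, box = 48)
  w <- wedge_descriptor(-60, 60)
  ## noise-free, identity pose -> exactly the wedge-corrupted map
  p0 <- simulate_particle(amap, w, snr = Inf, seed = 1, pose_true = pose())
  expect_map_equal(p0$map, apply_wedge(amap, w), tol = 1e-9)
  ## empirical variance ratio within 10% of the requested snr
  p1 <- simulate_particle(amap, w, snr = 1, seed = 2, pose_true = pose())
  sig <- apply_wedge(amap, w)$values
  noise <- p1$map$values - sig
  expect_equal(var(as.numeric(sig)) / var(as.numeric(noise)), 1,
               tolerance = 0.1)
  ## seeds: reproducible, and different seeds differ
  p2a <- simulate_particle(amap, w, snr = 1, seed = 5)
  p2b <- simulate_particle(amap, w, snr = 1, seed = 5)
  p2c <- simulate_particle(amap, w, snr = 1, seed = 6)
  expect_identical(p2a$map$values, p2b$map$values)
  expect_false(identical(p2a$map$values, p2c$map$values))
  expect_error(simulate_particle(amap, w, snr = -1, seed = 1), "snr")
})

test_that("generate_particle_set produces a reproducible posed stack", {
  spec <- ring_spec(copies = 8, radius = 24)
  w <- wedge_descriptor(-60, 60)
  ps <- generate_particle_set(spec, 5, w, snr = 2, seed = 9,
                              voxel_size = 6, box_nm = 96,
                              resolution_nm = 8)
  expect_length(ps$particles, 5)
  expect_equal(nrow(ps$poses), 5)
  expect_equal(nrow(ps$ground_truth), 8)
  ps2 <- generate_particle_set(spec, 5, w, snr = 2, seed = 9,
                               voxel_size = 6, box_nm = 96,
                               resolution_nm = 8)
  expect_identical(ps$particles[[3]]$map$values,
                   ps2$particles[[3]]$map$values)
  ## noise-free particle (no missing region) is recovered by the
  ## inverse true pose up to interpolation
  ps3 <- generate_particle_set(spec, 1, wedge_descriptor(-90, 90),
                               snr = Inf, seed = 4, voxel_size = 3,
                               box_nm = 96, resolution_nm = 6)
  back <- transform_map(ps3$particles[[1]]$map,
                        pose_invert(ps3$particles[[1]]$true_pose))
  expect_gt(map_cc(back, ps3$assembly_map), 0.97)
})

test_that("simulate_expression plants modules at the requested correlation", {
  sim <- simulate_expression(60, list(m1 = 20), 500, 0.8, seed = 11)
  expect_equal(dim(sim$fpkm), c(60, 500))
  expect_true(all(sim$fpkm >= 0))
  lg <- log2(sim$fpkm + 1)
  idx <- which(sim$modules == "m1")
  cm <- cor(t(lg[idx, ]))
  expect_gt(mean(cm[upper.tri(cm)]), 0.75)
  expect_lt(mean(cm[upper.tri(cm)]), 0.85)
  ## zero correlation: module indistinguishable from background
  sim0 <- simulate_expression(60, list(m1 = 20), 500, 0, seed = 12)
  cm0 <- cor(t(log2(sim0$fpkm[1:20, ] + 1)))
  expect_lt(mean(abs(cm0[upper.tri(cm0)])), 2 / sqrt(500))
  expect_error(simulate_expression(60, list(m1 = 20), 100, 1.5), "corr")
})
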