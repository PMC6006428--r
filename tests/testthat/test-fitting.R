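## Small fixtures: a rod model in a 16^3 box for oracle-equivalence
## tests, a Y model for planted-recovery tests.

rod16 <- function() {
  m <- render_density(make_subunit("r", "rod", list(length = 10)), 2, 32, 6)
  m
}

test_that("the SO(3) grid has the documented quasi-uniform size", {
  g <- so3_grid(30)
  ## independent recomputation of the construction's size
  n_dir <- round(4 * (180 / 30)^2 / pi)
  n_psi <- round(360 / 30)
  expect_equal(nrow(g), n_dir * n_psi)
  expect_equal(attr(g, "n_dir"), n_dir)
  ## quasi-uniform: a random rotation is never far from the grid
  set.seed(31)
  for (i in 1:10) {
    a <- c(runif(1, 0, 360), acos(runif(1, -1, 1)) * 180 / pi,
           runif(1, 0, 360))
    dmin <- min(apply(g, 1, rotation_distance, a2 = a))
    expect_lt(dmin, 30)
  }
})

test_that("score_fit scores truth high and disjoint placements near zero", {
  ym <- y_map(voxel = 3, box = 72)
  thr_m <- 0.5 * max(ym$values)
  thr_t <- envelope_threshold(ym, envelope_volume(ym, thr_m))
  s0 <- score_fit(ym, ym, pose(), thr_m, thr_t)
  expect_gte(s0$cc, 0.999)
  expect_gte(s0$overlap, 0.999)
  ## model placed wholly outside the density
  s1 <- score_fit(ym, ym, pose(shift = c(30, 0, 0)), thr_m, thr_t)
  expect_lte(s1$overlap, 0.05)
  expect_lt(abs(s1$score), 0.05)
  ## truth scores above the 95th percentile of random poses
  set.seed(33)
  rand <- replicate(200, {
    p <- pose(c(runif(1, 0, 360), runif(1, 0, 180), runif(1, 0, 360)),
              runif(3, -20, 20))
    score_fit(ym, ym, p, thr_m, thr_t)$score
  })
  expect_gt(s0$score, quantile(rand, 0.95))
  expect_error(score_fit(ym, ym, pose(), 10 * max(ym$values), thr_t),
               "empty model envelope")
})

test_that("accelerated translational search equals direct scoring", {
  m <- rod16()
  target <- transform_map(m, pose(c(30, 0, 0), c(4, 2, -2)))
  ens <- exhaustive_search(m, target, angular_step = 60,
                           translation_step = 1, volume_factor = 1,
                           max_shift = 8)
  set.seed(35)
  pick_t <- sample(nrow(ens$shifts), 20)
  pick_r <- sample(nrow(ens$angles), 10)
  for (ti in pick_t) for (ri in pick_r[1:3]) {
    p <- pose(ens$angles[ri, ], ens$shifts[ti, ] * ens$voxel_size)
    d <- tryCatch(score_fit(m, target, p, ens$model_thr, ens$target_thr),
                  error = function(e) NULL)
    if (is.null(d)) next                       # envelope left the box
    expect_lt(abs(ens$score[ti, ri] - d$score), 1e-5)
    expect_lt(abs(ens$cc[ti, ri] - d$cc), 1e-5)
    expect_lt(abs(ens$overlap[ti, ri] - d$overlap), 1e-5)
  }
})

test_that("a planted subunit is recovered within one grid step", {
  ym <- y_map(voxel = 3, box = 72)
  truth <- pose(c(40, 20, 10), c(6, -3, 3))
  target <- transform_map(ym, truth)
  ens <- exhaustive_search(ym, target, angular_step = 20,
                           translation_step = 1, volume_factor = 1,
                           max_shift = 12)
  i <- which.max(ens$score)
  ij <- arrayInd(i, dim(ens$score))
  best_ang <- ens$angles[ij[2], ]
  best_sh <- ens$shifts[ij[1], ] * ens$voxel_size
  expect_lte(rotation_distance(best_ang, truth$angles), 20)
  expect_lte(max(abs(best_sh - truth$shift)), 3)   # one voxel
})

test_that("searching an all-zero map is safe and scores zero", {
  m <- rod16()
  zero <- density_map(array(0, dim(m$values)), m$voxel_size)
  ens <- exhaustive_search(m, zero, angular_step = 90,
                           translation_step = 2, volume_factor = 1,
                           max_shift = 6, target_thr = 0.1)
  expect_true(all(ens$score == 0))
  expect_error(assess_significance(ens), "degenerate")
})

test_that("significance: p monotone in score, planted ring fully flagged", {
  ## noise-free double ring of 16 Y copies at z = 0 (the doubled
  ## outer-ring arrangement)
  spec <- architecture_spec(list(
    list(label = "Y", ring = "out", copies = 8, radius = 42, z = 0),
    list(label = "Y", ring = "in", copies = 8, radius = 25, z = 0,
         phase = 22.5)))
  ph <- ring_phantom(spec, voxel = 4, box = 128, res = 6)
  ym <- render_density(default_subunits()$Y, 4, 128, 6)
  ens <- exhaustive_search(ym, ph$map, angular_step = 30,
                           translation_step = 1, volume_factor = 16,
                           max_shift = 52)
  ens <- assess_significance(ens, alpha = 0.05, trans_tol = 12)
  ## the null p-value is non-increasing in the correlation
  ccs <- sort(ens$maxima$cc, decreasing = TRUE)
  p <- fisher_null_pvalue(ccs, 20)
  expect_true(all(diff(p) >= -1e-15))
  ## every planted copy has a significant truth-adjacent local maximum
  sig <- ens$maxima[ens$maxima$significant, ]
  expect_gt(nrow(sig), 0)
  dts <- nearest_dist(ph$gt, sig)   # truth -> nearest significant max
  for (i in seq_len(nrow(ph$gt))) {
    d <- min(sqrt((sig$tx - ph$gt$tx[i])^2 + (sig$ty - ph$gt$ty[i])^2 +
                  (sig$tz - ph$gt$tz[i])^2))
    expect_lt(d, 6)
  }
})

test_that("pure-noise maps produce significant clusters at most at rate alpha", {
  m <- render_density(make_subunit("r", "rod", list(length = 10)), 2, 40, 6)
  rates <- vapply(1:20, function(sd) {
    nz <- random_map(20, voxel = 2, seed = 400 + sd)
    ens <- exhaustive_search(m, nz, angular_step = 45,
                             translation_step = 1, volume_factor = 2,
                             max_shift = 10)
    ens <- assess_significance(ens, alpha = 0.05, trans_tol = 6)
    cl <- ens$clusters
    sum(cl$significant) / nrow(cl)
  }, 0)
  expect_lte(mean(rates), 0.05)
})

test_that("greedy clustering resolves a C8 ring into 8 placements", {
  spec <- ring_spec(copies = 8, radius = 30)
  ph <- ring_phantom(spec, voxel = 4, box = 112, res = 6)
  ym <- render_density(default_subunits()$Y, 4, 112, 6)
  ens <- exhaustive_search(ym, ph$map, angular_step = 30,
                           translation_step = 1, volume_factor = 8,
                           max_shift = 40)
  ens <- assess_significance(ens, 0.05, trans_tol = 12)
  sig <- ens$maxima[ens$maxima$significant, ]
  cl <- cluster_fits(sig, rot_tol = Inf, trans_tol = 12)
  ## the 8 top clusters sit on the planted ring, 45 degrees apart
  top <- cl[1:8, ]
  az <- sort((atan2(top$ty, top$tx) * 180 / pi) %% 360)
  gaps <- diff(c(az, az[1] + 360))
  expect_true(all(abs(gaps - 45) < 15))
  expect_true(all(nearest_dist(top, ph$gt) < 6))
  ## duplicated input yields identical clusters
  cl2 <- cluster_fits(rbind(sig, sig), rot_tol = Inf, trans_tol = 12)
  expect_equal(cl2[, c("tx", "ty", "tz", "score")],
               cl[, c("tx", "ty", "tz", "score")])
  ## single planted copy: exactly one cluster above significance
  one <- transform_map(ym, pose(c(15, 0, 0), c(5, 0, 0)))
  e1 <- exhaustive_search(ym, one, angular_step = 40,
                          translation_step = 1, volume_factor = 1,
                          max_shift = 16)
  e1 <- assess_significance(e1, 0.05, trans_tol = 14)
  expect_equal(sum(e1$clusters$significant), 1)
})

test_that("hierarchical fitting assigns a two-subunit phantom in order", {
  subs <- list(rod = make_subunit("rod", "rod", list(length = 16)),
               blob = make_subunit("blob", "blob-cluster", seed = 3))
  spec <- architecture_spec(list(
    list(label = "rod", ring = "big", copies = 8, radius = 36, z = 0),
    list(label = "blob", ring = "small", copies = 8, radius = 20,
         z = 0, phase = 22.5)))
  ph0 <- ring_phantom(spec, subunits = subs, voxel = 4, box = 112,
                      res = 6)
  ph <- list(map = lowpass_filter(ph0$map, 8), gt = ph0$gt)
  mm <- prepare_fit_models(subs, 4, 112, 6, lowpass_nm = 8)
  ## mask-focused searches: each model is fitted in its own ring
  ## region, as the per-ring refinement stage of the pipeline does
  d <- dim(ph$map$values)
  ctr <- (d[1] + 1) / 2
  rr <- sqrt((npcfit:::index_grid(d)[1, ] - ctr)^2 +
             (npcfit:::index_grid(d)[2, ] - ctr)^2) * 4
  mk <- function(sel) density_map(array(as.numeric(sel), d), 4,
                                  ph$map$origin)
  entries <- list(
    list(label = "rod", model_map = mm$rod, region_mask = mk(rr > 26),
         volume_factor = 8, max_shift = 44, trans_tol = 12),
    list(label = "blob", model_map = mm$blob, region_mask = mk(rr <= 26),
         volume_factor = 8, max_shift = 26, trans_tol = 7))
  fit <- hierarchical_fit(ph$map, entries, alpha = 0.05,
                          angular_step = 30)
  asg <- fit$assignment
  expect_equal(sum(asg$model == "rod"), 8)
  expect_equal(sum(asg$model == "blob"), 8)
  ## placements sit on the planted copies
  for (lb in c("rod", "blob")) {
    a <- asg[asg$model == lb, ]
    g <- ph$gt[ph$gt$subunit == lb, ]
    expect_true(all(nearest_dist(a, g) < 6))
  }
  ## the residual map retains no further significant rod placements
  refit <- hierarchical_fit(fit$residual_map, entries[1], alpha = 0.05,
                            angular_step = 30)
  expect_equal(nrow(refit$assignment), 0)
  ## empty model list: nothing assigned, map untouched
  none <- hierarchical_fit(ph$map, list())
  expect_equal(nrow(none$assignment), 0)
  expect_identical(none$residual_map, ph$map)
})

test_that("count_copies attributes placements to region masks", {
  d <- c(16, 16, 16)
  mk <- function(sel) density_map(array(as.numeric(sel), d), 4)
  z <- rep(1:16, each = 16 * 16)
  masks <- list(top = mk(z > 8), bottom = mk(z <= 8))
  asg <- data.frame(model = c("A", "A", "B"),
                    phi = 0, theta = 0, psi = 0,
                    tx = c(0, 0, 0), ty = c(0, 0, 0),
                    tz = c(10, -10, 10),
                    cc = 1, overlap = 1, score = 1, p = 0, q = 0,
                    n_members = 1L)
  cnt <- count_copies(asg, masks)
  expect_equal(cnt$count[cnt$model == "A" & cnt$region == "top"], 1)
  expect_equal(cnt$count[cnt$model == "A" & cnt$region == "bottom"], 1)
  expect_equal(cnt$count[cnt$model == "B" & cnt$region == "top"], 1)
  ## empty assignment -> empty counts
  expect_equal(nrow(count_copies(asg[0, ], masks)), 0)
  ## outside all masks -> unassigned
  far <- asg[1, ]; far$tz <- 100
  cnt2 <- count_copies(far, masks)
  expect_equal(cnt2$region, "unassigned")
})
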