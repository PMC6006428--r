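test_that("poses compose, invert and round-trip through Euler angles", {
  p <- pose(c(40, 30, -70), c(1, -2, 3))
  id <- pose_compose(pose_invert(p), p)
  expect_lt(rotation_distance(id$angles, c(0, 0, 0)), 1e-9)
  expect_lt(max(abs(id$shift)), 1e-9)
  for (seed in 1:5) {
    set.seed(seed)
    a <- c(runif(1, -180, 180), runif(1, 0, 180), runif(1, -180, 180))
    R <- pose_matrix(a)
    expect_lt(max(abs(pose_matrix(matrix_to_euler(R)) - R)), 1e-12)
  }
  ## gimbal cases
  expect_lt(max(abs(pose_matrix(matrix_to_euler(rot_z(25))) - rot_z(25))),
            1e-12)
})

test_that("density_map enforces its invariants", {
  expect_error(density_map(array(0, c(4, 4, 4)), 0), "positive")
  expect_error(density_map(array(0, c(4, 4, 4)), -1), "positive")
  expect_error(density_map(matrix(0, 4, 4), 1), "3-D")
})

test_that("MRC round-trip reproduces values and physical metadata", {
  m <- random_map(16, voxel = 1.5, seed = 3, origin = c(-24, -24, -24))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, f)
  m2 <- read_map(f)
  expect_lt(max(abs(m$values - m2$values)), 1e-6)   # float32 precision
  expect_equal(m2$voxel_size, 1.5, tolerance = 1e-6)
  expect_equal(m2$origin, c(-24, -24, -24), tolerance = 1e-5)
})

test_that("MRC header fields agree with an independent binary parser", {
  m <- random_map(32, voxel = 1.5, seed = 5, origin = c(-24, -24, -24))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, f)
  ## independent parser: raw readBin at the documented MRC2014 offsets
  con <- file(f, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_f <- readBin(con, "numeric", 256, size = 4, endian = "little")
  expect_identical(hdr_i[1:3], c(32L, 32L, 32L))      # NX NY NZ
  expect_identical(hdr_i[4], 2L)                      # MODE 2
  expect_identical(hdr_i[8:10], c(32L, 32L, 32L))     # MX MY MZ
  expect_equal(hdr_f[11:13], rep(32 * 15, 3), tolerance = 1e-4)  # CELLA (A)
  expect_identical(hdr_i[17:19], 1:3)                 # MAPC MAPR MAPS
  expect_equal(hdr_f[50:52], rep(-240, 3), tolerance = 1e-4)     # ORIGIN (A)
  seek(con, 52 * 4)
  expect_identical(rawToChar(readBin(con, "raw", 4)), "MAP ")
})

test_that("malformed volumes are rejected with the offending field named", {
  f <- withr::local_tempfile(fileext = ".mrc")
  writeBin(as.raw(rep(0, 2048)), f)
  expect_error(read_map(f), "MODE")
  expect_error(read_map(file.path(tempdir(), "nope.mrc")), "exist")
})

test_that("low-pass filter attenuates beyond cutoff and preserves the mean", {
  m <- random_map(32, voxel = 2, seed = 7)
  lf <- lowpass_filter(m, 8)
  expect_equal(mean(lf$values), mean(m$values), tolerance = 1e-12)
  ## independent spectrum oracle
  fa <- fft(lf$values)
  fr <- function(n) (((0:(n - 1)) + n %/% 2) %% n - n %/% 2) / n
  f1 <- fr(32)
  r <- sqrt(outer(outer(f1^2, f1^2, `+`), f1^2, `+`)) / 2
  hi <- r > 1 / 8 + 1 / 64 + 1e-9
  expect_lt(sum(abs(fa[hi])^2) / sum(abs(fa)^2), 1e-3)
  ## idempotence within tolerance (the soft edge re-weights the single
  ## transition shell, so exact equality is not expected)
  lf2 <- lowpass_filter(lf, 8)
  expect_gt(map_cc(lf2, lf), 0.99)
  expect_lt(sd(lf2$values - lf$values), 0.15 * sd(lf$values))
  const <- density_map(array(3, c(8, 8, 8)), 2)
  expect_map_equal(lowpass_filter(const, 8), const, tol = 1e-10)
  expect_error(lowpass_filter(m, 3), "Nyquist")
})

test_that("transform_map: identity exact, lattice rotations exact, inverse recovers", {
  m <- random_map(16, voxel = 2, seed = 11)
  expect_identical(transform_map(m, pose()), m)
  ## 90 degrees about z permutes the lattice: out[i,j,k] = in[j, n+1-i, k]
  r90 <- transform_map(m, pose(c(90, 0, 0)))
  n <- 16
  expected <- array(0, dim(m$values))
  for (i in 1:n) for (j in 1:n) expected[i, j, ] <- m$values[j, n + 1 - i, ]
  expect_lt(max(abs(r90$values - expected)), 1e-9)
  ## smooth phantom: transform then inverse-transform correlates >= 0.99
  ym <- y_map(voxel = 2, box = 64)
  tp <- pose(c(25, 10, 5), c(3, -2, 1))
  back <- transform_map(transform_map(ym, tp), pose_invert(tp))
  expect_gt(map_cc(back, ym), 0.99)
})

test_that("symmetrize is a C-symmetric projection that preserves the mean", {
  ym <- y_map()
  expect_identical(symmetrize(ym, 1), ym)
  s8 <- symmetrize(ym, 8)
  expect_gt(map_cc(s8, transform_map(s8, pose(c(45, 0, 0)))), 0.999)
  expect_equal(mean(s8$values), mean(ym$values), tolerance = 1e-3)
  ## symmetrizing an analytically C8-symmetric phantom changes voxel
  ## RMS by < 1% of map RMS (interpolation error only)
  ring <- ring_phantom(ring_spec(copies = 8, radius = 20), voxel = 1.5,
                       box = 78, res = 8)$map
  ring8 <- symmetrize(ring, 8)
  expect_lt(sd(ring8$values - ring$values), 0.01 * sd(ring$values))
  ## projection: symmetrize(symmetrize(m)) == symmetrize(m) within the
  ## same interpolation tolerance
  ring88 <- symmetrize(ring8, 8)
  expect_lt(sd(ring88$values - ring8$values), 0.01 * sd(ring8$values))
  expect_error(symmetrize(ym, 0), "order")
})

test_that("missing wedge zeroes the analytic solid-angle fraction and projects", {
  m <- random_map(48, voxel = 2, seed = 13)
  full <- apply_wedge(m, wedge_descriptor(-90, 90))
  expect_map_equal(full, m, tol = 1e-9)
  w <- wedge_descriptor(-60, 60)
  out <- apply_wedge(m, w)
  ## count zeroed coefficients inside the Nyquist disc of the tilt plane,
  ## where the analytic fraction (90 - 60)/90 * ... = 1/3 applies
  fa <- fft(out$values)
  fr <- function(n) (((0:(n - 1)) + n %/% 2) %% n - n %/% 2) / n
  f1 <- fr(48)
  kx <- array(rep(f1, 48 * 48), c(48, 48, 48))
  kz <- array(rep(f1, each = 48 * 48), c(48, 48, 48))
  disc <- sqrt(kx^2 + kz^2) <= 0.5 & sqrt(kx^2 + kz^2) > 0
  zeroed <- abs(fa) < 1e-8 * max(abs(fa))
  expect_equal(mean(zeroed[disc]), 1 / 3, tolerance = 0.02)
  ## projection: applying twice equals applying once
  expect_map_equal(apply_wedge(out, w), out, tol = 1e-9)
  ## wedge and low-pass are both Fourier masks, so they commute
  a <- lowpass_filter(apply_wedge(m, w), 8)
  b <- apply_wedge(lowpass_filter(m, 8), w)
  expect_map_equal(a, b, tol = 1e-9)
  expect_error(wedge_descriptor(60, -60), "tilt_min")
  expect_error(wedge_descriptor(-95, 60), "90")
})

test_that("FSC is 1 against itself, near zero against noise, and locates the band limit", {
  ym <- y_map(voxel = 2, box = 64)
  fs <- fsc(ym, ym)
  expect_true(all(abs(fs$fsc[fs$n_voxels > 0] - 1) < 1e-9))
  ## against independent noise, shell values stay within sampling error
  nz <- random_map(32, voxel = 2, seed = 17)
  fn <- fsc(ym, nz)
  ok <- fn$n_voxels > 10
  expect_true(all(abs(fn$fsc[ok]) < 3 / sqrt(fn$n_voxels[ok])))
  expect_error(fsc(ym, random_map(16, 2)), "mismatch")
  ## linear interpolation of the threshold crossing
  curve <- data.frame(freq = c(0, 0.1, 0.2, 0.3), fsc = c(1, 1, 0.1, 0),
                      n_voxels = 1)
  ## crossing 0.143 between 0.1 and 0.2: t = (1-0.143)/0.9
  f_star <- 0.1 + (1 - 0.143) / (1 - 0.1) * 0.1
  expect_equal(resolution_at(curve, 0.143), 1 / f_star, tolerance = 1e-12)
})

test_that("two half-set averages resolve at the rendering resolution", {
  ## phantom rendered at 4 nm; with mild noise the FSC 0.143 crossing is
  ## set by the signal band limit, i.e. ~the rendering resolution
  spec <- ring_spec(copies = 8, radius = 20)
  asm <- build_assembly(spec, default_subunits())
  amap <- render_density(asm$model, 1.5, 72, 4)
  mk_half <- function(seed, n = 8) {
    acc <- 0
    for (i in seq_len(n)) {
      set.seed(seed + i)
      acc <- acc + amap$values +
        array(rnorm(length(amap$values), 0,
                    0.65 * sd(amap$values)), dim(amap$values))
    }
    density_map(acc / n, amap$voxel_size, amap$origin)
  }
  h1 <- mk_half(1000); h2 <- mk_half(2000)
  res <- resolution_at(fsc(h1, h2), 0.143)
  step <- 1 / (1 / 4 - 1 / (48 * 1.5))   # one voxel-frequency step coarser
  expect_gt(res, 1 / (1 / 4 + 1 / (48 * 1.5)))
  expect_lt(res, step)
})
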