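## Fourier-space and geometric operations on density maps.
## All spectral masks act on the unshifted FFT layout (DC at [1,1,1]).

.npcfit_cache <- new.env(parent = emptyenv())

fftn <- function(x) stats::fft(x)
ifftn_re <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

fft_freqs <- function(n) (((0:(n - 1)) + n %/% 2) %% n - n %/% 2) / n

## Per-axis frequency arrays in cycles/voxel, cached by grid size.
freq_grids <- function(d) {
  key <- paste0("fq", paste(d, collapse = "x"))
  g <- .npcfit_cache[[key]]
  if (is.null(g)) {
    f1 <- fft_freqs(d[1]); f2 <- fft_freqs(d[2]); f3 <- fft_freqs(d[3])
    g <- list(fx = array(rep(f1, times = d[2] * d[3]), d),
              fy = array(rep(rep(f2, each = d[1]), times = d[3]), d),
              fz = array(rep(f3, each = d[1] * d[2]), d))
    .npcfit_cache[[key]] <- g
  }
  g
}

## Voxel-centre index grid (3 x prod(d) matrix, 1-based), cached.
index_grid <- function(d) {
  key <- paste0("ix", paste(d, collapse = "x"))
  g <- .npcfit_cache[[key]]
  if (is.null(g)) {
    g <- rbind(rep(seq_len(d[1]), times = d[2] * d[3]),
               rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
               rep(seq_len(d[3]), each = d[1] * d[2]))
    .npcfit_cache[[key]] <- g
  }
  g
}

## Trilinear interpolation of `arr` at continuous 1-based voxel coords
## (3 x N matrix).  Points outside the grid evaluate to `fill`.
trilinear <- function(arr, pts, fill = 0) {
  d <- dim(arr)
  x <- pts[1, ]; y <- pts[2, ]; z <- pts[3, ]
  i0 <- floor(x); j0 <- floor(y); k0 <- floor(z)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  ## snap fp epsilon so exact lattice transforms stay exact at edges
  snap <- function(i0, f) {
    lo <- f < 1e-9; f[lo] <- 0
    hi <- f > 1 - 1e-9; i0[hi] <- i0[hi] + 1L; f[hi] <- 0
    list(i0 = i0, f = f)
  }
  s <- snap(i0, fx); i0 <- s$i0; fx <- s$f
  s <- snap(j0, fy); j0 <- s$i0; fy <- s$f
  s <- snap(k0, fz); k0 <- s$i0; fz <- s$f
  ok <- i0 >= 1 & j0 >= 1 & k0 >= 1 & i0 <= d[1] & j0 <= d[2] & k0 <= d[3] &
        (i0 + (fx > 0)) <= d[1] & (j0 + (fy > 0)) <= d[2] & (k0 + (fz > 0)) <= d[3]
  out <- rep(fill, length(x))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  i1 <- pmin(i0 + 1L, d[1]); j1 <- pmin(j0 + 1L, d[2]); k1 <- pmin(k0 + 1L, d[3])
  n1 <- d[1]; n12 <- d[1] * d[2]
  lin <- function(i, j, k) i + (j - 1L) * n1 + (k - 1L) * n12
  v <- arr[lin(i0, j0, k0)] * (1 - fx) * (1 - fy) * (1 - fz) +
       arr[lin(i1, j0, k0)] * fx       * (1 - fy) * (1 - fz) +
       arr[lin(i0, j1, k0)] * (1 - fx) * fy       * (1 - fz) +
       arr[lin(i1, j1, k0)] * fx       * fy       * (1 - fz) +
       arr[lin(i0, j0, k1)] * (1 - fx) * (1 - fy) * fz +
       arr[lin(i1, j0, k1)] * fx       * (1 - fy) * fz +
       arr[lin(i0, j1, k1)] * (1 - fx) * fy       * fz +
       arr[lin(i1, j1, k1)] * fx       * fy       * fz
  out[ok] <- v
  out
}

#' Low-pass filter a map
#'
#' Fourier mask with a raised-cosine (soft) edge one frequency shell
#' wide, centred on the cut-off `1/cutoff_nm`.  The soft edge suppresses
#' the real-space ringing a hard mask would introduce, which matters for
#' the cross-correlation scores downstream.  The DC term passes
#' unattenuated, so the real-space mean is preserved.
#'
#' @param map a [density_map()].
#' @param cutoff_nm cut-off as a real-space period in nm; must be at
#'   least `2 * voxel_size` (Nyquist).
#' @return filtered `density_map` on the same grid.
#' @export
lowpass_filter <- function(map, cutoff_nm) {
  stopifnot(is_density_map(map))
  if (cutoff_nm < 2 * map$voxel_size)
    stop("cutoff_nm (", cutoff_nm, ") is below Nyquist (",
         2 * map$voxel_size, " nm) for this voxel size")
  d <- dim(map$values)
  g <- freq_grids(d)
  r <- sqrt(g$fx^2 + g$fy^2 + g$fz^2) / map$voxel_size   # cycles/nm
  fc <- 1 / cutoff_nm
  dw <- 1 / (max(d) * map$voxel_size)                    # one shell width
  w <- ifelse(r <= fc, 1,
              ifelse(r >= fc + dw, 0, 0.5 * (1 + cos(pi * (r - fc) / dw))))
  out <- ifftn_re(fftn(map$values) * w)
  density_map(array(out, d), map$voxel_size, map$origin)
}

#' Missing-wedge descriptor
#'
#' Describes the un-sampled ("missing wedge") region of Fourier space
#' for single-axis tomography with tilt angles in `[tilt_min, tilt_max]`
#' degrees about `tilt_axis` (the beam is along z).  A Fourier point is
#' sampled iff some tilted central section passes through it.  `rot`
#' optionally carries a rotation applied to the wedge (used when
#' subvolumes are rotated during averaging/extraction).
#'
#' @param tilt_min,tilt_max tilt range in degrees, `-90 <= tilt_min <
#'   tilt_max <= 90`; the full range `(-90, 90)` leaves no missing
#'   region.
#' @param tilt_axis `"y"` (default) or `"x"`.
#' @param rot optional 3x3 rotation matrix applied to the wedge.
#' @return an object of class `wedge`.
#' @export
wedge_descriptor <- function(tilt_min = -60, tilt_max = 60, tilt_axis = "y",
                             rot = NULL) {
  if (!(tilt_min < tilt_max)) stop("tilt_min must be < tilt_max")
  if (tilt_min < -90 || tilt_max > 90)
    stop("tilt angles must lie within [-90, 90] degrees")
  tilt_axis <- match.arg(tilt_axis, c("y", "x"))
  structure(list(tilt_min = tilt_min, tilt_max = tilt_max,
                 tilt_axis = tilt_axis, rot = rot),
            class = "wedge")
}

#' Binary Fourier mask of the sampled region for a wedge
#' @param d grid dimensions.
#' @param wedge a [wedge_descriptor()] or `NULL` (fully sampled).
#' @return logical array, `TRUE` where Fourier space is sampled.
#' @export
wedge_mask <- function(d, wedge) {
  if (is.null(wedge)) return(array(TRUE, d))
  stopifnot(inherits(wedge, "wedge"))
  g <- freq_grids(d)
  kx <- g$fx; ky <- g$fy; kz <- g$fz
  if (!is.null(wedge$rot)) {
    R <- wedge$rot
    ## rotate wedge by R == evaluate base wedge at R^-1 k
    kx2 <- R[1, 1] * kx + R[2, 1] * ky + R[3, 1] * kz
    ky2 <- R[1, 2] * kx + R[2, 2] * ky + R[3, 2] * kz
    kz2 <- R[1, 3] * kx + R[2, 3] * ky + R[3, 3] * kz
    kx <- kx2; ky <- ky2; kz <- kz2
  }
  ## in-plane axis orthogonal to the tilt axis
  kp <- if (wedge$tilt_axis == "y") kx else ky
  ## A point is sampled iff some central section at tilt theta contains it:
  ## kp*sin(theta) + kz*cos(theta) = 0  =>  tan(theta) = -kz/kp.
  ratio <- ifelse(kp == 0, ifelse(kz == 0, 0, Inf), -kz / kp)
  theta <- rad2deg(atan(ratio))
  m <- (theta >= wedge$tilt_min & theta <= wedge$tilt_max) |
       (kp == 0 & kz == 0)                       # ky axis always sampled
  array(m, d)
}

#' Apply a missing wedge to a map
#'
#' Zeroes all Fourier coefficients inside the missing-wedge region; the
#' output is real because the sampled region is symmetric under
#' `k -> -k`.  Applying the same wedge twice equals applying it once
#' (the operation is a projection).
#'
#' @param map a [density_map()].
#' @param wedge a [wedge_descriptor()] or `NULL` for no-op.
#' @return the corrupted `density_map`.
#' @export
apply_wedge <- function(map, wedge) {
  stopifnot(is_density_map(map))
  if (is.null(wedge)) return(map)
  d <- dim(map$values)
  m <- wedge_mask(d, wedge)
  out <- ifftn_re(fftn(map$values) * m)
  density_map(array(out, d), map$voxel_size, map$origin)
}

## Resample `map` under pose: output voxel at physical point p takes the
## input value at R^-1 (p - c - t) + c, c = grid centre.  Trilinear.
#' Rigid-body transform of a map
#'
#' Applies pose `p` (rotation about the grid centre, then translation)
#' and resamples by trilinear interpolation.  The identity pose returns
#' the input unchanged (exactly); rotations that map the lattice onto
#' itself (multiples of 90 degrees about a grid axis) are exact up to
#' floating point.
#'
#' @param map a [density_map()].
#' @param p a [pose()].
#' @return transformed `density_map` on the same grid.
#' @export
transform_map <- function(map, p) {
  stopifnot(is_density_map(map), inherits(p, "pose"))
  if (is_identity_pose(p)) return(map)
  d <- dim(map$values)
  R <- pose_matrix(p)
  cvox <- (d + 1) / 2
  idx <- index_grid(d)
  rel <- (idx - cvox) * map$voxel_size
  rel[1, ] <- rel[1, ] - p$shift[1]
  rel[2, ] <- rel[2, ] - p$shift[2]
  rel[3, ] <- rel[3, ] - p$shift[3]
  src <- crossprod(R, rel) / map$voxel_size + cvox     # R^T == R^-1
  vals <- trilinear(map$values, src)
  density_map(array(vals, d), map$voxel_size, map$origin)
}

#' Impose rotational (Cn) symmetry on a map
#'
#' Averages the map over rotations by `k * 360/order` degrees about the
#' given grid axis through the grid centre.  The result is invariant
#' (within interpolation tolerance) under rotation by `360/order`, and
#' symmetrizing twice equals symmetrizing once.
#'
#' @param map a [density_map()].
#' @param order symmetry order, integer >= 1.
#' @param axis `"z"` (default), `"y"` or `"x"`.
#' @return symmetrized `density_map`.
#' @export
symmetrize <- function(map, order, axis = "z") {
  stopifnot(is_density_map(map))
  if (!is.numeric(order) || order < 1 || order != round(order))
    stop("`order` must be an integer >= 1")
  axis <- match.arg(axis, c("z", "y", "x"))
  if (order == 1) return(map)
  acc <- map$values
  for (k in seq_len(order - 1)) {
    ang <- 360 * k / order
    p <- switch(axis,
                z = pose(c(ang, 0, 0)),
                y = pose(matrix_to_euler(rot_y(ang))),
                x = pose(matrix_to_euler(rot_x(ang))))
    acc <- acc + transform_map(map, p)$values
  }
  density_map(acc / order, map$voxel_size, map$origin)
}

#' Fourier shell correlation between two maps
#'
#' Per-shell normalised correlation of the two spectra; shells are one
#' frequency step `1/(n * voxel_size)` wide.
#'
#' @param map_a,map_b maps on the same grid.
#' @return data.frame with columns `freq` (cycles/nm, shell centre),
#'   `fsc`, and `n_voxels` per shell.
#' @export
fsc <- function(map_a, map_b) {
  stopifnot(is_density_map(map_a), is_density_map(map_b))
  check_same_grid(map_a, map_b)
  d <- dim(map_a$values)
  n <- max(d)
  g <- freq_grids(d)
  shell <- round(sqrt(g$fx^2 + g$fy^2 + g$fz^2) * n)
  smax <- n %/% 2
  keep <- shell <= smax
  fa <- fftn(map_a$values); fb <- fftn(map_b$values)
  sh <- factor(as.integer(shell[keep]) + 1L, levels = seq_len(smax + 1L))
  num <- vapply(split(Re(fa[keep] * Conj(fb[keep])), sh), sum, 0)
  da <- vapply(split(abs(fa[keep])^2, sh), sum, 0)
  db <- vapply(split(abs(fb[keep])^2, sh), sum, 0)
  cnt <- tabulate(sh, nbins = smax + 1L)
  den <- sqrt(da * db)
  data.frame(freq = (0:smax) / (n * map_a$voxel_size),
             fsc = ifelse(den > 0, num / den, 0),
             n_voxels = cnt,
             row.names = NULL)
}

#' Resolution at an FSC threshold
#'
#' Inverse of the frequency at which the FSC curve first drops below
#' `threshold`, linearly interpolated between shells.  If the curve
#' never crosses, the finest sampled frequency is used (the estimate is
#' then Nyquist-limited).
#'
#' @param curve data.frame from [fsc()].
#' @param threshold FSC criterion; 0.143 by default, 0.5 by convention
#'   for independently refined halves vs. a noise-free reference.
#' @return resolution in nm.
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  f <- curve$freq; v <- curve$fsc
  below <- which(v < threshold & f > 0)
  if (length(below) == 0) return(1 / max(f))
  i <- below[1]
  if (i == 1) return(1 / f[1])
  ## linear interpolation between shells i-1 and i
  t <- (v[i - 1] - threshold) / (v[i - 1] - v[i])
  fc <- f[i - 1] + t * (f[i] - f[i - 1])
  1 / fc
}
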