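## Missing-wedge-aware alignment and iterative averaging.

#' Wedge-constrained cross-correlation
#'
#' Normalised correlation of two volumes computed only over the Fourier
#' region sampled by *both* wedges (the constrained cross-correlation of
#' missing-wedge tomography).  The DC term is excluded, making the
#' value a correlation in `[-1, 1]`.
#'
#' @param volume,reference maps on the same grid.
#' @param wedge_v,wedge_r wedges of the two volumes (`NULL` = fully
#'   sampled).
#' @return scalar score in `[-1, 1]`.
#' @export
constrained_cc <- function(volume, reference, wedge_v = NULL,
                           wedge_r = NULL) {
  stopifnot(is_density_map(volume), is_density_map(reference))
  check_same_grid(volume, reference)
  d <- dim(volume$values)
  m <- wedge_mask(d, wedge_v) & wedge_mask(d, wedge_r)
  m[1, 1, 1] <- FALSE                           # exclude DC
  if (!any(m)) stop("wedges have empty Fourier overlap")
  fv <- fftn(volume$values)[m]
  fr <- fftn(reference$values)[m]
  den <- sqrt(sum(abs(fv)^2) * sum(abs(fr)^2))
  if (den == 0) return(0)
  max(-1, min(1, sum(Re(fv * Conj(fr))) / den))
}

## Translation scan of constrained CC: returns the real-space array of
## (unnormalised-shift) constrained correlation values; normalisation
## uses the global masked norms, standard in subtomogram averaging.
constrained_cc_scan <- function(volume, reference, wedge_v, wedge_r) {
  d <- dim(volume$values)
  m <- wedge_mask(d, wedge_v) & wedge_mask(d, wedge_r)
  m[1, 1, 1] <- FALSE
  fv <- fftn(volume$values) * m
  fr <- fftn(reference$values) * m
  den <- sqrt(sum(abs(fv)^2) * sum(abs(fr)^2)) / length(fv)
  if (den == 0) return(array(0, d))
  ifftn_re(fv * Conj(fr)) / den
}

## In-plane (+ small cone) rotation set used to align whole particles.
particle_rotation_set <- function(angular_step, cone_deg = 8,
                                  cone_step = NULL) {
  azs <- seq(0, 360 - angular_step, by = angular_step)
  if (is.null(cone_step)) cone_step <- cone_deg
  tilts <- unique(c(0, if (cone_deg > 0) c(-cone_deg, cone_deg)))
  rots <- list()
  for (az in azs) for (t1 in tilts) for (t2 in tilts)
    rots[[length(rots) + 1]] <-
      matrix_to_euler(rot_z(az) %*% rot_y(t1) %*% rot_x(t2))
  do.call(rbind, rots)
}

#' Align one particle to a reference
#'
#' Grid search over rotations (in-plane azimuths at `angular_step`
#' degrees crossed with a small out-of-plane cone) with, for each
#' rotation, a wedge-constrained translational correlation scan; the
#' returned pose maximises the constrained CC.  Ties are broken by the
#' smaller rotation angle, then lexicographically on the pose.
#'
#' The pose maps the *reference frame into the particle frame* — i.e.
#' `transform_map(particle, pose_invert(pose))` is the particle aligned
#' onto the reference.
#'
#' @param particle a [subtomo()].
#' @param reference a [density_map()].
#' @param angular_step in-plane angular step in degrees.
#' @param max_shift maximum translation in nm (must be < box/4).
#' @param cone_deg out-of-plane search cone half-angle (degrees).
#' @return a [pose()] with attribute `"score"`.
#' @export
align_particle <- function(particle, reference, angular_step = 15,
                           max_shift = 8, cone_deg = 0) {
  stopifnot(inherits(particle, "subtomo"), angular_step > 0)
  d <- dim(particle$map$values)
  vx <- particle$map$voxel_size
  if (max_shift >= min(d) * vx / 4)
    stop("max_shift must be below a quarter of the box")
  angs <- particle_rotation_set(angular_step, cone_deg)
  ## shift lattice allowed around zero (circular FFT indices)
  ms_vox <- floor(max_shift / vx)
  off <- fft_freqs_idx(d, ms_vox)
  best <- NULL
  for (i in seq_len(nrow(angs))) {
    a <- angs[i, ]
    rref <- transform_map(reference, pose(a))
    cc <- constrained_cc_scan(particle$map, rref, particle$wedge, NULL)
    sub <- cc[off$ix, off$iy, off$iz, drop = FALSE]
    j <- which.max(sub)
    sc <- sub[j]
    jj <- arrayInd(j, dim(sub))
    sh <- c(off$sx[jj[1]], off$sy[jj[2]], off$sz[jj[3]]) * vx
    cand <- list(angles = a, shift = sh, score = sc,
                 rotang = rotation_distance(c(0, 0, 0), a))
    if (is.null(best) || sc > best$score + 1e-12 ||
        (abs(sc - best$score) <= 1e-12 &&
         (cand$rotang < best$rotang - 1e-9 ||
          (abs(cand$rotang - best$rotang) <= 1e-9 &&
           pose_lex_less(cand, best)))))
      best <- cand
  }
  p <- pose(best$angles, best$shift)
  attr(p, "score") <- best$score
  p
}

pose_lex_less <- function(a, b) {
  va <- c(a$angles, a$shift); vb <- c(b$angles, b$shift)
  i <- which(abs(va - vb) > 1e-9)
  if (!length(i)) return(FALSE)
  va[i[1]] < vb[i[1]]
}

## circular FFT shift indices within +/- ms voxels
fft_freqs_idx <- function(d, ms) {
  pick <- function(n) {
    s <- c(0:min(ms, n %/% 2), if (ms >= 1) -(1:min(ms, (n - 1) %/% 2)))
    list(idx = (s %% n) + 1L, s = s)
  }
  px <- pick(d[1]); py <- pick(d[2]); pz <- pick(d[3])
  list(ix = px$idx, iy = py$idx, iz = pz$idx,
       sx = px$s, sy = py$s, sz = pz$s)
}

rotate_wedge <- function(wedge, angles) {
  if (is.null(wedge)) return(NULL)
  R <- pose_matrix(pose(angles))
  base <- if (is.null(wedge$rot)) diag(3) else wedge$rot
  w <- wedge
  w$rot <- R %*% base
  w
}

#' Iterative missing-wedge-weighted averaging
#'
#' Each iteration aligns every particle to the current reference,
#' computes a wedge-compensated average (sum of the aligned particles'
#' Fourier data divided by the summed wedge coverage, floored at
#' `floor_frac` of the mean coverage to avoid division blow-up where
#' few particles sample a Fourier voxel), and symmetrizes by
#' `symmetry_order`.
#'
#' @param particles list of [subtomo()] (>= 2).
#' @param initial_reference starting [density_map()].
#' @param n_iter number of iterations.
#' @param symmetry_order imposed Cn order (1 = none).
#' @param angular_step,max_shift,cone_deg alignment search parameters
#'   (see [align_particle()]).
#' @param floor_frac coverage floor as a fraction of mean coverage.
#' @param tol convergence tolerance `c(degrees, nm)` on the mean pose
#'   update of the final iteration.
#' @return list with `average` ([density_map()]) and `state` (list:
#'   per-particle `poses`, per-iteration mean angular/translational
#'   update `delta`, `converged` flag at `tol`).
#' @export
iterative_average <- function(particles, initial_reference, n_iter = 3,
                              symmetry_order = 8, angular_step = 15,
                              max_shift = 8, cone_deg = 0,
                              floor_frac = 0.1, tol = c(2, 1)) {
  stopifnot(length(particles) >= 2)
  ref <- initial_reference
  poses <- rep(list(pose()), length(particles))
  delta <- data.frame(iter = integer(), mean_ang = numeric(),
                      mean_trans = numeric())
  for (it in seq_len(n_iter)) {
    new_poses <- lapply(particles, align_particle, reference = ref,
                        angular_step = angular_step,
                        max_shift = max_shift, cone_deg = cone_deg)
    dang <- mean(mapply(function(a, b)
      rotation_distance(a$angles, b$angles), poses, new_poses))
    dtr <- mean(mapply(function(a, b)
      sqrt(sum((a$shift - b$shift)^2)), poses, new_poses))
    delta <- rbind(delta, data.frame(iter = it, mean_ang = dang,
                                     mean_trans = dtr))
    poses <- new_poses
    ref <- wedge_weighted_average(particles, poses, floor_frac)
    if (symmetry_order > 1) ref <- symmetrize(ref, symmetry_order)
  }
  conv <- nrow(delta) >= 2 &&
    delta$mean_ang[nrow(delta)] <= tol[1] &&
    delta$mean_trans[nrow(delta)] <= tol[2]
  list(average = ref,
       state = list(poses = poses, delta = delta, converged = conv))
}

#' Wedge-compensated average of aligned particles
#'
#' Brings each particle into the reference frame with the inverse of
#' its pose, accumulates Fourier data and rotated wedge coverage, and
#' divides by the coverage with a floor.
#'
#' @param particles list of [subtomo()].
#' @param poses list of [pose()]s from [align_particle()].
#' @param floor_frac coverage floor fraction.
#' @return a [density_map()].
#' @export
wedge_weighted_average <- function(particles, poses, floor_frac = 0.1) {
  d <- dim(particles[[1]]$map$values)
  num <- array(0 + 0i, d); cov <- array(0, d)
  for (i in seq_along(particles)) {
    pinv <- pose_invert(poses[[i]])
    al <- transform_map(particles[[i]]$map, pinv)
    w <- rotate_wedge(particles[[i]]$wedge, pinv$angles)
    wm <- wedge_mask(d, w)
    num <- num + fftn(al$values) * wm
    cov <- cov + wm
  }
  fl <- max(floor_frac * mean(cov), .Machine$double.eps)
  avg <- ifftn_re(num / pmax(cov, fl))
  density_map(array(avg, d), particles[[1]]$map$voxel_size,
              particles[[1]]$map$origin)
}

#' Extract symmetry-related asymmetric units
#'
#' For each aligned particle, rotates the particle into the reference
#' frame, then for every symmetry position `k = 0..order-1` rotates by
#' `k * 360/order` about z and crops a `unit_box` cube centred on the
#' asymmetric-unit anchor (by default the mid-radius point on the +x
#' axis).  Wedge descriptors are rotated consistently.  Output length
#' is `length(particles) * symmetry_order`.
#'
#' @param particles list of [subtomo()].
#' @param poses aligned poses (reference -> particle), one per particle.
#' @param symmetry_order Cn order.
#' @param unit_box unit cube side in voxels.
#' @param unit_center physical anchor of the unit centre (nm), default
#'   `c(r_mid, 0, 0)` with `r_mid` a quarter of the box extent.
#' @return list of [subtomo()] of the units.
#' @export
extract_asymmetric_units <- function(particles, poses, symmetry_order = 8,
                                     unit_box = NULL, unit_center = NULL) {
  stopifnot(length(particles) == length(poses))
  d <- dim(particles[[1]]$map$values)
  vx <- particles[[1]]$map$voxel_size
  if (is.null(unit_box)) unit_box <- d[1] %/% 2
  if (any(unit_box > d))
    stop("unit_box exceeds the particle box")
  if (is.null(unit_center)) unit_center <- c(d[1] * vx / 4, 0, 0)
  units <- vector("list", length(particles) * symmetry_order)
  n <- 0
  for (i in seq_along(particles)) {
    pinv <- pose_invert(poses[[i]])
    al <- transform_map(particles[[i]]$map, pinv)
    w0 <- rotate_wedge(particles[[i]]$wedge, pinv$angles)
    for (k in seq_len(symmetry_order) - 1) {
      ang <- c(-k * 360 / symmetry_order, 0, 0)
      rot <- transform_map(al, pose(ang))
      wk <- rotate_wedge(w0, ang)
      cen_vox <- round(unit_center / vx + (d + 1) / 2)
      h <- unit_box %/% 2
      ir <- (cen_vox[1] - h):(cen_vox[1] + h - 1 + unit_box %% 2)
      jr <- (cen_vox[2] - h):(cen_vox[2] + h - 1 + unit_box %% 2)
      kr <- (cen_vox[3] - h):(cen_vox[3] + h - 1 + unit_box %% 2)
      if (min(ir, jr, kr) < 1 || max(ir) > d[1] || max(jr) > d[2] ||
          max(kr) > d[3])
        stop("unit_box at the unit centre falls outside the particle box")
      vals <- rot$values[ir, jr, kr, drop = FALSE]
      n <- n + 1
      units[[n]] <- subtomo(
        density_map(array(vals, rep(unit_box, 3)), vx),
        wk, true_pose = NULL, snr = particles[[i]]$snr)
    }
  }
  units
}

#' Mask-focused per-ring refinement
#'
#' Re-aligns units against the average restricted to each ring mask
#' (the mask multiplies the reference before scoring), and returns one
#' refined average per ring.  With an all-ones mask this reduces to
#' unmasked refinement.
#'
#' @param units list of [subtomo()] asymmetric units.
#' @param ring_masks named list of mask [density_map()]s on the unit
#'   grid (binary or soft, non-empty).
#' @param angular_step,max_shift alignment parameters.
#' @param floor_frac averaging coverage floor.
#' @return named list of refined [density_map()]s, one per ring.
#' @export
masked_refine <- function(units, ring_masks, angular_step = 10,
                          max_shift = 4, floor_frac = 0.1) {
  stopifnot(length(units) >= 2, length(ring_masks) >= 1)
  raw <- wedge_weighted_average(units, rep(list(pose()), length(units)),
                                floor_frac)
  out <- list()
  for (nm in names(ring_masks)) {
    msk <- ring_masks[[nm]]
    stopifnot(is_density_map(msk))
    if (all(msk$values == 0)) stop("empty mask: ", nm)
    mref <- density_map(raw$values * msk$values, raw$voxel_size,
                        raw$origin)
    poses <- lapply(units, align_particle, reference = mref,
                    angular_step = angular_step, max_shift = max_shift)
    ref <- wedge_weighted_average(units, poses, floor_frac)
    out[[nm]] <- density_map(ref$values * msk$values +
                             raw$values * (1 - msk$values),
                             ref$voxel_size, ref$origin)
  }
  out
}
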