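#' Synthetic subtomogram container
#'
#' A simulated particle: the corrupted map, the wedge it was corrupted
#' with, the true pose the assembly was transformed by (kept only for
#' scoring against ground truth; alignment must not look at it), and
#' the nominal SNR.
#'
#' @param map a [density_map()].
#' @param wedge a [wedge_descriptor()] (required).
#' @param true_pose a [pose()] or `NULL`.
#' @param snr signal-to-noise variance ratio, or `Inf` for noise-free.
#' @return object of class `subtomo`.
#' @export
subtomo <- function(map, wedge, true_pose = NULL, snr = Inf) {
  stopifnot(is_density_map(map), inherits(wedge, "wedge"))
  if (!(is.infinite(snr) || snr > 0)) stop("snr must be > 0 or Inf")
  structure(list(map = map, wedge = wedge, true_pose = true_pose,
                 snr = snr),
            class = "subtomo")
}

#' Simulate one particle subtomogram
#'
#' Draws a true pose (uniform in-plane azimuth; Gaussian out-of-plane
#' tilt of sd `tilt_sd` degrees; Gaussian shift of sd `shift_sd` nm),
#' transforms the assembly map by it, applies the missing wedge, and
#' adds white Gaussian noise scaled so that
#' `var(signal) / var(noise) = snr` over the whole box.  Deterministic
#' given `seed`.
#'
#' @param assembly_map noise-free [density_map()] of the assembly.
#' @param wedge a [wedge_descriptor()].
#' @param snr variance ratio (`Inf` = noise-free).
#' @param seed integer seed.
#' @param pose_true force a specific pose instead of drawing one.
#' @param tilt_sd,shift_sd pose-distribution scales (degrees, nm).
#' @return a [subtomo()].
#' @export
simulate_particle <- function(assembly_map, wedge, snr = 1, seed = 1,
                              pose_true = NULL, tilt_sd = 4, shift_sd = 2) {
  stopifnot(is_density_map(assembly_map))
  if (!(is.infinite(snr) || snr > 0)) stop("snr must be > 0 or Inf")
  withr_seed(seed, {
    if (is.null(pose_true)) {
      ax <- stats::runif(1, 0, 360)
      tl <- stats::rnorm(2, 0, tilt_sd)
      R <- rot_z(ax) %*% rot_y(tl[1]) %*% rot_x(tl[2])
      pose_true <- pose(matrix_to_euler(R), stats::rnorm(3, 0, shift_sd))
    }
    sig <- apply_wedge(transform_map(assembly_map, pose_true), wedge)
    vals <- sig$values
    if (is.finite(snr)) {
      nsd <- stats::sd(as.numeric(vals)) / sqrt(snr)
      vals <- vals + array(stats::rnorm(length(vals), 0, nsd), dim(vals))
    }
    subtomo(density_map(vals, sig$voxel_size, sig$origin),
            wedge, pose_true, snr)
  })
}

#' Generate a particle stack with ground truth
#'
#' Renders the assembly defined by `spec` once, then simulates
#' `n_particles` independently posed, wedge-corrupted, noisy copies.
#' A pure function of `(spec, seed)`.
#'
#' @param spec an [architecture_spec()].
#' @param n_particles number of particles (>= 1).
#' @param wedge a [wedge_descriptor()].
#' @param snr per-particle SNR (variance ratio).
#' @param seed integer seed; particle `i` uses `seed + i`.
#' @param voxel_size,box_nm,resolution_nm rendering parameters.
#' @param subunits named list of subunit models; defaults to
#'   [default_subunits()].
#' @return list with `particles` (list of [subtomo()]), `ground_truth`
#'   (placement table from [build_assembly()]), `poses` (data.frame of
#'   per-particle true poses) and `assembly_map`.
#' @export
generate_particle_set <- function(spec, n_particles, wedge, snr = 1,
                                  seed = 1, voxel_size = 4, box_nm = 128,
                                  resolution_nm = 6, subunits = NULL) {
  stopifnot(n_particles >= 1)
  if (is.null(subunits)) subunits <- default_subunits()
  asm <- build_assembly(spec, subunits)
  amap <- render_density(asm$model, voxel_size, box_nm, resolution_nm)
  particles <- lapply(seq_len(n_particles), function(i)
    simulate_particle(amap, wedge, snr, seed = seed + i))
  poses <- do.call(rbind, lapply(seq_along(particles), function(i) {
    p <- particles[[i]]$true_pose
    data.frame(particle = i, phi = p$angles[1], theta = p$angles[2],
               psi = p$angles[3], tx = p$shift[1], ty = p$shift[2],
               tz = p$shift[3])
  }))
  list(particles = particles, ground_truth = asm$ground_truth,
       poses = poses, assembly_map = amap)
}
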