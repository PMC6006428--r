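## End-to-end orchestration: the phantom fitting experiment, region
## masks, JSON-config runs with manifests.

#' Cylindrical z-slab region masks for the three NPC rings
#'
#' The cytoplasmic ring (CR) occupies `z > z_split`, the nuclear ring
#' (NR) `z < -z_split`, and the inner ring (IR) the slab between; the
#' three masks partition the grid.
#'
#' @param map a [density_map()] defining the grid (z measured from the
#'   grid centre).
#' @param z_split slab boundary in nm (default 15).
#' @return named list of binary mask [density_map()]s (`CR`, `IR`,
#'   `NR`).
#' @export
ring_region_masks <- function(map, z_split = 15) {
  d <- dim(map$values)
  z <- (index_grid(d)[3, ] - (d[3] + 1) / 2) * map$voxel_size
  mk <- function(sel) density_map(array(as.numeric(sel), d),
                                  map$voxel_size, map$origin)
  list(CR = mk(z > z_split),
       IR = mk(abs(z) <= z_split),
       NR = mk(z < -z_split))
}

#' Render and filter subunit models onto a target grid
#'
#' Renders each subunit at the grid centre at the stated resolution and
#' applies the same low-pass filter as the target map, yielding the
#' model maps used by the fitting stage.
#'
#' @param subunits named list of [bead_model()]s.
#' @param voxel_size,box_nm,resolution_nm rendering parameters.
#' @param lowpass_nm optional low-pass cut-off (nm).
#' @return named list of model [density_map()]s.
#' @export
prepare_fit_models <- function(subunits, voxel_size, box_nm,
                               resolution_nm, lowpass_nm = NULL) {
  lapply(subunits, function(su) {
    m <- render_density(su, voxel_size, box_nm, resolution_nm)
    if (!is.null(lowpass_nm)) m <- lowpass_filter(m, lowpass_nm)
    m
  })
}

#' Build a symmetrized particle average of an assembly phantom
#'
#' Simulates `n_particles` wedge-corrupted noisy particles of the
#' assembly map at random poses, seeds each with a small perturbation
#' of its true pose (standing in for the manual coarse orientation
#' step), refines the poses by one constrained-CC alignment pass,
#' computes the wedge-compensated average and imposes the rotational
#' symmetry.
#'
#' @param assembly_map noise-free rendered assembly [density_map()].
#' @param n_particles number of particles to average.
#' @param wedge a [wedge_descriptor()].
#' @param snr per-particle SNR.
#' @param seed RNG seed.
#' @param symmetry_order imposed Cn order.
#' @param perturb_rot,perturb_shift sd of the seeding perturbation
#'   (degrees about z, nm).
#' @param refine_step,refine_shift local refinement sampling: azimuth
#'   deltas at `refine_step` degrees (up to +/- 2 steps) composed with
#'   each seeded pose, and a translational scan within `refine_shift`
#'   nm; `refine_step = 0` skips refinement.
#' @return list with `average` ([density_map()]), `particles`, `poses`.
#' @export
average_phantom_particles <- function(assembly_map, n_particles = 16,
                                      wedge = wedge_descriptor(-60, 60),
                                      snr = 1, seed = 42,
                                      symmetry_order = 8,
                                      perturb_rot = 4, perturb_shift = 2,
                                      refine_step = 3, refine_shift = 6) {
  particles <- lapply(seq_len(n_particles), function(i)
    simulate_particle(assembly_map, wedge, snr, seed = seed + i))
  init <- lapply(seq_along(particles), function(i)
    withr_seed(seed + 7919L + i, {
      pert <- pose(c(stats::rnorm(1, 0, perturb_rot), 0, 0),
                   stats::rnorm(3, 0, perturb_shift))
      pose_compose(pert, particles[[i]]$true_pose)
    }))
  avg <- wedge_weighted_average(particles, init)
  if (symmetry_order > 1) avg <- symmetrize(avg, symmetry_order)
  poses <- init
  if (refine_step > 0) {
    poses <- lapply(seq_along(particles), function(i)
      refine_pose_local(particles[[i]], avg, init[[i]],
                        daz = refine_step * (-2:2),
                        max_shift = refine_shift))
    avg <- wedge_weighted_average(particles, poses)
    if (symmetry_order > 1) avg <- symmetrize(avg, symmetry_order)
  }
  list(average = avg, particles = particles, poses = poses)
}

## Local constrained-CC refinement of a seeded pose: azimuthal deltas
## composed with the seed (out-of-plane angles are retained), plus a
## translational correlation scan.
refine_pose_local <- function(particle, reference, init, daz = -6:6,
                              max_shift = 6) {
  vx <- particle$map$voxel_size
  d <- dim(particle$map$values)
  ms_vox <- floor(max_shift / vx)
  off <- fft_freqs_idx(d, ms_vox)
  best <- NULL
  for (a in daz) {
    ptry <- pose_compose(init, pose(c(a, 0, 0)))
    rref <- transform_map(reference, ptry)
    cc <- constrained_cc_scan(particle$map, rref, particle$wedge, NULL)
    sub <- cc[off$ix, off$iy, off$iz, drop = FALSE]
    j <- which.max(sub)
    jj <- arrayInd(j, dim(sub))
    sh <- c(off$sx[jj[1]], off$sy[jj[2]], off$sz[jj[3]]) * vx
    if (is.null(best) || sub[j] > best$score)
      best <- list(score = sub[j],
                   pose = pose(ptry$angles, ptry$shift + sh))
  }
  best$pose
}

#' The phantom copy-number experiment
#'
#' Builds the assembly phantom for `spec`, simulates a stack of
#' wedge-corrupted particles at the stated SNR, computes their
#' symmetrized wedge-compensated average (the structure-determination
#' stage), low-pass filters the average and the subunit models, then
#' runs the hierarchical fitting pipeline with each subunit searched in
#' the ring region(s) its copies occupy (mask-focused, as in per-ring
#' refinement) and counts accepted placements per region.
#'
#' @param spec an [architecture_spec()] (e.g. [crnpc_spec()]).
#' @param subunits named list of subunit models; default
#'   [default_subunits()].
#' @param voxel_size,box_nm,resolution_nm phantom rendering.
#' @param n_avg number of particles averaged into the fitting target
#'   (1 = fit the single raw particle).
#' @param snr particle SNR (variance ratio); `Inf` = noise-free.
#' @param wedge missing wedge; default +/-60 degrees.
#' @param seed RNG seed for the noise realisation.
#' @param angular_step,translation_step fitting search sampling.
#' @param alpha FDR level.
#' @param lowpass_nm low-pass applied to map and models (default 8 nm,
#'   the Nyquist limit at 4 nm voxels).
#' @param z_split ring region boundary (nm).
#' @param overlap_min,rescore_frac acceptance gates (see
#'   [hierarchical_fit()]).
#' @param trans_margin extra search radius beyond the widest ring (nm).
#' @return list with `counts` (per model x region), `assignment`,
#'   `ground_truth`, `target_map`, `region_masks`, `fit` (the full
#'   [hierarchical_fit()] result) and `model_maps`.
#' @export
fit_phantom_architecture <- function(spec, subunits = NULL,
                                     voxel_size = 4, box_nm = 128,
                                     resolution_nm = 6, n_avg = 16,
                                     snr = 1,
                                     wedge = wedge_descriptor(-60, 60),
                                     seed = 42, angular_step = 30,
                                     translation_step = 1, alpha = 0.05,
                                     lowpass_nm = 8, z_split = 15,
                                     overlap_min = 0.6,
                                     rescore_frac = 0.5,
                                     trans_margin = 10) {
  if (is.null(subunits)) subunits <- default_subunits()
  asm <- build_assembly(spec, subunits)
  amap <- render_density(asm$model, voxel_size, box_nm, resolution_nm)
  if (n_avg > 1) {
    avg <- average_phantom_particles(amap, n_particles = n_avg,
                                     wedge = wedge, snr = snr,
                                     seed = seed,
                                     symmetry_order = spec$symmetry_order)
    target <- avg$average
  } else {
    part <- simulate_particle(amap, wedge, snr, seed = seed,
                              pose_true = pose())
    target <- part$map
  }
  if (!is.null(lowpass_nm)) target <- lowpass_filter(target, lowpass_nm)
  masks <- ring_region_masks(target, z_split)
  labels <- unique(vapply(spec$rings, `[[`, "", "label"))
  model_maps <- prepare_fit_models(subunits[labels], voxel_size, box_nm,
                                   resolution_nm, lowpass_nm)
  region_of_ring <- function(r)
    if (r$z > z_split) "CR" else if (r$z < -z_split) "NR" else "IR"
  ## one search per (model, ring region): each ring map gets its own
  ## envelope threshold, as in mask-focused per-ring refinement
  combos <- unique(do.call(rbind, lapply(spec$rings, function(r)
    data.frame(label = r$label, region = region_of_ring(r)))))
  entries <- lapply(seq_len(nrow(combos)), function(i) {
    lb <- combos$label[i]; rg <- combos$region[i]
    rings <- Filter(function(r) r$label == lb && region_of_ring(r) == rg,
                    spec$rings)
    ## envelope volume budget: expected copies in this ring region, with
    ## a 50% smearing allowance for the elongated Y whose large-radius,
    ## tangentially overlapping copies blur the most under residual
    ## azimuthal alignment error; compact protomers need none
    list(label = lb, id = paste(lb, rg, sep = ":"),
         model_map = model_maps[[lb]], region_mask = masks[[rg]],
         volume_factor = (if (lb == "Y") 1.5 else 1) *
           sum(vapply(rings, `[[`, 0, "copies")),
         max_shift = max(vapply(rings, `[[`, 0, "radius")) + trans_margin,
         trans_tol = if (lb == "Y") 12 else 8)
  })
  ## largest model first
  sizes <- vapply(entries, function(e) sum(e$model_map$values > 0), 0)
  entries <- entries[order(-sizes)]
  fit <- hierarchical_fit(target, entries, alpha = alpha,
                          angular_step = angular_step,
                          translation_step = translation_step,
                          overlap_min = overlap_min,
                          rescore_frac = rescore_frac)
  counts <- count_copies(fit$assignment, masks)
  list(counts = counts, assignment = fit$assignment,
       ground_truth = asm$ground_truth, target_map = target,
       region_masks = masks, fit = fit, model_maps = model_maps)
}

## ---------------------------------------------------------------------
## JSON-config pipeline
## ---------------------------------------------------------------------

config_schema <- function() {
  list(
    seed = TRUE,
    phantom = list(architecture = TRUE, voxel_size = TRUE, box_nm = TRUE,
                   resolution_nm = TRUE, snr = TRUE,
                   wedge = list(tilt_min = TRUE, tilt_max = TRUE),
                   n_particles = TRUE),
    average = list(enabled = TRUE, n_iter = TRUE, angular_step = TRUE,
                   symmetry_order = TRUE, max_shift = TRUE),
    fit = list(enabled = TRUE, angular_step = TRUE,
               translation_step = TRUE, alpha = TRUE, lowpass_nm = TRUE,
               overlap_min = TRUE, rescore_frac = TRUE, z_split = TRUE),
    analyze = list(enabled = TRUE, contact_nm = TRUE),
    coexpr = list(enabled = TRUE, n_genes = TRUE, n_samples = TRUE,
                  within_module_corr = TRUE, modules = TRUE,
                  p_threshold = TRUE))
}

validate_config <- function(cfg, schema = config_schema(), path = "") {
  stopifnot(is.list(cfg))
  for (k in names(cfg)) {
    here <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(schema))
      stop("unknown config key: ", here)
    if (is.list(schema[[k]]) && is.list(cfg[[k]]))
      validate_config(cfg[[k]], schema[[k]], here)
  }
  invisible(TRUE)
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) + match(stage, c("generate", "average", "fit",
                                     "analyze", "coexpr")) * 10007L) %%
    2147483647L
}

#' Run the full pipeline from a JSON config
#'
#' Stages: `generate` (phantom + particles) -> `average` (optional
#' iterative averaging) -> `fit` (hierarchical fitting + copy counts)
#' -> `analyze` (register, geometry, head-to-tail) -> `coexpr`
#' (optional co-expression run on simulated expression data).  Every
#' stage derives its seed from the single global seed, writes its
#' outputs under `out_dir`, and is skipped if its outputs already
#' exist and `resume = TRUE`.  A `manifest.json` records the config
#' hash, seeds, package version and stage timings; a rerun with the
#' same config and seed reproduces the outputs.
#'
#' @param config path to a JSON config or an equivalent named list.
#'   Unknown keys are rejected with the offending key named.
#' @param out_dir output/run directory (created).
#' @param resume skip stages whose outputs exist.
#' @return invisibly, the run directory path.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  ph <- config$phantom %||% list()
  spec <- phantom_spec_from_config(ph$architecture %||% "crnpc")
  vx <- ph$voxel_size %||% 4
  box <- ph$box_nm %||% 128
  res <- ph$resolution_nm %||% 6
  snr <- ph$snr %||% 1
  wg <- wedge_descriptor(ph$wedge$tilt_min %||% -60,
                         ph$wedge$tilt_max %||% 60)
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[3]
    r <- force(expr)
    timings[[stage]] <<- round(proc.time()[3] - t0, 2)
    r
  }
  ## -- generate ------------------------------------------------------
  gt_path <- file.path(out_dir, "ground_truth.tsv")
  fitres <- NULL
  fit_cfg <- config$fit %||% list()
  if (!isFALSE(fit_cfg$enabled)) {
    cnt_path <- file.path(out_dir, "counts.tsv")
    if (!(resume && file.exists(cnt_path))) {
      fitres <- tick("fit", fit_phantom_architecture(
        spec, voxel_size = vx, box_nm = box, resolution_nm = res,
        snr = snr, wedge = wg, seed = stage_seed(seed, "generate"),
        angular_step = fit_cfg$angular_step %||% 30,
        translation_step = fit_cfg$translation_step %||% 1,
        alpha = fit_cfg$alpha %||% 0.05,
        lowpass_nm = fit_cfg$lowpass_nm %||% 8,
        z_split = fit_cfg$z_split %||% 15,
        overlap_min = fit_cfg$overlap_min %||% 0.6,
        rescore_frac = fit_cfg$rescore_frac %||% 0.5))
      utils::write.table(fitres$ground_truth, gt_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(fitres$counts, cnt_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(fitres$assignment,
                         file.path(out_dir, "assignment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_map(fitres$target_map, file.path(out_dir, "target.mrc"))
    }
  }
  ## -- analyze -------------------------------------------------------
  an_cfg <- config$analyze %||% list()
  if (!isFALSE(an_cfg$enabled) && !is.null(fitres)) {
    tick("analyze", {
      asg <- fitres$assignment
      ya <- asg[asg$model == "Y" & asg$tz > 0, , drop = FALSE]
      yb <- asg[asg$model == "Y" & asg$tz < 0, , drop = FALSE]
      if (nrow(ya) && nrow(yb)) {
        reg <- rotational_register(ya, yb, spec$symmetry_order)
        jsonlite::write_json(
          list(median_offset = reg$median_offset,
               in_register = reg$in_register,
               offsets = reg$offsets),
          file.path(out_dir, "register.json"),
          auto_unbox = TRUE, digits = NA)
      }
      geo <- ring_geometry(fitres$target_map)
      utils::write.table(
        data.frame(inner_diameter = geo$inner_diameter,
                   outer_diameter = geo$outer_diameter,
                   axial_extent = geo$axial_extent),
        file.path(out_dir, "geometry.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      NULL
    })
  }
  ## -- coexpr --------------------------------------------------------
  cx <- config$coexpr %||% list()
  if (isTRUE(cx$enabled)) {
    tick("coexpr", {
      mods <- cx$modules %||% list(npc = 20, coat = 20)
      sim <- simulate_expression(cx$n_genes %||% 100, mods,
                                 cx$n_samples %||% 200,
                                 cx$within_module_corr %||% 0.8,
                                 seed = stage_seed(seed, "coexpr"))
      nrm <- normalize_expression(sim$fpkm)
      cm <- pcc_matrix(nrm, cx$p_threshold %||% 0.01)
      ord <- order_by_clustering(cm)
      utils::write.table(cm$masked,
                         file.path(out_dir, "pcc_masked.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      writeLines(rownames(nrm)[ord],
                 file.path(out_dir, "gene_order.txt"))
      NULL
    })
  }
  ## -- manifest ------------------------------------------------------
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    package = "npcfit",
    version = as.character(utils::packageVersion("npcfit")),
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = seed,
    stage_seeds = stats::setNames(
      lapply(c("generate", "average", "fit", "analyze", "coexpr"),
             function(s) stage_seed(seed, s)),
      c("generate", "average", "fit", "analyze", "coexpr")),
    timings = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

phantom_spec_from_config <- function(arch) {
  if (inherits(arch, "architecture_spec")) return(arch)
  if (is.character(arch)) {
    if (arch == "crnpc") return(crnpc_spec())
    if (arch == "inner_ring") return(inner_ring_spec())
    if (file.exists(arch)) return(read_architecture_spec(arch))
    stop("unknown architecture: ", arch)
  }
  architecture_spec(arch$rings, arch$symmetry_order %||% 8,
                    arch$channel_diameter %||% NA_real_)
}
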