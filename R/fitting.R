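## Exhaustive rigid-body fitting of subunit models into ring densities,
## with empirical-null significance assessment.

#' Density threshold enclosing a target volume
#'
#' The isovalue above which exactly `volume_nm3` of map volume lies;
#' the default envelope convention of the fitting stage (thresholds
#' enclosing the expected molecular volume).
#'
#' @param map a [density_map()].
#' @param volume_nm3 enclosed volume in nm^3.
#' @return scalar threshold.
#' @export
envelope_threshold <- function(map, volume_nm3) {
  vx3 <- map$voxel_size^3
  k <- max(1L, min(length(map$values), round(volume_nm3 / vx3)))
  sort(as.numeric(map$values), decreasing = TRUE)[k]
}

## envelope volume (nm^3) of a map above a threshold
envelope_volume <- function(map, thr) {
  sum(map$values >= thr) * map$voxel_size^3
}

#' Score a rigid fit of a model into a map
#'
#' The model map is posed into the target grid; `cc` is the Pearson
#' correlation between model and target over the voxels where the posed
#' model density exceeds `model_thr` (the model envelope); `overlap` is
#' the fraction of those voxels where the target exceeds `target_thr`;
#' the combined score is `cc * overlap`, which penalises high-cc fits
#' hanging outside the map envelope.
#'
#' @param model_map model [density_map()] on the target grid (rendered
#'   and low-pass filtered to the target's resolution).
#' @param target_map target [density_map()].
#' @param p a [pose()].
#' @param model_thr model envelope isovalue.
#' @param target_thr target envelope isovalue.
#' @return list with `cc`, `overlap`, `score`.
#' @export
score_fit <- function(model_map, target_map, p, model_thr, target_thr) {
  stopifnot(is_density_map(model_map), is_density_map(target_map))
  check_same_grid(model_map, target_map)
  tm <- transform_map(model_map, p)
  ## renormalise the posed model to its nominal peak: interpolation
  ## lowers rotated maxima, which would otherwise shrink the envelope
  ## relative to the fixed isovalue
  mx <- max(tm$values)
  if (mx <= 0) stop("empty model envelope at this pose/threshold")
  tm$values <- tm$values * (max(model_map$values) / mx)
  W <- tm$values >= model_thr
  if (!any(W)) stop("empty model envelope at this pose/threshold")
  mv <- tm$values[W]; tv <- target_map$values[W]
  cc <- if (stats::sd(mv) == 0 || stats::sd(tv) == 0) 0
        else stats::cor(mv, tv)
  cc <- max(-1, min(1, cc))
  overlap <- mean(tv >= target_thr)
  list(cc = cc, overlap = overlap, score = cc * overlap)
}

## translation lattice: circular FFT shifts within +/- max_shift voxels,
## subsampled by `step` voxels
trans_lattice <- function(d, max_vox, step) {
  ax <- function(n, m) {
    s <- unique(c(seq(0, min(m, n %/% 2), by = step),
                  -seq(step, min(m, (n - 1) %/% 2), by = step)))
    s
  }
  sx <- ax(d[1], max_vox[1]); sy <- ax(d[2], max_vox[2])
  sz <- ax(d[3], max_vox[3])
  list(sx = sort(sx), sy = sort(sy), sz = sort(sz))
}

#' Exhaustive six-dimensional fitting search
#'
#' Evaluates the combined fit score at every orientation of a
#' quasi-uniform SO(3) grid ([so3_grid()]) and every translation on a
#' voxel lattice, using the correlation theorem to scan translations
#' (equal to direct [score_fit()] evaluation within numerical
#' tolerance).  The model is rotated about the grid centre and shifted
#' circularly; keep `max_shift` small enough that the model envelope
#' does not wrap (default: half the box minus the model extent).
#'
#' @param model_map model [density_map()] on the target grid.
#' @param target_map target [density_map()].
#' @param angular_step orientation grid step (degrees).
#' @param translation_step translation lattice step (voxels).
#' @param model_thr,target_thr envelope isovalues; defaults: model at a
#'   quarter of its maximum (a generous footprint, so the correlation
#'   rests on enough voxels to carry evidence), target enclosing the
#'   model envelope volume times `volume_factor`.
#' @param max_shift maximum translation (nm) per axis.
#' @param volume_factor multiple of the model envelope volume used for
#'   the default target threshold (set to the expected number of copies
#'   when known).
#' @return object of class `fit_ensemble`: score/cc/overlap matrices
#'   (translations x orientations), the orientation grid, translation
#'   lattice, thresholds and parameters.
#' @export
exhaustive_search <- function(model_map, target_map, angular_step = 30,
                              translation_step = 1,
                              model_thr = NULL, target_thr = NULL,
                              max_shift = NULL, volume_factor = 8) {
  stopifnot(is_density_map(model_map), is_density_map(target_map),
            angular_step > 0, translation_step > 0)
  check_same_grid(model_map, target_map)
  d <- dim(target_map$values)
  vx <- target_map$voxel_size
  if (is.null(model_thr)) model_thr <- 0.25 * max(model_map$values)
  if (is.null(target_thr)) {
    vol <- envelope_volume(model_map, model_thr) * volume_factor
    target_thr <- envelope_threshold(target_map, vol)
  }
  if (is.null(max_shift)) {
    ext <- (sum(model_map$values >= model_thr) * vx^3 * 3 / (4 * pi))^(1 / 3)
    max_shift <- min(d) * vx / 2 - ext
  }
  ms_vox <- pmax(0, floor(rep(max_shift, length.out = 3) / vx))
  lat <- trans_lattice(d, ms_vox, translation_step)
  idx <- list(x = (lat$sx %% d[1]) + 1L, y = (lat$sy %% d[2]) + 1L,
              z = (lat$sz %% d[3]) + 1L)
  shifts <- as.matrix(expand.grid(sx = lat$sx, sy = lat$sy, sz = lat$sz,
                                  KEEP.OUT.ATTRS = FALSE))
  n_trans <- nrow(shifts)
  angles <- so3_grid(angular_step)
  n_rot <- nrow(angles)
  T1 <- target_map$values
  FT <- fftn(T1); FT2 <- fftn(T1^2)
  FB <- fftn((T1 >= target_thr) + 0)
  score <- matrix(0, n_trans, n_rot)
  ccm <- matrix(0, n_trans, n_rot)
  ovm <- matrix(0, n_trans, n_rot)
  n_env <- integer(n_rot)
  eps <- 1e-12
  mx0 <- max(model_map$values)
  for (r in seq_len(n_rot)) {
    M <- transform_map(model_map, pose(angles[r, ]))$values
    if (max(M) <= 0) next
    M <- M * (mx0 / max(M))   # peak renormalisation, as in score_fit
    W <- (M >= model_thr) + 0
    n <- sum(W)
    n_env[r] <- n
    if (n < 2) next
    K1 <- W * M
    sm <- sum(K1); sm2 <- sum(K1 * M)
    varM <- sm2 - sm^2 / n
    if (varM <= eps) next
    FK1 <- Conj(fftn(K1)); FK0 <- Conj(fftn(W))
    S1 <- ifftn_re(FT * FK1)[idx$x, idx$y, idx$z, drop = FALSE]
    S0 <- ifftn_re(FT * FK0)[idx$x, idx$y, idx$z, drop = FALSE]
    S2 <- ifftn_re(FT2 * FK0)[idx$x, idx$y, idx$z, drop = FALSE]
    SB <- ifftn_re(FB * FK0)[idx$x, idx$y, idx$z, drop = FALSE]
    num <- S1 - sm * S0 / n
    varT <- pmax(S2 - S0^2 / n, 0)
    ## FFT roundoff leaves ~1e-15-relative residue in empty regions;
    ## snap those to exactly zero so off-support fits score 0.
    vfloor <- max(1e-8 * max(varT), eps)
    cc <- num / sqrt(varM * pmax(varT, vfloor))
    cc <- pmax(-1, pmin(1, cc))
    cc[varT <= vfloor] <- 0
    ov <- pmax(0, pmin(1, round(SB) / n))
    score[, r] <- as.numeric(cc * ov)
    ccm[, r] <- as.numeric(cc)
    ovm[, r] <- as.numeric(ov)
  }
  structure(list(score = score, cc = ccm, overlap = ovm,
                 angles = angles, shifts = shifts, n_env = n_env,
                 voxel_size = vx, dims = d,
                 trans_tol_default = model_envelope_diameter(model_map,
                                                             model_thr) / 2,
                 model_thr = model_thr, target_thr = target_thr,
                 params = list(angular_step = angular_step,
                               translation_step = translation_step,
                               max_shift = max_shift)),
            class = "fit_ensemble")
}

#' @export
print.fit_ensemble <- function(x, ...) {
  cat(sprintf("<fit_ensemble> %d orientations x %d translations = %d fits; top score %.3f\n",
              nrow(x$angles), nrow(x$shifts), length(x$score),
              max(x$score)))
  invisible(x)
}

## Translational local maxima per orientation on the stored lattice.
## Returns a data.frame of candidate fits.
ensemble_local_maxima <- function(ens) {
  nx <- length(unique(ens$shifts[, 1]))
  ny <- length(unique(ens$shifts[, 2]))
  nz <- length(unique(ens$shifts[, 3]))
  ord <- order(ens$shifts[, 3], ens$shifts[, 2], ens$shifts[, 1])
  out <- vector("list", ncol(ens$score))
  for (r in seq_len(ncol(ens$score))) {
    a <- array(ens$score[ord, r], c(nx, ny, nz))
    m <- array(TRUE, dim(a))        # >= all 6 neighbours
    strict <- array(FALSE, dim(a))  # > at least one (rejects flat plateaus)
    pad <- function(arr, di, dj, dk) {
      b <- array(-Inf, dim(arr))
      si <- seq_len(nx - abs(di)); sj <- seq_len(ny - abs(dj))
      sk <- seq_len(nz - abs(dk))
      b[si + max(di, 0), sj + max(dj, 0), sk + max(dk, 0)] <-
        arr[si + max(-di, 0), sj + max(-dj, 0), sk + max(-dk, 0)]
      b
    }
    for (dd in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))) {
      nb <- pad(a, dd[1], dd[2], dd[3])
      m <- m & (a >= nb)
      strict <- strict | (a > nb)
    }
    w <- which(m & strict & is.finite(a))
    if (!length(w)) next
    lin <- ord[match(w, seq_along(a))]
    out[[r]] <- data.frame(rot = r, trans = lin)
  }
  cand <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(cand)) return(NULL)
  ## a candidate placement must touch the target envelope at all;
  ## off-support maxima are bookkeeping artefacts of the zero plateau
  on <- ens$overlap[cbind(cand$trans, cand$rot)] > 0
  cand <- cand[on, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  data.frame(rot = cand$rot, trans = cand$trans,
             phi = ens$angles[cand$rot, 1],
             theta = ens$angles[cand$rot, 2],
             psi = ens$angles[cand$rot, 3],
             tx = ens$shifts[cand$trans, 1] * ens$voxel_size,
             ty = ens$shifts[cand$trans, 2] * ens$voxel_size,
             tz = ens$shifts[cand$trans, 3] * ens$voxel_size,
             cc = ens$cc[cbind(cand$trans, cand$rot)],
             overlap = ens$overlap[cbind(cand$trans, cand$rot)],
             score = ens$score[cbind(cand$trans, cand$rot)])
}

#' Significance assessment of an ensemble
#'
#' Candidate placements are the translational local maxima of the
#' score field (restricted to fits whose envelope touches the target
#' envelope at all).  Under the null hypothesis that no copy of the
#' model sits at a pose, the envelope correlation of `n_env` voxels of
#' noise has the exact Fisher null: `atanh(cc) * sqrt(n_env - 3)` is
#' standard normal.  Each maximum gets an upper-tail p-value from that
#' null, Sidak/Bonferroni-corrected for the average number of grid
#' fits it represents; maxima are then greedily clustered
#' ([cluster_fits()]) and Benjamini-Hochberg q-values are computed
#' across the cluster representatives (dense grid fits are massively
#' dependent; clusters approximate independent hypotheses).  A cluster
#' with `q <= alpha` is significant, and its member maxima inherit the
#' flag.
#'
#' @param ensemble a `fit_ensemble` from [exhaustive_search()] with at
#'   least 100 sampled fits.
#' @param alpha FDR level (default 0.05).
#' @param rot_tol,trans_tol clustering tolerances (degrees, nm);
#'   `trans_tol` defaults to half the model envelope diameter.
#' @return the ensemble with added elements `maxima` (local maxima
#'   with `p`, `cluster`, `significant`), `clusters` (representatives
#'   with `p`, `q`, `significant`, `n_members`) and `alpha`.
#' @export
assess_significance <- function(ensemble, alpha = 0.05, rot_tol = Inf,
                                trans_tol = NULL) {
  stopifnot(inherits(ensemble, "fit_ensemble"))
  s <- as.numeric(ensemble$score)
  if (length(s) < 100) stop("ensemble too small for a null fit (need >= 100)")
  mx <- ensemble_local_maxima(ensemble)
  if (is.null(mx) || nrow(mx) < 2)
    stop("degenerate (constant) score distribution; no local maxima to assess")
  n_env <- ensemble$n_env[mx$rot]
  mx$p <- fisher_null_pvalue(mx$cc, n_env)
  occ <- sum(ensemble$overlap > 0) / nrow(mx)
  mx$p <- pmin(1, mx$p * max(occ, 1))
  if (is.null(trans_tol))
    trans_tol <- ensemble$trans_tol_default %||%
      (4 * ensemble$voxel_size)
  cl <- cluster_fits(mx, rot_tol = rot_tol, trans_tol = trans_tol)
  cl$q <- stats::p.adjust(cl$p, method = "BH")
  cl$significant <- cl$q <= alpha
  ## attribute each maximum to its nearest significant-or-not cluster
  pos <- as.matrix(mx[, c("tx", "ty", "tz")])
  cpos <- as.matrix(cl[, c("tx", "ty", "tz")])
  nearest <- max.col(-(outer(rowSums(pos^2), rep(1, nrow(cl))) -
                       2 * pos %*% t(cpos) +
                       outer(rep(1, nrow(pos)), rowSums(cpos^2))))
  mx$cluster <- nearest
  mx$significant <- cl$significant[nearest] &
    sqrt(rowSums((pos - cpos[nearest, , drop = FALSE])^2)) <= trans_tol
  ensemble$maxima <- mx
  ensemble$clusters <- cl
  ensemble$alpha <- alpha
  ensemble$null <- list(type = "fisher", occ = occ,
                        trans_tol = trans_tol, rot_tol = rot_tol)
  ensemble
}

#' Upper-tail p-value of an envelope correlation under the Fisher null
#'
#' The exact null for the correlation of `n_env` independent noise
#' voxels with the model envelope: `atanh(cc) * sqrt(n_env - 3)` is
#' standard normal.  Monotone non-increasing in `cc`.
#'
#' @param cc correlation values.
#' @param n_env envelope voxel counts (recycled).
#' @return p-values.
#' @export
fisher_null_pvalue <- function(cc, n_env) {
  z <- atanh(pmax(-0.9999, pmin(0.9999, cc)))
  stats::pnorm(z * sqrt(pmax(n_env - 3, 1)), lower.tail = FALSE)
}

#' Greedy best-first clustering of fits
#'
#' Takes the highest-score fit as a cluster representative, absorbs all
#' fits within `trans_tol` nm *and* `rot_tol` degrees of it, and
#' repeats on the remainder.  Representatives are returned sorted by
#' score.  Duplicated entries collapse into the same clusters.
#'
#' @param fits data.frame of fits (columns `phi, theta, psi, tx, ty,
#'   tz, score`, e.g. the `maxima` of an assessed ensemble).
#' @param rot_tol rotational tolerance in degrees (`Inf` clusters on
#'   position alone, appropriate for quasi-symmetric models).
#' @param trans_tol translational tolerance in nm.
#' @return data.frame of cluster representatives with `n_members`.
#' @export
cluster_fits <- function(fits, rot_tol = Inf, trans_tol) {
  stopifnot(trans_tol > 0, rot_tol > 0, nrow(fits) >= 1)
  fits <- fits[order(-fits$score), , drop = FALSE]
  pos <- as.matrix(fits[, c("tx", "ty", "tz")])
  angs <- as.matrix(fits[, c("phi", "theta", "psi")])
  if (is.finite(rot_tol))
    Rlist <- apply(angs, 1, pose_matrix, simplify = FALSE)
  remaining <- rep(TRUE, nrow(fits))
  reps <- integer(); members <- integer()
  while (any(remaining)) {
    i <- which(remaining)[1]                    # highest remaining score
    idx <- which(remaining)
    dtr <- sqrt(colSums((t(pos[idx, , drop = FALSE]) - pos[i, ])^2))
    close <- dtr <= trans_tol
    if (is.finite(rot_tol) && any(close)) {
      Ri <- Rlist[[i]]
      sub <- idx[close]
      rd <- vapply(sub, function(j) {
        Rrel <- crossprod(Ri, Rlist[[j]])
        rad2deg(acos(max(-1, min(1, (sum(diag(Rrel)) - 1) / 2))))
      }, 0)
      close[close] <- rd <= rot_tol
    }
    absorbed <- idx[close]
    absorbed <- union(absorbed, i)
    reps <- c(reps, i)
    members <- c(members, length(absorbed))
    remaining[absorbed] <- FALSE
  }
  out <- fits[reps, , drop = FALSE]
  out$n_members <- members
  rownames(out) <- NULL
  out
}

#' Hierarchical fitting with greedy acceptance and density masking
#'
#' The full inference for one target map: for each model, in the given
#' order (largest / most constrained first), run the exhaustive search,
#' assess significance, cluster the local maxima, then accept clusters
#' greedily: each candidate is re-scored against the *current* working
#' map (from which previously accepted placements have been masked
#' out); it is accepted only if its q-value passes `alpha`, its
#' re-scored overlap reaches `overlap_min`, and its re-scored combined
#' score retains at least `rescore_frac` of the original cluster score
#' (placements whose support was already claimed collapse here).
#' Accepted model density is masked (zeroed inside the posed model
#' envelope) or subtracted from the working map before continuing.
#'
#' @param target_map the map to explain.
#' @param ordered_models list of model entries, each a list with
#'   `label`, `model_map` (a [density_map()] on the target grid),
#'   optional `region_mask` ([density_map()], restricts the search to a
#'   ring region as in mask-focused refinement), optional `trans_tol`
#'   (default: half the model envelope diameter), `rot_tol`,
#'   `volume_factor`, `max_shift`.
#' @param alpha FDR level.
#' @param angular_step,translation_step search sampling.
#' @param overlap_min minimum re-scored envelope overlap for acceptance.
#' @param rescore_frac minimum retained score fraction after masking.
#' @param snap snap each candidate to its local score optimum by a
#'   translational hill-climb (one voxel steps) before gating; this
#'   collapses displaced duplicate representatives onto the same
#'   position so the double-count guard can catch them.
#' @param residual_mode `"mask"` (zero accepted envelope; default) or
#'   `"subtract"` (subtract the fitted model density).
#' @return list with `assignment` (data.frame: model, pose, cc,
#'   overlap, score, p, q per accepted placement), `ensembles` (one
#'   assessed ensemble per model) and `residual_map`.
#' @export
hierarchical_fit <- function(target_map, ordered_models, alpha = 0.05,
                             angular_step = 30, translation_step = 1,
                             overlap_min = 0.6, rescore_frac = 0.5,
                             snap = TRUE,
                             residual_mode = c("mask", "subtract")) {
  residual_mode <- match.arg(residual_mode)
  work <- target_map
  assignment <- list(); ensembles <- list()
  if (length(ordered_models) == 0)
    return(list(assignment = empty_assignment(), ensembles = list(),
                residual_map = work))
  for (entry in ordered_models) {
    mm <- entry$model_map
    stopifnot(is_density_map(mm))
    search_map <- work
    if (!is.null(entry$region_mask))
      search_map <- density_map(work$values * entry$region_mask$values,
                                work$voxel_size, work$origin)
    ens <- exhaustive_search(
      mm, search_map, angular_step = angular_step,
      translation_step = translation_step,
      model_thr = entry$model_thr %||% NULL,
      target_thr = entry$target_thr %||% NULL,
      max_shift = entry$max_shift %||% NULL,
      volume_factor = entry$volume_factor %||% 8)
    trans_tol <- entry$trans_tol %||%
      (model_envelope_diameter(mm, ens$model_thr) / 2)
    rot_tol <- entry$rot_tol %||% Inf
    ens <- assess_significance(ens, alpha, rot_tol = rot_tol,
                               trans_tol = trans_tol)
    clusters <- ens$clusters[ens$clusters$significant, , drop = FALSE]
    accepted <- list()
    if (nrow(clusters) > 0) {
      for (ci in seq_len(nrow(clusters))) {
        cl <- clusters[ci, ]
        p <- pose(c(cl$phi, cl$theta, cl$psi), c(cl$tx, cl$ty, cl$tz))
        wmask <- work_masked(work, entry$region_mask)
        if (snap)
          p <- snap_fit_pose(mm, wmask, p, ens$model_thr,
                             ens$target_thr)
        cl$tx <- p$shift[1]; cl$ty <- p$shift[2]; cl$tz <- p$shift[3]
        rs <- score_fit(mm, wmask, p, ens$model_thr, ens$target_thr)
        if (rs$overlap < overlap_min) next
        if (rs$score < rescore_frac * cl$score) next
        ## double-count guard
        if (length(accepted)) {
          prev <- do.call(rbind, lapply(accepted, function(a)
            a[c("tx", "ty", "tz")]))
          dmin <- min(sqrt(rowSums(sweep(matrix(unlist(prev), ncol = 3),
                                         2, c(cl$tx, cl$ty, cl$tz))^2)))
          if (dmin < trans_tol) {
            warning("rejecting overlapping accepted placement of model '",
                    entry$label, "' (double-count guard)")
            next
          }
        }
        accepted[[length(accepted) + 1]] <- data.frame(
          model = entry$label, phi = p$angles[1], theta = p$angles[2],
          psi = p$angles[3], tx = cl$tx, ty = cl$ty, tz = cl$tz,
          cc = rs$cc, overlap = rs$overlap, score = rs$score,
          p = cl$p, q = cl$q, n_members = cl$n_members)
        ## mask with a tighter footprint than the correlation envelope
        ## so an accepted copy does not erase its neighbours' support
        mask_thr <- entry$mask_thr %||% (2 * ens$model_thr)
        work <- remove_placement(work, mm, p, mask_thr, residual_mode)
      }
    }
    ensembles[[entry$id %||% entry$label]] <- ens
    if (length(accepted))
      assignment[[length(assignment) + 1]] <- do.call(rbind, accepted)
  }
  assignment <- if (length(assignment)) do.call(rbind, assignment)
               else empty_assignment()
  rownames(assignment) <- NULL
  list(assignment = assignment, ensembles = ensembles,
       residual_map = work)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_assignment <- function() {
  data.frame(model = character(), phi = numeric(), theta = numeric(),
             psi = numeric(), tx = numeric(), ty = numeric(),
             tz = numeric(), cc = numeric(), overlap = numeric(),
             score = numeric(), p = numeric(), q = numeric(),
             n_members = integer())
}

work_masked <- function(work, region_mask) {
  if (is.null(region_mask)) return(work)
  density_map(work$values * region_mask$values, work$voxel_size,
              work$origin)
}

## Greedy hill-climb of the fit score over one-voxel translation steps
## and small intrinsic rotations (grid-search refinement: recovers the
## sub-step pose the coarse SO(3)/translation lattice cannot express).
snap_fit_pose <- function(model_map, target_map, p, model_thr,
                          target_thr, max_steps = 6, rot_step = 5) {
  vx <- target_map$voxel_size
  cur <- p
  cur_s <- score_fit(model_map, target_map, cur, model_thr,
                     target_thr)$score
  rots <- list()
  for (gen in list(rot_z, rot_y, rot_x)) for (dd in c(-rot_step, rot_step))
    rots[[length(rots) + 1]] <- gen(dd)
  for (it in seq_len(max_steps)) {
    moved <- FALSE
    for (ax in 1:3) for (dd in c(-vx, vx)) {
      sh <- cur$shift; sh[ax] <- sh[ax] + dd
      cand <- pose(cur$angles, sh)
      s <- score_fit(model_map, target_map, cand, model_thr,
                     target_thr)$score
      if (s > cur_s + 1e-9) {
        cur <- cand; cur_s <- s; moved <- TRUE
      }
    }
    R <- pose_matrix(cur)
    for (dR in rots) {
      cand <- pose(matrix_to_euler(R %*% dR), cur$shift)
      s <- score_fit(model_map, target_map, cand, model_thr,
                     target_thr)$score
      if (s > cur_s + 1e-9) {
        cur <- cand; cur_s <- s; moved <- TRUE
      }
    }
    if (!moved) break
  }
  cur
}

model_envelope_diameter <- function(model_map, thr) {
  W <- which(model_map$values >= thr, arr.ind = TRUE)
  if (nrow(W) < 2) return(2 * model_map$voxel_size)
  rng <- apply(W, 2, range)
  sqrt(sum((rng[2, ] - rng[1, ])^2)) * model_map$voxel_size
}

remove_placement <- function(work, model_map, p, model_thr, mode) {
  tm <- transform_map(model_map, p)
  if (mode == "mask") {
    v <- work$values
    v[tm$values >= model_thr] <- 0
    density_map(v, work$voxel_size, work$origin)
  } else {
    W <- tm$values >= model_thr
    beta <- if (any(W)) sum(work$values[W] * tm$values[W]) /
              max(sum(tm$values[W]^2), .Machine$double.eps) else 0
    density_map(work$values - beta * tm$values, work$voxel_size,
                work$origin)
  }
}

#' Attribute accepted placements to map regions and count copies
#'
#' Each placement is assigned to the region whose mask contains its
#' centre (nearest voxel); placements outside all masks are reported
#' as `"unassigned"`.
#'
#' @param assignment assignment data.frame from [hierarchical_fit()].
#' @param region_masks named list of mask [density_map()]s (values
#'   above 0.5 count as inside).
#' @return data.frame of counts per (model, region), including an
#'   `unassigned` region when applicable.
#' @export
count_copies <- function(assignment, region_masks) {
  if (nrow(assignment) == 0)
    return(data.frame(model = character(), region = character(),
                      count = integer()))
  region <- rep("unassigned", nrow(assignment))
  for (nm in names(region_masks)) {
    msk <- region_masks[[nm]]
    d <- dim(msk$values)
    cvox <- (d + 1) / 2
    for (i in seq_len(nrow(assignment))) {
      v <- round(c(assignment$tx[i], assignment$ty[i],
                   assignment$tz[i]) / msk$voxel_size + cvox)
      if (all(v >= 1) && all(v <= d) &&
          msk$values[v[1], v[2], v[3]] > 0.5 &&
          region[i] == "unassigned")
        region[i] <- nm
    }
  }
  out <- as.data.frame(table(model = assignment$model, region = region),
                       stringsAsFactors = FALSE)
  names(out)[3] <- "count"
  out[out$count > 0, , drop = FALSE]
}
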