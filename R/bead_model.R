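#' Bead (pseudo-atom) subunit models
#'
#' A subcomplex is represented as a set of weighted beads: a data.frame
#' with columns `x, y, z` (nm), `weight` (> 0), `radius` (nm) and `role`
#' (`"head"`, `"tail"` or `""`).  At the >= 3 nm resolutions targeted
#' here the shape envelope, not atomic detail, determines rigid-body
#' fits, so beads stand in for atomic models of the Y-complex and inner
#' ring protomers.  The model centroid (weighted) is always at the
#' origin.
#'
#' @param beads data.frame with columns `x, y, z, weight, radius` and
#'   optionally `role`.
#' @param label subunit name, e.g. `"Y"`, `"protomer"`, `"double-Y"`.
#' @return object of class `bead_model`.
#' @export
bead_model <- function(beads, label = "subunit") {
  stopifnot(is.data.frame(beads), nrow(beads) >= 1,
            all(c("x", "y", "z", "weight", "radius") %in% names(beads)))
  if (any(!is.finite(as.matrix(beads[, c("x", "y", "z")]))))
    stop("bead coordinates must be finite")
  if (any(beads$weight <= 0)) stop("bead weights must be > 0")
  if (is.null(beads$role)) beads$role <- ""
  structure(list(beads = beads, label = label), class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("<bead_model> '%s': %d beads, extent %.1f nm\n",
              x$label, nrow(x$beads), model_extent(x)))
  invisible(x)
}

bead_xyz <- function(model) as.matrix(model$beads[, c("x", "y", "z")])

#' Maximum inter-bead distance of a model (nm)
#' @param model a [bead_model()].
#' @return largest pairwise bead-centre distance in nm.
#' @export
model_extent <- function(model) {
  xyz <- bead_xyz(model)
  if (nrow(xyz) == 1) return(2 * model$beads$radius[1])
  max(stats::dist(xyz))
}

center_beads <- function(beads) {
  w <- beads$weight / sum(beads$weight)
  for (cc in c("x", "y", "z")) beads[[cc]] <- beads[[cc]] - sum(beads[[cc]] * w)
  beads
}

#' Apply a pose to a bead model
#' @param model a [bead_model()].
#' @param p a [pose()].
#' @return posed `bead_model` (centroid no longer at origin in general).
#' @export
transform_beads <- function(model, p) {
  R <- pose_matrix(p)
  xyz <- bead_xyz(model) %*% t(R)
  b <- model$beads
  b$x <- xyz[, 1] + p$shift[1]
  b$y <- xyz[, 2] + p$shift[2]
  b$z <- xyz[, 3] + p$shift[3]
  out <- model
  out$beads <- b
  out
}

#' Generate a toy subunit model
#'
#' Three shape families cover the subcomplexes the pipeline fits:
#' \describe{
#'   \item{`"Y"`}{an elongated, *chiral* Y: a stem along +y with two
#'     unequal arms splayed at the head end — the long arm in the
#'     xy-plane, the short arm raised out of plane by `arm_lift`
#'     degrees.  Unequal arms plus the out-of-plane lift remove all
#'     rotational self-symmetry (including the near-mirror flip a
#'     planar Y would admit at low resolution), so orientation recovery
#'     is unambiguous.  The tail bead (`role = "tail"`) is the -y stem
#'     end, the head bead (`role = "head"`) the tip of the long arm —
#'     these anchor the head-to-tail adjacency analysis.}
#'   \item{`"rod"`}{collinear beads along y.}
#'   \item{`"blob-cluster"`}{a seeded random cluster of beads inside an
#'     ellipsoid; stands in for a compact inner-ring protomer.}
#' }
#' Deterministic for a fixed seed; the centroid is at the origin.
#'
#' @param label subunit name.
#' @param shape one of `"Y"`, `"rod"`, `"blob-cluster"`.
#' @param shape_params named list overriding the per-family defaults:
#'   `Y`: `stem, arm_long, arm_short, arm_angle, spacing, bead_radius`;
#'   `rod`: `length, spacing, bead_radius`;
#'   `blob-cluster`: `n_beads, semi_axes, bead_radius`.
#' @param seed integer RNG seed (only `"blob-cluster"` draws random
#'   numbers).
#' @return a [bead_model()].
#' @export
make_subunit <- function(label, shape = c("Y", "rod", "blob-cluster"),
                         shape_params = list(), seed = 1) {
  shape <- match.arg(shape)
  pars <- switch(shape,
    "Y" = list(stem = 16, arm_long = 11, arm_short = 7, arm_angle = 50,
               arm_lift = 35, spacing = 2.5, bead_radius = 1.5),
    "rod" = list(length = 20, spacing = 2.5, bead_radius = 1.5),
    "blob-cluster" = list(n_beads = 14, semi_axes = c(6, 5, 3.5),
                          bead_radius = 1.5))
  pars[names(shape_params)] <- shape_params
  beads <- switch(shape,
    "Y" = {
      ## stem from tail (-y) to junction (+y)
      ys <- seq(-pars$stem * 0.8, pars$stem * 0.2, by = pars$spacing)
      stem <- data.frame(x = 0, y = ys, z = 0)
      jy <- max(ys)
      a <- deg2rad(pars$arm_angle)
      lift <- deg2rad(pars$arm_lift)
      t1 <- seq(pars$spacing, pars$arm_long, by = pars$spacing)
      t2 <- seq(pars$spacing, pars$arm_short, by = pars$spacing)
      arm1 <- data.frame(x = sin(a) * t1, y = jy + cos(a) * t1, z = 0)
      arm2 <- data.frame(x = -sin(a) * cos(lift) * t2,
                         y = jy + cos(a) * cos(lift) * t2,
                         z = sin(lift) * t2)
      b <- rbind(stem, arm1, arm2)
      b$role <- ""
      b$role[1] <- "tail"                       # -y stem end
      b$role[nrow(stem) + length(t1)] <- "head" # long-arm tip
      b
    },
    "rod" = {
      if (pars$length <= 0) {
        data.frame(x = 0, y = 0, z = 0, role = "")
      } else {
        ys <- seq(-pars$length / 2, pars$length / 2, by = pars$spacing)
        b <- data.frame(x = 0, y = ys, z = 0, role = "")
        b$role[1] <- "tail"; b$role[nrow(b)] <- "head"
        b
      }
    },
    "blob-cluster" = {
      n <- pars$n_beads
      pts <- withr_seed(seed, {
        m <- matrix(stats::runif(3 * n, -1, 1), ncol = 3)
        sweep(m, 2, pars$semi_axes, `*`)
      })
      data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3], role = "")
    })
  beads$weight <- 1
  beads$radius <- pars$bead_radius
  bead_model(center_beads(beads), label)
}

## run expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  force(expr)
}

#' Render a bead model into a density map
#'
#' Forward model: each bead contributes an isotropic 3-D Gaussian whose
#' full width at half maximum equals `resolution_nm` (combined in
#' quadrature with the bead radius), normalised so the map integral
#' `sum(values) * voxel^3` equals the total bead weight.
#'
#' @param model a [bead_model()].
#' @param voxel_size nm per voxel.
#' @param box_nm physical box edge length in nm (cubic box).
#' @param resolution_nm rendering resolution (Gaussian FWHM); must be at
#'   least `voxel_size`.  Values below `2 * voxel_size` are slightly
#'   sub-Nyquist; for Gaussian densities the resulting aliasing is
#'   negligible.
#' @param origin physical origin; default centres the box on 0.
#' @return a [density_map()].
#' @export
render_density <- function(model, voxel_size, box_nm, resolution_nm,
                           origin = NULL) {
  stopifnot(inherits(model, "bead_model"))
  if (resolution_nm < voxel_size)
    stop("resolution_nm must be >= voxel_size")
  n <- round(box_nm / voxel_size)
  if (is.null(origin)) origin <- rep(-voxel_size * (n - 1) / 2, 3)
  xyz <- bead_xyz(model)
  half <- box_nm / 2
  lo <- origin - voxel_size / 2
  hi <- origin + voxel_size * (n - 0.5)
  bad <- which(xyz[, 1] < lo[1] | xyz[, 1] > hi[1] |
               xyz[, 2] < lo[2] | xyz[, 2] > hi[2] |
               xyz[, 3] < lo[3] | xyz[, 3] > hi[3])
  if (length(bad))
    stop("model extends outside the box; offending beads: ",
         paste(bad, collapse = ", "))
  vals <- array(0, c(n, n, n))
  sig_res <- resolution_nm / (2 * sqrt(2 * log(2)))
  ax <- origin[1] + voxel_size * (0:(n - 1))
  ay <- origin[2] + voxel_size * (0:(n - 1))
  az <- origin[3] + voxel_size * (0:(n - 1))
  for (b in seq_len(nrow(xyz))) {
    sig <- sqrt(sig_res^2 + (model$beads$radius[b] / 2)^2)
    amp <- model$beads$weight[b] / ((2 * pi)^1.5 * sig^3)
    w <- ceiling(4 * sig / voxel_size)
    ci <- round((xyz[b, ] - origin) / voxel_size) + 1
    ir <- max(1, ci[1] - w):min(n, ci[1] + w)
    jr <- max(1, ci[2] - w):min(n, ci[2] + w)
    kr <- max(1, ci[3] - w):min(n, ci[3] + w)
    gx <- exp(-(ax[ir] - xyz[b, 1])^2 / (2 * sig^2))
    gy <- exp(-(ay[jr] - xyz[b, 2])^2 / (2 * sig^2))
    gz <- exp(-(az[kr] - xyz[b, 3])^2 / (2 * sig^2))
    vals[ir, jr, kr] <- vals[ir, jr, kr] +
      amp * (gx %o% gy %o% gz)
  }
  density_map(vals, voxel_size, origin)
}

#' Read/write bead models as TSV
#'
#' Columns: `x y z weight radius role` plus a `label` attribute line is
#' not stored; pass `label` explicitly on read.
#' @param model a [bead_model()].
#' @param path file path.
#' @param label subunit label on read.
#' @return `read_bead_model` returns a [bead_model()].
#' @export
write_bead_model <- function(model, path) {
  utils::write.table(model$beads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_bead_model
#' @export
read_bead_model <- function(path, label = "subunit") {
  b <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(b$role)) b$role <- ""
  b$role[is.na(b$role)] <- ""
  bead_model(b, label)
}

#' Combine posed copies of bead models into one composite model
#' @param models list of `bead_model`s already posed into a common frame.
#' @param label label of the composite.
#' @param recenter recentre the weighted centroid at the origin
#'   (default `FALSE`: keep absolute placement).
#' @return a [bead_model()].
#' @export
combine_beads <- function(models, label = "composite", recenter = FALSE) {
  beads <- do.call(rbind, lapply(models, function(m) {
    b <- m$beads
    b$subunit <- m$label
    b
  }))
  if (recenter) beads <- center_beads(beads)
  bead_model(beads, label)
}

#' Build a double-Y model from ring geometry
#'
#' Two copies of a Y model placed as the outer/inner pair of a double
#' outer ring: the outer copy tangential at radius `r_outer`, the inner
#' copy at `r_inner` advanced azimuthally by `stagger` degrees, both
#' re-centred on their common centroid.  Searching this rigid pair can
#' only succeed where *both* sub-rings are present, which is what
#' discriminates a 16-copy (double) ring from an 8-copy (single) one.
#'
#' @param y_model a Y [bead_model()].
#' @param r_outer,r_inner ring radii (nm).
#' @param stagger azimuthal offset of the inner copy (degrees).
#' @return a `bead_model` labelled `"double-Y"`.
#' @export
make_double_y <- function(y_model, r_outer = 42, r_inner = 25, stagger = 22.5) {
  outer <- transform_beads(y_model, pose(c(0, 0, 0), c(r_outer, 0, 0)))
  inner <- transform_beads(
    y_model, pose(c(stagger, 0, 0),
                  c(r_inner * cos(deg2rad(stagger)),
                    r_inner * sin(deg2rad(stagger)), 0)))
  out <- combine_beads(list(outer, inner), label = "double-Y", recenter = TRUE)
  out
}
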