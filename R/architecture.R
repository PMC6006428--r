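## Downstream architectural measurements on ring maps and placements.

#' Normalised difference map
#'
#' Both maps are scaled to zero mean and unit variance inside a common
#' mask, then subtracted voxelwise (`a - b`).  Exactly antisymmetric in
#' its arguments.  The density present in one ring but not the other
#' (e.g. the inner Y-complex ring of a doubled nuclear ring) survives
#' as positive difference density.
#'
#' @param map_a,map_b pre-aligned maps on the same grid (shared
#'   symmetry axis).
#' @param mask optional [density_map()]; statistics and output are
#'   restricted to `mask > 0.5` (default: whole grid).
#' @return a `density_map` of `a - b`, with attribute `"provenance"`.
#' @export
difference_map <- function(map_a, map_b, mask = NULL) {
  stopifnot(is_density_map(map_a), is_density_map(map_b))
  check_same_grid(map_a, map_b)
  sel <- if (is.null(mask)) TRUE else mask$values > 0.5
  za <- map_a$values; zb <- map_b$values
  norm <- function(v) {
    mu <- mean(v[sel]); s <- stats::sd(v[sel])
    if (s == 0) v - mu else (v - mu) / s
  }
  za <- norm(za); zb <- norm(zb)
  out <- za - zb
  if (!is.null(mask)) out <- out * (mask$values > 0.5)
  m <- density_map(array(out, dim(map_a$values)), map_a$voxel_size,
                   map_a$origin)
  attr(m, "provenance") <- "difference_map(a, b): z(a) - z(b)"
  m
}

#' Rotational register between two placement sets
#'
#' Computes each placement's azimuth from its translation, then for
#' every placement in `a` the angular offset to the nearest placement
#' in `b`, reported modulo the symmetry unit `360/order` and folded
#' into `(-180/order, 180/order]`.  The sets are declared in register
#' when the median absolute offset is below `tolerance`.
#'
#' @param placements_a,placements_b data.frames with `tx, ty` columns
#'   (non-empty).
#' @param symmetry_order Cn order.
#' @param tolerance register tolerance in degrees (default 5).
#' @return list with `offsets` (degrees, one per placement of `a`),
#'   `median_offset`, `in_register`.
#' @export
rotational_register <- function(placements_a, placements_b,
                                symmetry_order = 8, tolerance = 5) {
  if (nrow(placements_a) == 0 || nrow(placements_b) == 0)
    stop("empty placement set")
  unit <- 360 / symmetry_order
  az <- function(df) rad2deg(atan2(df$ty, df$tx))
  aa <- az(placements_a); ab <- az(placements_b)
  offsets <- vapply(aa, function(a) {
    d <- (a - ab) %% unit
    d <- ifelse(d > unit / 2, d - unit, d)
    d[which.min(abs(d))]
  }, 0)
  med <- stats::median(abs(offsets))
  list(offsets = offsets, median_offset = med,
       in_register = med < tolerance)
}

#' Ring geometry from a cylindrically averaged profile
#'
#' The map is averaged over azimuth about the given axis through the
#' grid centre to give a radius x height profile; the profile is
#' thresholded at `threshold_frac` of its maximum (half-maximum by
#' default, a scale-free convention).  Inner diameter = twice the first
#' radius exceeding the threshold; outer diameter = twice the last;
#' axial extent = the thresholded span of the height profile.
#'
#' @param map a [density_map()] containing one annular assembly centred
#'   on `axis`.
#' @param axis symmetry axis (only `"z"` supported).
#' @param threshold_frac fraction of the profile maximum.
#' @return list with `inner_diameter`, `outer_diameter`,
#'   `axial_extent` (nm) and the `profile` (radius x z matrix).
#' @export
ring_geometry <- function(map, axis = "z", threshold_frac = 0.5) {
  stopifnot(is_density_map(map))
  axis <- match.arg(axis, "z")
  d <- dim(map$values)
  vx <- map$voxel_size
  idx <- index_grid(d)
  cvox <- (d + 1) / 2
  r <- sqrt((idx[1, ] - cvox[1])^2 + (idx[2, ] - cvox[2])^2) * vx
  rbin <- round(r / vx) + 1L
  zbin <- idx[3, ]
  nr <- max(rbin)
  prof <- matrix(0, nr, d[3])
  cnt <- matrix(0, nr, d[3])
  v <- as.numeric(map$values)
  for (k in seq_len(d[3])) {
    sel <- zbin == k
    t1 <- tapply(v[sel], rbin[sel], mean)
    prof[as.integer(names(t1)), k] <- t1
  }
  mx <- max(prof)
  if (mx <= 0) stop("threshold yields an empty region (non-positive map)")
  thr <- threshold_frac * mx
  rprof <- apply(prof, 1, max)
  zprof <- apply(prof, 2, max)
  rin <- which(rprof >= thr)
  if (!length(rin)) stop("threshold yields an empty region")
  zin <- which(zprof >= thr)
  list(inner_diameter = 2 * (min(rin) - 1) * vx,
       outer_diameter = 2 * (max(rin) - 1) * vx,
       axial_extent = (max(zin) - min(zin)) * vx,
       profile = prof)
}

#' Head-to-tail adjacency graph of ring placements
#'
#' Poses the model's designated head and tail beads by each placement;
#' a directed edge `i -> j` is created when `i`'s head lies within
#' `contact_nm` of `j`'s tail.  A closed head-to-tail ring of `n`
#' copies yields a single n-cycle.
#'
#' @param placements data.frame with pose columns (`phi, theta, psi,
#'   tx, ty, tz`).
#' @param subunit_model a [bead_model()] with beads of role `"head"`
#'   and `"tail"`.
#' @param contact_nm contact distance threshold.
#' @return list with `edges` (data.frame `from, to, dist`) and
#'   `cycles` (list of integer vectors, the directed cycles).
#' @export
head_to_tail_graph <- function(placements, subunit_model, contact_nm = 8) {
  b <- subunit_model$beads
  hi <- which(b$role == "head"); ti <- which(b$role == "tail")
  if (length(hi) != 1 || length(ti) != 1)
    stop("subunit model lacks unique 'head'/'tail' bead annotations")
  n <- nrow(placements)
  heads <- matrix(0, n, 3); tails <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    p <- pose(c(placements$phi[i], placements$theta[i],
                placements$psi[i]),
              c(placements$tx[i], placements$ty[i], placements$tz[i]))
    R <- pose_matrix(p)
    heads[i, ] <- as.numeric(R %*% c(b$x[hi], b$y[hi], b$z[hi])) + p$shift
    tails[i, ] <- as.numeric(R %*% c(b$x[ti], b$y[ti], b$z[ti])) + p$shift
  }
  edges <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dd <- sqrt(sum((heads[i, ] - tails[j, ])^2))
    if (dd <= contact_nm)
      edges[[length(edges) + 1]] <- data.frame(from = i, to = j, dist = dd)
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(from = integer(), to = integer(),
                           dist = numeric())
  ## trace directed cycles (each node keeps its nearest out-edge)
  nxt <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    e <- edges[edges$from == i, , drop = FALSE]
    if (nrow(e)) nxt[i] <- e$to[which.min(e$dist)]
  }
  seen <- rep(FALSE, n); cycles <- list()
  for (s in seq_len(n)) {
    if (seen[s] || is.na(nxt[s])) next
    path <- integer(); cur <- s
    while (!is.na(cur) && !(cur %in% path)) {
      path <- c(path, cur); cur <- nxt[cur]
    }
    if (!is.na(cur) && cur == path[1] && !any(seen[path])) {
      cycles[[length(cycles) + 1]] <- path
      seen[path] <- TRUE
    }
  }
  list(edges = edges, cycles = cycles)
}
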