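#' Declarative ring architecture of an NPC-like assembly
#'
#' An `architecture_spec` lists concentric rings of subunit copies.
#' Each ring places `copies` posed copies of a subunit at equal angular
#' spacing on a circle of radius `radius` nm at height `z` nm, with an
#' azimuthal `phase` offset (degrees) and an optional out-of-plane
#' `tilt` (degrees, about the local tangential axis).  Subunits are
#' oriented with their local +y axis along the ring tangent, so
#' elongated models arrange head-to-tail.
#'
#' @param rings list of ring definitions; each a list with fields
#'   `label` (subunit label), `ring` (ring id, e.g. `"CR"`), `copies`,
#'   `radius`, `z`, `tilt` (default 0), `phase` (default 0).
#' @param symmetry_order rotational symmetry order (8 for the NPC).
#' @param channel_diameter nominal central channel diameter (nm),
#'   metadata only.
#' @return object of class `architecture_spec`.
#' @export
architecture_spec <- function(rings, symmetry_order = 8,
                              channel_diameter = NA_real_) {
  stopifnot(length(rings) >= 1)
  rings <- lapply(rings, function(r) {
    if (is.null(r$tilt)) r$tilt <- 0
    if (is.null(r$phase)) r$phase <- 0
    stopifnot(!is.null(r$label), !is.null(r$ring),
              r$copies >= 1, r$radius >= 0)
    if (r$radius > 0 && r$copies %% symmetry_order != 0 &&
        !isTRUE(r$asymmetric))
      stop("ring '", r$ring, "': copies (", r$copies,
           ") not divisible by the symmetry order (", symmetry_order,
           "); set asymmetric = TRUE to allow")
    r
  })
  structure(list(rings = rings, symmetry_order = symmetry_order,
                 channel_diameter = channel_diameter),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> C%d, %d rings, %d total copies\n",
              x$symmetry_order, length(x$rings), total_copies(x)))
  for (r in x$rings)
    cat(sprintf("  %-9s %-10s %2d copies  r = %4.1f nm  z = %+5.1f nm  phase %.1f\n",
                r$ring, r$label, r$copies, r$radius, r$z, r$phase))
  invisible(x)
}

#' Total copy count implied by a spec
#' @param spec an [architecture_spec()].
#' @return integer.
#' @export
total_copies <- function(spec) sum(vapply(spec$rings, `[[`, 0, "copies"))

#' The default algal-NPC-style phantom architecture
#'
#' Encodes the asymmetric outer-ring layout of the algal NPC: the
#' cytoplasmic ring (CR) carries 8 Y-complexes; the nuclear ring (NR)
#' carries 16 as a double ring — 8 outer copies in rotational register
#' with the CR plus 8 inner copies staggered by half a symmetry unit;
#' the inner ring (IR) holds 8 spokes of 4 stacked protomers each
#' (32 protomers).  Scaffold extends ~60 nm axially.
#'
#' @param y_length_scale multiplier on the default Y-model dimensions
#'   (geometry of the rings is fixed; used for sensitivity checks).
#' @return an [architecture_spec()].
#' @export
crnpc_spec <- function(y_length_scale = 1) {
  architecture_spec(
    rings = list(
      list(label = "Y", ring = "CR",     copies = 8, radius = 42, z =  24, phase = 0),
      list(label = "Y", ring = "NR-out", copies = 8, radius = 42, z = -24, phase = 0),
      list(label = "Y", ring = "NR-in",  copies = 8, radius = 25, z = -24, phase = 22.5),
      list(label = "protomer", ring = "IR-c-out", copies = 8, radius = 38, z =  7, phase = 0),
      list(label = "protomer", ring = "IR-n-out", copies = 8, radius = 38, z = -7, phase = 0),
      list(label = "protomer", ring = "IR-c-in",  copies = 8, radius = 22, z =  7, phase = 0),
      list(label = "protomer", ring = "IR-n-in",  copies = 8, radius = 22, z = -7, phase = 0)),
    symmetry_order = 8,
    channel_diameter = 30)
}

#' Inner-ring-only phantom architecture (8 spokes x 4 protomers)
#' @return an [architecture_spec()].
#' @export
inner_ring_spec <- function() {
  architecture_spec(
    rings = list(
      list(label = "protomer", ring = "IR-c-out", copies = 8, radius = 38, z =  7, phase = 0),
      list(label = "protomer", ring = "IR-n-out", copies = 8, radius = 38, z = -7, phase = 0),
      list(label = "protomer", ring = "IR-c-in",  copies = 8, radius = 22, z =  7, phase = 0),
      list(label = "protomer", ring = "IR-n-in",  copies = 8, radius = 22, z = -7, phase = 0)),
    symmetry_order = 8,
    channel_diameter = 30)
}

#' Default subunit models for the bundled architectures
#' @param seed RNG seed for the stochastic blob-cluster protomer.
#' @return named list of [bead_model()]s (`Y`, `protomer`).
#' @export
default_subunits <- function(seed = 7) {
  list("Y" = make_subunit("Y", "Y"),
       "protomer" = make_subunit("protomer", "blob-cluster", seed = seed))
}

#' Place subunits according to an architecture spec
#'
#' Each copy `k = 0..copies-1` of a ring gets azimuth
#' `phase + k * 360/copies`; its pose is `Rz(azimuth) Rx(tilt)` with
#' translation `(radius*cos(az), radius*sin(az), z)`.  C-symmetric rings
#' are therefore invariant under rotation by `360/symmetry_order`.
#'
#' @param spec an [architecture_spec()].
#' @param subunits named list of [bead_model()]s keyed by ring `label`.
#' @return list with `ground_truth` (data.frame: one row per placed
#'   copy, columns `subunit, ring, copy, phi, theta, psi, tx, ty, tz`)
#'   and `model` (composite posed [bead_model()]).
#' @export
build_assembly <- function(spec, subunits) {
  stopifnot(inherits(spec, "architecture_spec"))
  missing <- setdiff(unique(vapply(spec$rings, `[[`, "", "label")),
                     names(subunits))
  if (length(missing))
    stop("no subunit model supplied for label(s): ",
         paste(missing, collapse = ", "))
  rows <- list(); posed <- list()
  for (r in spec$rings) {
    sub <- subunits[[r$label]]
    for (k in seq_len(r$copies) - 1) {
      az <- r$phase + k * 360 / r$copies
      R <- rot_z(az) %*% rot_x(r$tilt)
      tr <- c(r$radius * cos(deg2rad(az)), r$radius * sin(deg2rad(az)), r$z)
      p <- pose(matrix_to_euler(R), tr)
      rows[[length(rows) + 1]] <- data.frame(
        subunit = r$label, ring = r$ring, copy = k,
        phi = p$angles[1], theta = p$angles[2], psi = p$angles[3],
        tx = tr[1], ty = tr[2], tz = tr[3])
      posed[[length(posed) + 1]] <- transform_beads(sub, p)
    }
  }
  gt <- do.call(rbind, rows)
  stopifnot(nrow(gt) == total_copies(spec))
  list(ground_truth = gt, model = combine_beads(posed, label = "assembly"))
}

#' Serialise/deserialise an architecture spec as JSON
#' @param spec an [architecture_spec()].
#' @param path file path.
#' @return `read_architecture_spec` returns an [architecture_spec()].
#' @export
write_architecture_spec <- function(spec, path) {
  jsonlite::write_json(
    list(symmetry_order = spec$symmetry_order,
         channel_diameter = spec$channel_diameter,
         rings = spec$rings),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_architecture_spec
#' @export
read_architecture_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  architecture_spec(j$rings, j$symmetry_order,
                    if (is.null(j$channel_diameter)) NA_real_
                    else j$channel_diameter)
}
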