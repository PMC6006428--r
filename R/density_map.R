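#' Volumetric density maps
#'
#' The universal volumetric container of the package.  `values` is a 3-D
#' numeric array; the first array index runs along x, the second along y,
#' the third along z (R column-major order, x fastest).  Voxels are
#' isotropic cubes of edge `voxel_size` nanometres; the physical
#' coordinate of voxel `(i, j, k)` (1-based indices, voxel centres) is
#' `origin + voxel_size * (c(i, j, k) - 1)`.
#'
#' @param values 3-D numeric array.
#' @param voxel_size voxel edge length in nm (> 0, isotropic).
#' @param origin numeric(3), physical position in nm of the centre of
#'   voxel (1,1,1).
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("`values` must be a 3-D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (nm)")
  if (any(dim(values) < 1)) stop("grid dimensions must all be >= 1")
  stopifnot(length(origin) == 3, all(is.finite(origin)))
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_map> %d x %d x %d voxels, %.3g nm/voxel, origin (%.3g, %.3g, %.3g) nm\n",
              d[1], d[2], d[3], x$voxel_size, x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

is_density_map <- function(x) inherits(x, "density_map")

check_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("maps have mismatched grid dimensions")
  if (abs(a$voxel_size - b$voxel_size) > 1e-9)
    stop("maps have mismatched voxel sizes")
  invisible(TRUE)
}

#' Physical centre of a map grid (nm)
#' @param map a `density_map`.
#' @return numeric(3) position of the grid centre in nm.
#' @export
map_center <- function(map) {
  map$origin + map$voxel_size * (dim(map$values) - 1) / 2
}

## ---------------------------------------------------------------------
## MRC2014-style I/O (mode 2, little-endian float32).
## No installed R package reads MRC volumes, so the format is implemented
## directly.  Cell lengths are stored in Angstrom per MRC convention
## (1 nm = 10 A); the ORIGIN words (49:51) carry the physical origin.
## ---------------------------------------------------------------------

#' Read a density map from an MRC2014 file
#'
#' Supports mode-2 (float32) volumes with isotropic voxels, the format
#' the package itself writes.  Header fields that disagree with those
#' constraints produce an error naming the offending field.
#'
#' @param path path to an existing `.mrc` file.
#' @return a [density_map()].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  nxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (mode != 2L)
    stop("malformed MRC header: MODE is ", mode, ", only mode 2 (float32) supported")
  if (any(nxyz < 1) || any(nxyz > 1e4))
    stop("malformed MRC header: NX/NY/NZ out of range: ", paste(nxyz, collapse = " "))
  invisible(readBin(con, "integer", 3, size = 4, endian = "little")) # nxstart
  mxyz <- readBin(con, "integer", 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", 3, size = 4, endian = "little"))  # cellb
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("malformed MRC header: MAPC/MAPR/MAPS must be 1 2 3, got ",
         paste(mapcrs, collapse = " "))
  invisible(readBin(con, "numeric", 3, size = 4, endian = "little"))  # dmin dmax dmean
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))  # ispg
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  invisible(readBin(con, "integer", 25, size = 4, endian = "little")) # extra 25:49
  origin_a <- readBin(con, "numeric", 3, size = 4, endian = "little") # words 50:52
  maptag <- rawToChar(readBin(con, "raw", 4))                         # word 53
  if (maptag != "MAP ")
    stop("malformed MRC header: MAP tag is '", maptag, "'")
  invisible(readBin(con, "raw", 1024 - 53 * 4))
  if (nsymbt > 0) invisible(readBin(con, "raw", nsymbt))
  if (any(mxyz < 1)) stop("malformed MRC header: MX/MY/MZ out of range")
  vx <- cella / mxyz / 10                       # A -> nm
  if (any(vx <= 0)) stop("malformed MRC header: CELLA yields non-positive voxel size")
  if (max(vx) - min(vx) > 1e-4 * max(vx))
    stop("anisotropic voxel size not supported: ",
         paste(signif(vx, 6), collapse = " "), " nm")
  vals <- readBin(con, "numeric", prod(nxyz), size = 4, endian = "little")
  if (length(vals) != prod(nxyz))
    stop("malformed MRC file: data section shorter than NX*NY*NZ")
  density_map(array(vals, nxyz), mean(vx), origin_a / 10)
}

#' Write a density map to an MRC2014 file
#' @param map a [density_map()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_map <- function(map, path) {
  stopifnot(is_density_map(map))
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d); wi(2L)                       # nx ny nz, mode 2
  wi(c(0L, 0L, 0L))                   # nxstart
  wi(d)                               # mx my mz
  wf(d * map$voxel_size * 10)         # cella (A)
  wf(c(90, 90, 90))                   # cellb
  wi(c(1L, 2L, 3L))                   # mapc mapr maps
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(1L); wi(0L)                      # ispg, nsymbt
  wi(integer(25))                     # extra, words 25:49
  wf(map$origin * 10)                 # origin (A), words 50:52
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(as.numeric(map$values)))             # rms
  wi(0L)                                            # nlabl
  writeBin(raw(800), con)                           # labels
  writeBin(as.numeric(map$values), con, size = 4, endian = "little")
  invisible(path)
}
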