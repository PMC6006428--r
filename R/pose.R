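#' Rigid-body poses
#'
#' A pose is a proper rigid transform `x' = R x + t` acting on physical
#' coordinates in nanometres.  Rotations are parameterised as *intrinsic
#' ZYZ Euler angles* in degrees (`phi` about z, then `theta` about the new
#' y, then `psi` about the new z), the single convention used throughout
#' the package.  Translations are 3-vectors in nm.
#'
#' @param angles numeric(3), ZYZ Euler angles in degrees.
#' @param shift numeric(3), translation in nm.
#' @return An object of class `pose`.
#' @export
#' @examples
#' p <- pose(c(45, 10, -30), c(1, 0, 2))
#' pose_compose(p, pose_invert(p))  # identity within numeric tolerance
pose <- function(angles = c(0, 0, 0), shift = c(0, 0, 0)) {
  stopifnot(length(angles) == 3, length(shift) == 3,
            all(is.finite(angles)), all(is.finite(shift)))
  structure(list(angles = as.numeric(angles), shift = as.numeric(shift)),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> ZYZ = (%.2f, %.2f, %.2f) deg, shift = (%.2f, %.2f, %.2f) nm\n",
              x$angles[1], x$angles[2], x$angles[3],
              x$shift[1], x$shift[2], x$shift[3]))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_z <- function(a) {
  a <- deg2rad(a); c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

rot_y <- function(a) {
  a <- deg2rad(a); c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

rot_x <- function(a) {
  a <- deg2rad(a); c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' Rotation matrix of a pose
#'
#' Returns the 3x3 proper rotation matrix for intrinsic ZYZ Euler angles:
#' `R = Rz(phi) %*% Ry(theta) %*% Rz(psi)`.
#' @param angles numeric(3) ZYZ angles in degrees, or a `pose`.
#' @return 3x3 rotation matrix.
#' @export
pose_matrix <- function(angles) {
  if (inherits(angles, "pose")) angles <- angles$angles
  rot_z(angles[1]) %*% rot_y(angles[2]) %*% rot_z(angles[3])
}

#' Recover ZYZ Euler angles from a rotation matrix
#'
#' Inverse of [pose_matrix()].  At the gimbal singularities (theta = 0 or
#' 180 degrees) the split between phi and psi is not unique; psi is set
#' to 0 there.
#' @param R 3x3 rotation matrix.
#' @return numeric(3) ZYZ angles in degrees.
#' @export
matrix_to_euler <- function(R) {
  ct <- max(-1, min(1, R[3, 3]))
  theta <- acos(ct)
  if (sin(theta) > 1e-9) {
    phi <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  } else if (ct > 0) {          # theta ~ 0: pure z-rotation by phi+psi
    phi <- atan2(R[2, 1], R[1, 1])
    psi <- 0
  } else {                      # theta ~ 180
    phi <- atan2(-R[2, 1], -R[1, 1])
    psi <- 0
  }
  rad2deg(c(phi, theta, psi))
}

#' Compose two poses
#'
#' `pose_compose(b, a)` is the pose that first applies `a`, then `b`.
#' @param b,a poses.
#' @return a `pose`.
#' @export
pose_compose <- function(b, a) {
  Rb <- pose_matrix(b); Ra <- pose_matrix(a)
  R <- Rb %*% Ra
  t <- as.numeric(Rb %*% a$shift) + b$shift
  pose(matrix_to_euler(R), t)
}

#' Invert a pose
#' @param p a pose.
#' @return the pose `q` with `pose_compose(q, p)` the identity.
#' @export
pose_invert <- function(p) {
  R <- pose_matrix(p)
  pose(matrix_to_euler(t(R)), as.numeric(-t(R) %*% p$shift))
}

#' Geodesic angle (degrees) between two rotations
#'
#' The angle of the relative rotation `R1' R2`; used as the rotational
#' distance when clustering fits.
#' @param a1,a2 ZYZ angle triples (degrees) or poses.
#' @return angle in degrees in `[0, 180]`.
#' @export
rotation_distance <- function(a1, a2) {
  R <- t(pose_matrix(a1)) %*% pose_matrix(a2)
  rad2deg(acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))))
}

is_identity_pose <- function(p, tol = 1e-12) {
  all(abs(p$angles) < tol) && all(abs(p$shift) < tol)
}
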