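#' Quasi-uniform SO(3) orientation grid
#'
#' Orientations are built as (direction of the rotated z-axis) x
#' (in-plane spin): directions come from a Fibonacci sphere lattice
#' with `round(4 * (180/step)^2 / pi)` points (nearest-neighbour
#' angular spacing ~ `step`), crossed with `round(360/step)` in-plane
#' angles.  The construction is deterministic and its size is exactly
#' `n_dir * n_psi`.
#'
#' @param angular_step grid step in degrees (> 0).
#' @return matrix with columns `phi, theta, psi` (ZYZ degrees), one row
#'   per orientation; attributes `step`, `n_dir`, `n_psi`.
#' @export
so3_grid <- function(angular_step) {
  stopifnot(angular_step > 0)
  n_dir <- max(1L, as.integer(round(4 * (180 / angular_step)^2 / pi)))
  n_psi <- max(1L, as.integer(round(360 / angular_step)))
  i <- seq_len(n_dir) - 0.5
  ga <- pi * (3 - sqrt(5))                     # golden angle
  cth <- 1 - 2 * i / n_dir                     # uniform in cos(theta)
  theta <- rad2deg(acos(pmax(-1, pmin(1, cth))))
  phi <- rad2deg((i * ga) %% (2 * pi))
  psi <- (seq_len(n_psi) - 1) * 360 / n_psi
  out <- cbind(phi = rep(phi, each = n_psi),
               theta = rep(theta, each = n_psi),
               psi = rep(psi, times = n_dir))
  attr(out, "step") <- angular_step
  attr(out, "n_dir") <- n_dir
  attr(out, "n_psi") <- n_psi
  out
}
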