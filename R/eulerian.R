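#' Pointwise speed of a velocity field
#'
#' Per-voxel Euclidean norm `sqrt(vx^2 + vy^2 + vz^2)` of one substep's
#' velocity field.
#'
#' @param v Length-`3n` velocity `[vx; vy; vz]`.
#' @param grid A [grid_spec()] object.
#' @return Length-`n` nonnegative speed map.
#' @export
speed_map <- function(v, grid) {
  check_vector_field(grid, v)
  vc <- split_velocity(grid, v)
  sqrt(vc$x^2 + vc$y^2 + vc$z^2)
}

#' Time-averaged Eulerian speed and relative-source maps
#'
#' Averages the per-substep Eulerian speed maps and relative-source maps
#' over a frame window: the mean over loops `N0 + 1` to `N1` and substeps
#' `0` to `m - 1`, i.e. a plain mean over `m * (N1 - N0)` substep fields.
#'
#' @param solutions List of [gauss_newton()] solutions in loop order
#'   (loop `k` carries frame `k - 1` to frame `k`).
#' @param N0,N1 Frame window bounds, `0 <= N0 < N1 <=` number of loops.
#' @return List with `speed` and `source`, each a length-`n` field.
#' @export
time_averaged_maps <- function(solutions, N0 = 0, N1 = length(solutions)) {
  stopifnot(N0 >= 0, N1 > N0, N1 <= length(solutions))
  grid <- solutions[[1L]]$grid
  m <- grid$m
  speed_sum <- numeric(grid$n)
  source_sum <- numeric(grid$n)
  for (k in (N0 + 1L):N1) {
    sol <- solutions[[k]]
    for (j in seq_len(m)) {
      speed_sum <- speed_sum + speed_map(sol$controls$v[[j]], grid)
      source_sum <- source_sum + sol$controls$r[[j]]
    }
  }
  nfields <- m * (N1 - N0)
  list(speed = speed_sum / nfields, source = source_sum / nfields)
}
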