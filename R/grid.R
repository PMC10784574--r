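#' Cell-centered space-time grid
#'
#' Defines the cell-centered 3D grid and the uniform time partition on which
#' densities, velocities and relative sources are discretized. All flattened
#' fields use the x-fastest ordering (x index varies fastest, then y, then z),
#' which is R's native array layout, so `as.vector(arr)` of an
#' `n1 x n2 x n3` array is the canonical flattened vector.
#'
#' @param n1,n2,n3 Voxel counts along x, y, z (each >= 1).
#' @param dx,dy,dz Voxel spacings (grid length units, > 0).
#' @param dt Duration of one numerical substep (time units, > 0).
#' @param m Number of substeps between two consecutive images (>= 1).
#'
#' @return An object of class `uromt_grid`: a list with elements
#'   `n1,n2,n3,n` (total voxels), `dx,dy,dz,dt,m` and `T = m*dt`.
#' @examples
#' g <- grid_spec(4, 4, 3, m = 2, dt = 0.4)
#' g$n      # 48
#' g$T      # 0.8
#' @export
grid_spec <- function(n1, n2, n3, dx = 1, dy = 1, dz = 1, dt = 0.4, m = 10) {
  stopifnot(n1 >= 1, n2 >= 1, n3 >= 1, m >= 1,
            dx > 0, dy > 0, dz > 0, dt > 0)
  structure(list(
    n1 = as.integer(n1), n2 = as.integer(n2), n3 = as.integer(n3),
    n  = as.integer(n1) * as.integer(n2) * as.integer(n3),
    dx = dx, dy = dy, dz = dz,
    dt = dt, m = as.integer(m), T = m * dt
  ), class = "uromt_grid")
}

#' @export
print.uromt_grid <- function(x, ...) {
  cat(sprintf("uromt grid: %d x %d x %d voxels (n = %d), spacing (%g, %g, %g)\n",
              x$n1, x$n2, x$n3, x$n, x$dx, x$dy, x$dz))
  cat(sprintf("time: m = %d substeps of dt = %g (T = %g)\n", x$m, x$dt, x$T))
  invisible(x)
}

# voxel volume and the discrete space-time measure used by the cost
cell_volume <- function(grid) grid$dx * grid$dy * grid$dz

# 1-based (i, j, k) index triples of all cells, x fastest; n x 3 matrix
cell_index_triples <- function(grid) {
  cbind(
    rep_len(seq_len(grid$n1), grid$n),
    rep_len(rep(seq_len(grid$n2), each = grid$n1), grid$n),
    rep(seq_len(grid$n3), each = grid$n1 * grid$n2)
  )
}

# flatten (i, j, k) triples to linear indices under the x-fastest order
flatten_index <- function(grid, i, j, k) {
  i + (j - 1L) * grid$n1 + (k - 1L) * grid$n1 * grid$n2
}

check_scalar_field <- function(grid, x, name = "field") {
  if (length(x) != grid$n)
    stop(sprintf("%s has length %d; expected n = %d", name, length(x), grid$n))
  if (!all(is.finite(x)))
    stop(sprintf("%s contains non-finite values", name))
  invisible(TRUE)
}

check_vector_field <- function(grid, v, name = "velocity") {
  if (length(v) != 3L * grid$n)
    stop(sprintf("%s has length %d; expected 3n = %d", name, length(v), 3L * grid$n))
  if (!all(is.finite(v)))
    stop(sprintf("%s contains non-finite values", name))
  invisible(TRUE)
}

# split a length-3n [vx; vy; vz] vector into a list of components
split_velocity <- function(grid, v) {
  n <- grid$n
  list(x = v[seq_len(n)], y = v[n + seq_len(n)], z = v[2L * n + seq_len(n)])
}
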