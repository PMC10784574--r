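# Lagrangian post-processing: pathlines through the concatenated per-substep
# velocity fields, with per-vertex speed and Peclet attributes, and the
# start-to-end velocity flux (displacement) vectors.

# trilinear interpolation of a flattened scalar field at continuous index
# coordinates (p is an npts x 3 matrix, clamped to the cell-center box)
trilinear_interp <- function(grid, field, p) {
  ext <- c(grid$n1, grid$n2, grid$n3)
  f <- matrix(0L, nrow(p), 3L)
  fr <- matrix(0, nrow(p), 3L)
  for (a in 1:3) {
    q <- pmin(pmax(p[, a], 1), ext[a])
    if (ext[a] > 1L) {
      fa <- pmin(floor(q), ext[a] - 1L)
      f[, a] <- as.integer(fa)
      fr[, a] <- q - fa
    } else {
      f[, a] <- 1L
    }
  }
  out <- numeric(nrow(p))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    if ((cx == 1 && grid$n1 == 1L) || (cy == 1 && grid$n2 == 1L) ||
        (cz == 1 && grid$n3 == 1L)) next
    w <- (if (cx == 0) 1 - fr[, 1] else fr[, 1]) *
         (if (cy == 0) 1 - fr[, 2] else fr[, 2]) *
         (if (cz == 0) 1 - fr[, 3] else fr[, 3])
    idx <- flatten_index(grid, f[, 1] + cx, f[, 2] + cy, f[, 3] + cz)
    out <- out + w * field[idx]
  }
  out
}

# central-difference gradient magnitude of a flattened field (one-sided at
# the boundary), in physical units
gradient_magnitude <- function(grid, field) {
  arr <- array(field, dim = c(grid$n1, grid$n2, grid$n3))
  gsq <- array(0, dim = dim(arr))
  steps <- c(grid$dx, grid$dy, grid$dz)
  for (a in 1:3) {
    ext <- dim(arr)[a]
    if (ext < 2L) next
    up <- slice_shift(arr, a, 1L)
    dn <- slice_shift(arr, a, -1L)
    denom <- array(2 * steps[a], dim = dim(arr))
    edge <- slice_index(dim(arr), a, c(1L, ext))
    denom[edge] <- steps[a]
    gsq <- gsq + ((up - dn) / denom)^2
  }
  as.vector(sqrt(gsq))
}

# shift an array along axis a by one cell, replicating the edge
slice_shift <- function(arr, a, dir) {
  ext <- dim(arr)[a]
  ord <- if (dir > 0) pmin(seq_len(ext) + 1L, ext) else pmax(seq_len(ext) - 1L, 1L)
  idx <- list(seq_len(dim(arr)[1]), seq_len(dim(arr)[2]), seq_len(dim(arr)[3]))
  idx[[a]] <- ord
  arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# logical mask selecting given positions along axis a
slice_index <- function(dims, a, positions) {
  mask <- array(FALSE, dim = dims)
  idx <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  idx[[a]] <- positions
  mask[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  mask
}

#' Deterministic pathline seeds
#'
#' Cell centers where the density exceeds a threshold, subsampled every
#' `stride`-th voxel per axis, in flattened (x-fastest) order.
#'
#' @param rho0 Length-`n` density used for seeding.
#' @param grid A [grid_spec()] object.
#' @param threshold Keep voxels with `rho0 > threshold`.
#' @param stride Per-axis subsampling step (>= 1).
#' @return Matrix with columns `x, y, z` of seed coordinates (continuous
#'   index units); zero rows (with a warning) if no voxel qualifies.
#' @export
seed_points <- function(rho0, grid, threshold = 0, stride = 1L) {
  check_scalar_field(grid, rho0, "rho0")
  stopifnot(threshold >= 0, stride >= 1)
  idx <- cell_index_triples(grid)
  keep <- rho0 > threshold &
    (idx[, 1] - 1L) %% stride == 0L &
    (idx[, 2] - 1L) %% stride == 0L &
    (idx[, 3] - 1L) %% stride == 0L
  if (!any(keep)) warning("no seed points above threshold")
  pts <- idx[keep, , drop = FALSE]
  storage.mode(pts) <- "double"
  colnames(pts) <- c("x", "y", "z")
  pts
}

#' Trace pathlines through the fitted velocity fields
#'
#' Integrates seeds through every substep of every loop with explicit Euler
#' steps `x <- x + dt * v(x)` (velocity components trilinearly interpolated
#' at the current position, positions clamped to the domain box). Each
#' vertex carries the local speed and the Peclet number
#' `Pe = rho * ||v|| / (sigma * ||grad rho|| + eps)` — the ratio of
#' advective to diffusive flux magnitude — with the density and its
#' central-difference gradient interpolated from the concurrent interpolated
#' image. With `sigma = 0`, `Pe` is reported as `Inf` wherever
#' `rho * ||v|| > 0` and 0 elsewhere.
#'
#' @param solutions List of [gauss_newton()] solutions in loop order.
#' @param seeds Seed matrix from [seed_points()] (columns `x, y, z`).
#' @param eps Regularizer in the Peclet denominator.
#' @return An object of class `uromt_pathlines`: list with `paths` (per seed
#'   a list of `vertices` (matrix), `speed`, `peclet` vectors), `seeds`, and
#'   the grid.
#' @export
trace_pathlines <- function(solutions, seeds, eps = 1e-12) {
  grid <- solutions[[1L]]$grid
  sigma <- solutions[[1L]]$params$sigma
  npts <- nrow(seeds)
  pos <- seeds[, 1:3, drop = FALSE]
  total_steps <- length(solutions) * grid$m
  verts <- array(NA_real_, dim = c(npts, 3L, total_steps + 1L))
  speed_attr <- matrix(NA_real_, npts, total_steps + 1L)
  pe_attr <- matrix(NA_real_, npts, total_steps + 1L)
  ext <- c(grid$n1, grid$n2, grid$n3)
  steps <- c(grid$dx, grid$dy, grid$dz)
  vertex <- 1L
  verts[, , vertex] <- pos
  for (k in seq_along(solutions)) {
    sol <- solutions[[k]]
    for (j in seq_len(grid$m)) {
      vc <- split_velocity(grid, sol$controls$v[[j]])
      vx <- trilinear_interp(grid, vc$x, pos)
      vy <- trilinear_interp(grid, vc$y, pos)
      vz <- trilinear_interp(grid, vc$z, pos)
      sp <- sqrt(vx^2 + vy^2 + vz^2)
      rho_here <- trilinear_interp(grid, sol$seq$rho[[j]], pos)
      gmag <- trilinear_interp(grid,
                               gradient_magnitude(grid, sol$seq$rho[[j]]), pos)
      if (sigma == 0) {
        pe <- ifelse(rho_here * sp > 0, Inf, 0)
      } else {
        pe <- rho_here * sp / (sigma * gmag + eps)
      }
      speed_attr[, vertex] <- sp
      pe_attr[, vertex] <- pe
      # Euler step in index coordinates, clamped to the cell-center box
      pos <- pos + grid$dt * cbind(vx / steps[1], vy / steps[2], vz / steps[3])
      for (a in 1:3) pos[, a] <- pmin(pmax(pos[, a], 1), ext[a])
      vertex <- vertex + 1L
      verts[, , vertex] <- pos
    }
  }
  # attributes at the terminal vertex from the last loop's final state
  last <- solutions[[length(solutions)]]
  vc <- split_velocity(grid, last$controls$v[[grid$m]])
  sp <- sqrt(trilinear_interp(grid, vc$x, pos)^2 +
             trilinear_interp(grid, vc$y, pos)^2 +
             trilinear_interp(grid, vc$z, pos)^2)
  rho_here <- trilinear_interp(grid, last$seq$rho[[grid$m + 1L]], pos)
  gmag <- trilinear_interp(grid,
                           gradient_magnitude(grid, last$seq$rho[[grid$m + 1L]]),
                           pos)
  speed_attr[, vertex] <- sp
  pe_attr[, vertex] <- if (sigma == 0) ifelse(rho_here * sp > 0, Inf, 0) else
    rho_here * sp / (sigma * gmag + eps)
  paths <- lapply(seq_len(npts), function(s) {
    list(vertices = t(verts[s, , ]), speed = speed_attr[s, ],
         peclet = pe_attr[s, ])
  })
  structure(list(paths = paths, seeds = seeds, grid = grid),
            class = "uromt_pathlines")
}

#' Velocity flux (displacement) vectors
#'
#' The vector from each pathline's start to its end point, with the start
#' retained for rendering. Its norm is bounded by the pathline's arc length.
#'
#' @param pathlines A [trace_pathlines()] result.
#' @return Data frame with start coordinates (`x0, y0, z0`), displacement
#'   components (`dx, dy, dz`) and `norm`.
#' @export
flux_vectors <- function(pathlines) {
  rows <- lapply(pathlines$paths, function(p) {
    v <- p$vertices
    d <- v[nrow(v), ] - v[1L, ]
    c(v[1L, ], d, sqrt(sum(d^2)))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("x0", "y0", "z0", "dx", "dy", "dz", "norm")
  out
}

# polyline arc length helper (used by tests and export)
path_arc_length <- function(path) {
  v <- path$vertices
  if (nrow(v) < 2L) return(0)
  sum(sqrt(rowSums((v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2)))
}
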