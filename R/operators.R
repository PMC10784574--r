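#' Neumann Laplacian on the cell-centered grid
#'
#' Assembles the 7-point finite-difference Laplacian with ghost-point Neumann
#' closure (zero derivative across every face), so constants are in its null
#' space, every row sums to 0 and the matrix is symmetric. Second differences
#' are scaled by `1/dx^2`, `1/dy^2`, `1/dz^2` per axis.
#'
#' @param grid A [grid_spec()] object.
#' @return A sparse symmetric `n x n` `Matrix::dgCMatrix`.
#' @export
neumann_laplacian <- function(grid) {
  n <- grid$n
  idx <- cell_index_triples(grid)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  axes <- list(
    list(col = 1L, extent = grid$n1, h2 = grid$dx^2, stride = 1L),
    list(col = 2L, extent = grid$n2, h2 = grid$dy^2, stride = grid$n1),
    list(col = 3L, extent = grid$n3, h2 = grid$dz^2, stride = grid$n1 * grid$n2)
  )
  lin <- seq_len(n)
  for (ax in axes) {
    if (ax$extent < 2L) next
    has_prev <- idx[, ax$col] > 1L
    has_next <- idx[, ax$col] < ax$extent
    # off-diagonal couplings to existing neighbors
    ii <- c(ii, lin[has_next], lin[has_prev])
    jj <- c(jj, lin[has_next] + ax$stride, lin[has_prev] - ax$stride)
    xx <- c(xx, rep(1 / ax$h2, sum(has_next) + sum(has_prev)))
    # diagonal: one -1/h^2 per existing neighbor (ghost-point Neumann closure)
    ii <- c(ii, lin); jj <- c(jj, lin)
    xx <- c(xx, -(has_prev + has_next) / ax$h2)
  }
  if (length(ii) == 0L)
    return(Matrix::sparseMatrix(i = 1L, j = 1L, x = 0, dims = c(n, n)))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Implicit diffusion solver
#'
#' Builds and factorizes the backward-Euler diffusion system
#' `L = I - sigma*dt*Q` where `Q` is the Neumann Laplacian, for repeated
#' solves `L rho_{i+1} = rho_i^adv`. `L` is symmetric positive definite, so a
#' sparse Cholesky factorization is computed once and reused; its solves
#' conserve the total of any input vector (the Neumann closure makes `1' Q = 0`).
#'
#' @param grid A [grid_spec()] object.
#' @param sigma Diffusion coefficient (length^2/time, >= 0). `sigma = 0`
#'   makes the solve an exact identity.
#' @return An object of class `uromt_diffusion`: list with `sigma`, `Q`, `L`
#'   and a cached factorization.
#' @export
diffusion_solver <- function(grid, sigma) {
  stopifnot(sigma >= 0)
  Q <- neumann_laplacian(grid)
  if (sigma == 0) {
    return(structure(list(sigma = 0, grid = grid, Q = Q, L = NULL, chol = NULL),
                     class = "uromt_diffusion"))
  }
  L <- Matrix::Diagonal(grid$n) - (sigma * grid$dt) * Q
  L <- Matrix::forceSymmetric(L)
  ch <- tryCatch(Matrix::Cholesky(L, LDL = FALSE), error = function(e) NULL)
  structure(list(sigma = sigma, grid = grid, Q = Q, L = L, chol = ch),
            class = "uromt_diffusion")
}

#' Apply the inverse diffusion operator
#'
#' Solves `L rho = b` with `L = I - sigma*dt*Q` (backward-Euler diffusion over
#' one substep). Falls back to conjugate gradients at relative tolerance 1e-10
#' if the Cholesky factorization is unavailable; a non-convergent solve is an
#' error, never a silent return.
#'
#' @param solver A [diffusion_solver()] object.
#' @param b Length-`n` right-hand side (flattened field).
#' @return The diffused field, same length as `b`.
#' @export
apply_diffusion_inverse <- function(solver, b) {
  check_scalar_field(solver$grid, b, "diffusion input")
  if (solver$sigma == 0) return(b)
  if (!is.null(solver$chol))
    return(as.numeric(Matrix::solve(solver$chol, b, system = "A")))
  cg_solve_spd(solver$L, b, rtol = 1e-10, maxit = 10L * solver$grid$n)
}

# plain conjugate gradients on an SPD sparse matrix (fallback path)
cg_solve_spd <- function(A, b, rtol = 1e-10, maxit = 1000L) {
  x <- b # warm start: L is a perturbation of the identity
  r <- b - as.numeric(A %*% x)
  p <- r
  rs <- sum(r * r)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) return(numeric(length(b)))
  for (it in seq_len(maxit)) {
    if (sqrt(rs) <= rtol * bnorm) return(x)
    Ap <- as.numeric(A %*% p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (sqrt(rs) > rtol * bnorm)
    stop("diffusion solve did not converge")
  x
}

# Trilinear particle-in-cell geometry shared by the advection matrix and its
# velocity derivative. Cell centers live at integer index coordinates
# 1..n_axis; a center displaced by dt*v (converted to index units) is clamped
# componentwise to [1, n_axis] so no mass leaves the box. Returns, per cell,
# the floor index, the fractional offset and whether the clamp is active
# (strictly outside the box before clamping) per axis.
pic_geometry <- function(grid, v) {
  idx <- cell_index_triples(grid)
  vc <- split_velocity(grid, v)
  geom <- vector("list", 3L)
  extents <- c(grid$n1, grid$n2, grid$n3)
  steps <- c(grid$dx, grid$dy, grid$dz)
  for (a in 1:3) {
    q <- idx[, a] + grid$dt * vc[[a]] / steps[a]
    clamped <- q < 1 | q > extents[a]
    q <- pmin(pmax(q, 1), extents[a])
    if (extents[a] > 1L) {
      f <- pmin(floor(q), extents[a] - 1L)
      geom[[a]] <- list(f = as.integer(f), frac = q - f, clamped = clamped,
                        degenerate = FALSE)
    } else {
      geom[[a]] <- list(f = rep.int(1L, grid$n), frac = numeric(grid$n),
                        clamped = clamped, degenerate = TRUE)
    }
  }
  geom
}

#' Particle-in-cell advection matrix
#'
#' Builds the sparse matrix `S(v)` that advances a density one substep under
#' the velocity field `v`: each cell center is displaced by `dt*v`, clamped to
#' the domain box, and its mass is split over the (up to) eight nearest cell
#' centers with trilinear weights. Entry `(j, k)` is the fraction of cell
#' `k`'s mass allocated to cell `j`; every column sums to 1, so advection
#' conserves total mass exactly.
#'
#' @param grid A [grid_spec()] object.
#' @param v Length-`3n` velocity `[vx; vy; vz]` (grid length per time).
#' @return Sparse `n x n` `Matrix::dgCMatrix`.
#' @export
advection_matrix <- function(grid, v) {
  check_vector_field(grid, v)
  geom <- pic_geometry(grid, v)
  n <- grid$n
  cols <- seq_len(n)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wx <- if (cx == 0) 1 - geom[[1]]$frac else geom[[1]]$frac
    wy <- if (cy == 0) 1 - geom[[2]]$frac else geom[[2]]$frac
    wz <- if (cz == 0) 1 - geom[[3]]$frac else geom[[3]]$frac
    if ((cx == 1 && geom[[1]]$degenerate) ||
        (cy == 1 && geom[[2]]$degenerate) ||
        (cz == 1 && geom[[3]]$degenerate)) next
    w <- wx * wy * wz
    keep <- w != 0
    if (!any(keep)) next
    rows <- flatten_index(grid,
                          geom[[1]]$f[keep] + cx,
                          geom[[2]]$f[keep] + cy,
                          geom[[3]]$f[keep] + cz)
    ii <- c(ii, rows); jj <- c(jj, cols[keep]); xx <- c(xx, w[keep])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

# Derivative of S(v) w %*% (fixed w) with respect to v: the n x 3n sparse
# matrix B with B[j, (axis block) k] = w_k * d(weight_{jk}) / d(v_axis_k).
# Per-axis trilinear factors are linear in the displacement, so the
# derivative of the product is the per-axis sign times the other two
# factors, scaled by dt/h of that axis; a clamped axis contributes 0.
advection_derivative <- function(grid, v, w) {
  check_vector_field(grid, v)
  check_scalar_field(grid, w, "advected mass")
  geom <- pic_geometry(grid, v)
  n <- grid$n
  steps <- c(grid$dx, grid$dy, grid$dz)
  cols <- seq_len(n)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    if ((cx == 1 && geom[[1]]$degenerate) ||
        (cy == 1 && geom[[2]]$degenerate) ||
        (cz == 1 && geom[[3]]$degenerate)) next
    fx <- if (cx == 0) 1 - geom[[1]]$frac else geom[[1]]$frac
    fy <- if (cy == 0) 1 - geom[[2]]$frac else geom[[2]]$frac
    fz <- if (cz == 0) 1 - geom[[3]]$frac else geom[[3]]$frac
    rows <- flatten_index(grid,
                          geom[[1]]$f + cx, geom[[2]]$f + cy, geom[[3]]$f + cz)
    corner <- list(c(cx, cx == 0), c(cy, cy == 0), c(cz, cz == 0))
    facs <- list(fx, fy, fz)
    for (a in 1:3) {
      if (geom[[a]]$degenerate) next
      sgn <- if (corner[[a]][1] == 0) -1 else 1
      others <- facs[-a]
      dw <- sgn * (grid$dt / steps[a]) * others[[1]] * others[[2]] * w
      dw[geom[[a]]$clamped] <- 0
      keep <- dw != 0
      if (!any(keep)) next
      ii <- c(ii, rows[keep])
      jj <- c(jj, (a - 1L) * n + cols[keep])
      xx <- c(xx, dw[keep])
    }
  }
  if (length(ii) == 0L)
    return(Matrix::sparseMatrix(i = 1L, j = 1L, x = 0, dims = c(n, 3L * n)))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, 3L * n))
}

#' Relative-source step
#'
#' Applies one substep of local mass gain/loss:
#' `rho_src = (1 + dt * r * chi) * rho`, the discretized relative-source
#' equation. The indicator `chi` gates where the source may act; the total
#' mass ledger `sum(out) - sum(rho) = dt * sum(rho * r * chi)` holds to
#' machine precision.
#'
#' @param rho Length-`n` nonnegative density.
#' @param r Length-`n` relative source (fractional mass change per time).
#' @param chi Length-`n` indicator in `{0, 1}`.
#' @param dt Substep duration.
#' @param guard Feasibility floor: it is an error ("negativity violation") if
#'   `1 + dt*r*chi < guard` at any voxel with `rho > 0`.
#' @return The post-source density.
#' @export
apply_source <- function(rho, r, chi, dt, guard = 1e-8) {
  stopifnot(length(r) == length(rho), length(chi) == length(rho))
  fac <- 1 + dt * r * chi
  if (any(rho > 0 & fac < guard))
    stop("negativity violation: 1 + dt*r*chi fell below the feasibility floor on a positive-density voxel")
  fac * rho
}
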